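#' Jack-knife permutation effect sizes for individual regions
#'
#' Attributes a multivariate MDMR term effect to the individual outcome
#' columns. For each ROI column q, the column is dissociated from the
#' predictors by shuffling its values across participants K times; each
#' shuffle k yields a new distance matrix `D_k` (only the shuffled column's
#' contribution changes), and the term's pseudo-R2 is recomputed on the
#' re-centered `G_k`. The effect size is
#' `delta_q = pseudoR2(observed) - mean_k pseudoR2(shuffled)`: the share of
#' the term's multivariate signal that is lost when region q no longer
#' carries participant-specific information. A Monte-Carlo standard error
#' (`sd_k / sqrt(K)`) accompanies each delta.
#'
#' delta is a relative quantity: it scales with the dimensionality and
#' covariance of the outcome set and should not be compared across studies.
#'
#' @param Y T-scored outcome matrix (participants x ROIs).
#' @param cohort Aligned `cohort_table`.
#' @param term Term whose pseudo-R2 is decomposed: `"group"` or `"sex"`.
#' @param groups Optional length-2 character vector: restrict to a two-group
#'   contrast (participants in other groups are dropped and the group term
#'   becomes the two-level contrast, mirroring the pairwise MDMR refits).
#' @param model Covariate set passed to [build_design()].
#' @param metric Distance metric, as in [pairwise_distances()].
#' @param K Number of shuffles per column (>= 100).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Data frame of class `effect_size_table`: `column_id`, `delta`,
#'   `mc_se`, `K`; attributes `term`, `contrast`, `observed_R2`, `metric`.
#' @export
jackknife_effect_sizes <- function(Y, cohort, term = "group", groups = NULL,
                                   model = 1, metric = "manhattan",
                                   K = 1000, seed = NULL) {
  stopifnot(is.matrix(Y), nrow(Y) == nrow(cohort))
  if (K < 100) stop("K must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  contrast <- NA_character_
  df <- as.data.frame(cohort)
  if (!is.null(groups)) {
    stopifnot(length(groups) == 2L)
    keep <- df$group %in% groups
    Y <- Y[keep, , drop = FALSE]
    df <- droplevels(df[keep, , drop = FALSE])
    contrast <- paste(groups, collapse = " vs ")
  }
  n <- nrow(Y)
  design <- build_design(df, model = model)
  Hf <- hat_matrix(design$X)
  Hr <- hat_matrix(design_drop_term(design, term))
  Cn <- diag(n) - 1 / n
  M1 <- Cn %*% (Hf - Hr) %*% Cn
  M2 <- Cn

  manhattan <- match.arg(metric, c("manhattan", "euclidean")) == "manhattan"
  D <- pairwise_distances(Y, if (manhattan) "manhattan" else "euclidean")
  base <- if (manhattan) D else D^2
  A <- -0.5 * D^2
  R2_obs <- sum(M1 * A) / sum(M2 * A)

  cols <- colnames(Y)
  delta <- mc_se <- numeric(length(cols))
  for (j in seq_along(cols)) {
    yq <- Y[, j]
    if (stats::sd(yq) == 0) {
      warning("column '", cols[j], "' is constant; delta set to 0")
      delta[j] <- 0
      mc_se[j] <- 0
      next
    }
    comp <- abs(outer(yq, yq, `-`))
    if (!manhattan) comp <- comp^2
    perms <- replicate(K, sample.int(n)) - 1L
    storage.mode(perms) <- "integer"
    r2k <- jk_perm_r2(base, comp, M1, M2, perms, manhattan)
    delta[j] <- R2_obs - mean(r2k)
    mc_se[j] <- stats::sd(r2k) / sqrt(K)
  }
  structure(
    data.frame(column_id = cols, delta = delta, mc_se = mc_se, K = K,
               stringsAsFactors = FALSE),
    class = c("effect_size_table", "data.frame"),
    term = term, contrast = contrast, observed_R2 = R2_obs,
    metric = if (manhattan) "manhattan" else "euclidean"
  )
}

#' Rank regions by effect size
#'
#' @param table An `effect_size_table` from [jackknife_effect_sizes()].
#' @param top_k How many regions to return (default all). Ties in `delta`
#'   are broken lexicographically by `column_id`.
#' @return The table sorted by decreasing `delta`, truncated to `top_k`
#'   rows, with a `rank` column prepended.
#' @export
rank_regions <- function(table, top_k = nrow(table)) {
  stopifnot(inherits(table, "effect_size_table") || is.data.frame(table))
  if (top_k > nrow(table)) {
    stop("top_k (", top_k, ") exceeds the number of regions (", nrow(table), ")")
  }
  ord <- order(-table$delta, table$column_id)
  out <- as.data.frame(table)[ord, , drop = FALSE]
  out <- utils::head(out, top_k)
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}
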