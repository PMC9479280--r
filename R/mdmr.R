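#' Pairwise distance matrix between participants
#'
#' Computes the n x n matrix of pairwise distances across the ROI columns.
#' The Manhattan ("city-block") metric is the default for volumetric
#' analysis: it is more robust to extreme values than the Euclidean metric
#' and behaves well in higher-dimensional outcome spaces. The Euclidean
#' metric is provided because it links MDMR to classical multivariate
#' analysis (and to exact algebraic oracles).
#'
#' @param Y Numeric matrix (participants x ROIs), no missing values;
#'   typically a T-scored matrix from [normalize_volumes()].
#' @param metric `"manhattan"` (default) or `"euclidean"`.
#' @return A symmetric numeric matrix with zero diagonal, row/col names from
#'   `Y`, and the metric stored in `attr(, "metric")`.
#' @export
pairwise_distances <- function(Y, metric = c("manhattan", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(Y), is.numeric(Y))
  if (nrow(Y) < 2L) stop("at least two participants are required")
  if (anyNA(Y)) stop("missing values are not allowed")
  D <- as.matrix(stats::dist(Y, method = metric))
  attr(D, "metric") <- metric
  D
}

#' Gower-center a distance matrix
#'
#' Applies the McArdle-Anderson construction that turns pairwise distances
#' into a centered inner-product matrix: `A = -D^2 / 2`, `G = C A C` with
#' `C = I - J/n` the centering matrix. Every row and column of `G` sums to
#' zero; for Euclidean distances on column-centered data `Yc`,
#' `G = Yc %*% t(Yc)` exactly, which is the identity that makes the
#' Euclidean special case testable against ordinary least squares.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @return The centered Gower matrix `G` (same dimension), with the metric
#'   tag carried over.
#' @export
gower_center <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have a zero diagonal")
  A <- -0.5 * D^2
  rm <- rowMeans(A)
  G <- A - outer(rm, rep(1, ncol(A))) - outer(rep(1, nrow(A)), colMeans(A)) +
    mean(A)
  attr(G, "metric") <- attr(D, "metric")
  G
}

#' Multivariate distance matrix regression with permutation inference
#'
#' Regresses a Gower-centered distance matrix `G` on a design matrix and
#' tests each requested model term. For the full model with hat matrix
#' `H = X (X'X)^- X'`, the explained fraction is
#' `pseudo-R2 = tr(H G H) / tr(G)`; a term's pseudo-R2 is the increment over
#' the reduced model without that term's columns, and its pseudo-F is
#' `(increment trace / df1) / (tr(R G R) / df2)` with `R = I - H`,
#' `df1 = rank(X) - rank(X_reduced)` and `df2 = n - rank(X)`.
#'
#' Permutation p-values use the Freedman-Lane scheme by default: residuals
#' under the term's reduced model are permuted while the covariate fit is
#' retained, which preserves exchangeability for covariate-adjusted
#' contrasts. `scheme = "raw"` permutes participant labels directly. The
#' p-value uses the add-one estimator `(1 + #{F* >= F}) / (1 + B)`, with ties
#' counted as exceedances, so `p = 0` is never reported.
#'
#' Under the Manhattan metric `G` may be indefinite, so a term's pseudo-R2
#' can in principle fall outside the unit interval; such values are reported as computed
#' and flagged with a warning (permutation inference, being rank-based, is
#' unaffected).
#'
#' @param G Gower matrix from [gower_center()].
#' @param design An `mdmr_design` from [build_design()] with rows aligned
#'   to `G`.
#' @param terms Character vector of term labels to test; default all.
#' @param n_perm Number of permutations `B` (>= 99).
#' @param seed Integer seed for the permutation stream; `NULL` uses the
#'   current RNG state.
#' @param scheme `"freedman_lane"` (default) or `"raw"`.
#' @return An object of class `mdmr_result`: a data frame with one row per
#'   term (`term`, `df1`, `df2`, `pseudo_R2`, `pseudo_F`, `p_value`) and
#'   attributes `full_R2`, `n`, `n_perm`, `seed`, `scheme`, `metric`.
#' @export
mdmr_fit <- function(G, design, terms = NULL, n_perm = 999, seed = NULL,
                     scheme = c("freedman_lane", "raw")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(design, "mdmr_design"))
  n <- nrow(G)
  if (design$n != n) stop("design rows are not aligned to the Gower matrix")
  if (n_perm < 99) stop("n_perm must be at least 99")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(terms)) terms <- design$term_labels
  bad <- setdiff(terms, design$term_labels)
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "))

  trG <- sum(diag(G))
  Hf <- hat_matrix(design$X)
  rank_f <- qr(design$X)$rank
  df2 <- n - rank_f
  full_R2 <- sum(Hf * G) / trG
  resid_tr <- trG - sum(Hf * G)

  rows <- vector("list", length(terms))
  for (i in seq_along(terms)) {
    tm <- terms[i]
    Xr <- design_drop_term(design, tm)
    Hr <- hat_matrix(Xr)
    df1 <- rank_f - qr(Xr)$rank
    if (df1 < 1L) stop("term '", tm, "' is aliased with the remaining design")
    S1 <- Hf - Hr
    numer <- sum(S1 * G)
    F_obs <- (numer / df1) / (resid_tr / df2)
    R2_inc <- numer / trG

    perms <- replicate(n_perm, sample.int(n)) - 1L
    storage.mode(perms) <- "integer"
    tr2 <- if (scheme == "freedman_lane") {
      Rr <- diag(n) - Hr
      GRr <- G %*% Rr
      A0 <- Hr %*% (G %*% Hr)
      E <- Rr %*% GRr
      C1 <- Hr %*% GRr
      fl_perm_traces(S1, Hf, A0, E, C1, perms)
    } else {
      raw_perm_traces(S1, Hf, G, perms)
    }
    F_perm <- (tr2[, 1L] / df1) / (tr2[, 2L] / df2)
    p <- (1 + sum(F_perm >= F_obs)) / (1 + n_perm)
    rows[[i]] <- data.frame(term = tm, df1 = df1, df2 = df2,
                            pseudo_R2 = R2_inc, pseudo_F = F_obs,
                            p_value = p, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(0), df1 = integer(0), df2 = integer(0),
               pseudo_R2 = numeric(0), pseudo_F = numeric(0),
               p_value = numeric(0))
  if (any(out$pseudo_R2 < 0 | out$pseudo_R2 > 1)) {
    warning("pseudo_R2 outside [0, 1]; possible with an indefinite ",
            "(non-Euclidean) Gower matrix")
  }
  structure(out, class = c("mdmr_result", "data.frame"),
            full_R2 = full_R2, n = n, n_perm = n_perm, seed = seed,
            scheme = scheme, metric = attr(G, "metric"))
}

#' @export
print.mdmr_result <- function(x, ...) {
  cat(sprintf("MDMR (%s permutations, %s scheme, metric: %s)\n",
              format(attr(x, "n_perm"), big.mark = ","),
              attr(x, "scheme"), attr(x, "metric") %||% "unknown"))
  cat(sprintf("n = %d, full-model pseudo-R2 = %.4f\n\n",
              attr(x, "n"), attr(x, "full_R2")))
  df <- as.data.frame(x)
  df$pseudo_R2 <- signif(df$pseudo_R2, 4)
  df$pseudo_F <- signif(df$pseudo_F, 5)
  print(df, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-call MDMR from a T-scored matrix
#'
#' Convenience wrapper: computes distances, Gower-centers them, builds the
#' design and fits the omnibus MDMR model.
#'
#' @inheritParams pairwise_distances
#' @inheritParams build_design
#' @inheritParams mdmr_fit
#' @param cohort A `cohort_table` aligned to the rows of `Y`.
#' @return An `mdmr_result`; see [mdmr_fit()].
#' @export
mdmr <- function(Y, cohort, model = 1, metric = "manhattan",
                 interaction = FALSE, terms = NULL, n_perm = 999,
                 seed = NULL, scheme = "freedman_lane") {
  D <- pairwise_distances(Y, metric)
  G <- gower_center(D)
  design <- build_design(cohort, model = model, interaction = interaction)
  mdmr_fit(G, design, terms = terms, n_perm = n_perm, seed = seed,
           scheme = scheme)
}

#' Pairwise group contrasts via two-group MDMR refits
#'
#' For each unordered pair of groups, participants are subset to those two
#' groups, the distance submatrix is re-centered (Gower centering depends on
#' the sample, so `G` must be recomputed on the subset, never subset from the
#' full-sample `G`), and the two-level group term is tested adjusted for the
#' model's covariates.
#'
#' @param D Full-sample distance matrix from [pairwise_distances()].
#' @param cohort A `cohort_table` aligned to `D` with all three groups.
#' @inheritParams mdmr_fit
#' @inheritParams build_design
#' @return Data frame of class `mdmr_contrasts` with one row per contrast
#'   (`contrast`, `n`, `df1`, `df2`, `pseudo_R2`, `pseudo_F`, `p_value`).
#' @export
pairwise_group_contrasts <- function(D, cohort, model = 1, n_perm = 999,
                                     seed = NULL,
                                     scheme = "freedman_lane") {
  stopifnot(nrow(D) == nrow(cohort))
  groups <- factor(cohort$group)
  lev <- levels(droplevels(groups))
  if (length(lev) != 3L) stop("three groups are required")
  if (!is.null(seed)) set.seed(seed)
  pairs <- list(c("P-high", "P-low"), c("P-high", "changers"),
                c("changers", "P-low"))
  pairs <- lapply(pairs, function(p) if (all(p %in% lev)) p else NULL)
  pairs <- Filter(Negate(is.null), pairs)
  if (!length(pairs)) pairs <- utils::combn(lev, 2L, simplify = FALSE)

  rows <- lapply(pairs, function(pair) {
    idx <- which(groups %in% pair)
    sub <- droplevels(as.data.frame(cohort)[idx, , drop = FALSE])
    if (min(table(sub$group)) < 3L) stop("a group has fewer than 3 members")
    Dsub <- D[idx, idx, drop = FALSE]
    attr(Dsub, "metric") <- attr(D, "metric")
    G <- gower_center(Dsub)
    design <- build_design(sub, model = model)
    fit <- mdmr_fit(G, design, terms = "group", n_perm = n_perm,
                    seed = NULL, scheme = scheme)
    data.frame(contrast = paste(pair, collapse = " vs "), n = length(idx),
               df1 = fit$df1, df2 = fit$df2, pseudo_R2 = fit$pseudo_R2,
               pseudo_F = fit$pseudo_F, p_value = fit$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("mdmr_contrasts", "data.frame"),
            n_perm = n_perm, scheme = scheme, model = model)
}

#' Test the sex-by-group interaction
#'
#' Adds sex x group product columns to the model-1 design and tests them as a
#' single term against the main-effects reduced model.
#'
#' @inheritParams pairwise_group_contrasts
#' @return An `mdmr_result` with the interaction term row.
#' @export
interaction_test <- function(D, cohort, model = 1, n_perm = 999, seed = NULL,
                             scheme = "freedman_lane") {
  tab <- table(cohort$group, cohort$sex)
  if (sum(rowSums(tab > 0) == 2L) < 2L) {
    stop("interaction test needs both sexes represented in at least two groups")
  }
  G <- gower_center(D)
  design <- build_design(cohort, model = model, interaction = TRUE)
  term <- grep(":", design$term_labels, value = TRUE)[1L]
  mdmr_fit(G, design, terms = term, n_perm = n_perm, seed = seed,
           scheme = scheme)
}
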