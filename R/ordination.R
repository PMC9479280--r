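#' Distance-based redundancy analysis (dbRDA)
#'
#' Constrained ordination of a Gower-centered distance matrix: covariates
#' are partialled out by projecting `G` onto their orthogonal complement,
#' and the constraint (group) block's hat matrix is applied on both sides
#' before eigen-decomposition, `eigen(Hc Gp Hc)`. Participant scores on the
#' constrained axes are the eigenvectors scaled by the square roots of the
#' positive eigenvalues; with three groups at most two constrained axes
#' exist. For the Euclidean metric the constrained eigenvalues equal those
#' of a redundancy analysis of the fitted values of `Y ~ X`.
#'
#' @param D Distance matrix from [pairwise_distances()].
#' @param cohort Aligned `cohort_table`.
#' @param model Covariate set for the partialled-out block (see
#'   [build_design()]); ignored when `partial = FALSE`.
#' @param partial Partial out the model's covariates (age, sex, ...) before
#'   constraining on group. `FALSE` ordinates on the raw centered `G`.
#' @return Object of class `dbrda_ord`: list with `eigenvalues` (constrained,
#'   descending), `scores` (participants x axes), `centroids` and
#'   `centroid_se` (groups x axes; SE = within-group score SD / sqrt(n_g)),
#'   `centroid_distances` (exact pairwise centroid geometry from `G`, see
#'   [centroid_geometry()]), `prop_explained` (eigenvalue / tr(Gp)),
#'   `residual_eigenvalues`, and `status` (`"ok"` or `"empty"` when no
#'   positive constrained eigenvalue exists).
#' @export
dbrda_fit <- function(D, cohort, model = 1, partial = TRUE) {
  stopifnot(nrow(D) == nrow(cohort))
  n <- nrow(D)
  G <- gower_center(D)
  groups <- droplevels(factor(cohort$group))
  if (nlevels(groups) < 2L) stop("the constraint needs at least 2 group levels")
  design <- build_design(cohort, model = model)
  gidx <- match("group", design$term_labels)
  Xg <- design$X[, design$assign == gidx, drop = FALSE]
  if (partial) {
    Xc <- design$X[, design$assign != gidx, drop = FALSE]
    Rc <- diag(n) - hat_matrix(Xc)
    Gp <- Rc %*% G %*% Rc
    Xg_res <- Rc %*% Xg
  } else {
    Gp <- G
    Xg_res <- cbind(1, Xg)
  }
  Hc <- hat_matrix(Xg_res)
  M <- Hc %*% Gp %*% Hc
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- which(eig$values > tol)
  max_axes <- qr(Xg_res)$rank - if (partial) 0L else 1L
  pos <- utils::head(pos, max_axes)

  cg <- centroid_geometry(G, groups)
  if (!length(pos)) {
    return(structure(list(status = "empty", eigenvalues = numeric(0),
                          scores = NULL, centroids = NULL,
                          centroid_se = NULL, centroid_distances = cg,
                          prop_explained = numeric(0),
                          residual_eigenvalues = numeric(0)),
                     class = "dbrda_ord"))
  }
  lambda <- eig$values[pos]
  scores <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(lambda), length(pos))
  dimnames(scores) <- list(rownames(D), paste0("dbRDA", seq_along(pos)))

  centroids <- apply(scores, 2L, function(s) tapply(s, groups, mean))
  centroid_se <- apply(scores, 2L, function(s) {
    ng <- table(groups)
    if (any(ng < 2)) stop("centroid SE requires every group to have n >= 2")
    tapply(s, groups, stats::sd) / sqrt(as.vector(ng))
  })
  if (nlevels(groups) == 1L) {
    centroids <- matrix(centroids, 1L, dimnames = list(levels(groups), colnames(scores)))
  }

  Rres <- diag(n) - Hc
  Mr <- Rres %*% Gp %*% Rres
  res_eig <- eigen((Mr + t(Mr)) / 2, symmetric = TRUE, only.values = TRUE)$values

  structure(list(
    status = "ok",
    eigenvalues = lambda,
    scores = scores,
    centroids = centroids,
    centroid_se = centroid_se,
    centroid_distances = cg,
    prop_explained = lambda / sum(diag(Gp)),
    total_inertia = sum(diag(Gp)),
    residual_eigenvalues = res_eig
  ), class = "dbrda_ord")
}

#' @export
print.dbrda_ord <- function(x, ...) {
  if (x$status == "empty") {
    cat("<dbrda_ord> no positive constrained eigenvalue (empty result)\n")
    return(invisible(x))
  }
  cat(sprintf("<dbrda_ord> %d constrained axis/axes\n", length(x$eigenvalues)))
  cat("eigenvalues:", paste(signif(x$eigenvalues, 5), collapse = ", "), "\n")
  cat("proportion explained:",
      paste(signif(x$prop_explained, 4), collapse = ", "), "\n")
  cat("\ncentroids:\n")
  print(signif(x$centroids, 5))
  invisible(x)
}

#' Exact group-centroid geometry from a Gower matrix
#'
#' Squared distances between group centroids are computed directly from the
#' Gower matrix via indicator contrasts:
#' `d2(u, v) = e_u' G e_u + e_v' G e_v - 2 e_u' G e_v`, with `e_g` the
#' group-g indicator scaled by `1/n_g`. This uses the full geometry of `G`,
#' including any negative-eigenvalue directions of a non-Euclidean metric,
#' so no eigenvalue correction is needed; a negative squared distance (only
#' possible for non-Euclidean metrics) is reported with a flag, never
#' clipped silently. For the Euclidean metric the result equals the distance
#' between group mean vectors in outcome space.
#'
#' @param G Gower matrix from [gower_center()].
#' @param groups Factor (or vector) of group labels aligned to `G`'s rows.
#' @return List with `distance` (signed square root: `sign(d2) *
#'   sqrt(|d2|)`), `squared` (the raw `d2` values), and `negative` (logical
#'   matrix flagging negative squared distances).
#' @export
centroid_geometry <- function(G, groups) {
  groups <- droplevels(factor(groups))
  stopifnot(nrow(G) == length(groups), nlevels(groups) >= 2L)
  ng <- table(groups)
  E <- stats::model.matrix(~ groups - 1)
  E <- sweep(E, 2L, as.vector(ng), `/`)
  M <- t(E) %*% G %*% E
  d2 <- outer(diag(M), diag(M), `+`) - 2 * M
  dimnames(d2) <- list(levels(groups), levels(groups))
  diag(d2) <- 0
  neg <- d2 < -1e-12
  if (any(neg)) {
    warning("negative squared centroid distance(s); ",
            "reported with flag (non-Euclidean geometry)")
  }
  list(distance = sign(d2) * sqrt(abs(d2)), squared = d2, negative = neg)
}
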