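#' Convert raw ROI volumes to proportions of total brain volume
#'
#' Divides each ROI volume (mm^3) by the participant's total brain volume
#' (TBV, supplied in cm^3 in the cohort table and converted to mm^3 here).
#' This is the head-size correction applied before standardization: all
#' downstream analysis operates on the proportion each region occupies of the
#' participant's brain.
#'
#' @param volumes Numeric matrix (participants x ROIs, mm^3) with participant
#'   ids as row names, e.g. from [read_volumes()] or [simulate_cohort()].
#' @param cohort A `cohort_table` containing `tbv` (cm^3) for every volume row.
#' @return A matrix of the same shape with values in (0, 1). If any ROI
#'   volume exceeds its participant's TBV the offending cells are flagged
#'   with a warning and reported in the `"flagged"` attribute (never clipped).
#' @export
to_proportions <- function(volumes, cohort) {
  al <- align_volumes(volumes, cohort)
  tbv_mm3 <- al$cohort$tbv * 1000
  if (any(tbv_mm3 <= 0)) stop("TBV must be strictly positive")
  props <- al$volumes / tbv_mm3
  over <- which(props > 1, arr.ind = TRUE)
  if (nrow(over)) {
    warning(nrow(over), " ROI volume(s) exceed the participant's TBV; ",
            "values kept as computed (see attr(x, 'flagged'))")
    attr(props, "flagged") <- data.frame(
      participant_id = rownames(props)[over[, 1L]],
      column_id = colnames(props)[over[, 2L]]
    )
  }
  props
}

#' T-score a matrix column-wise
#'
#' Standardizes every column across participants to the psychometric T
#' convention, mean 50 and SD 10: `t = 50 + 10 * (x - mean(x)) / sd(x)` with
#' the sample (n-1) standard deviation. Any affine convention yields the same
#' Manhattan-distance geometry up to a global scale, to which all MDMR
#' statistics are invariant; the convention is fixed for reproducibility.
#'
#' @param x Numeric matrix (participants x ROIs), typically TBV-proportions.
#' @param center,scale Target mean and SD of each output column.
#' @return Matrix of the same shape; each column has mean `center` and SD
#'   `scale` over the analyzed sample.
#' @examples
#' to_tscores(cbind(a = c(1, 2, 3)))  # 40, 50, 60
#' @export
to_tscores <- function(x, center = 50, scale = 10) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (nrow(x) < 2L) stop("T-scoring requires at least two participants")
  if (anyNA(x)) stop("missing values are not allowed")
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  zero <- sdv <= 0 | !is.finite(sdv)
  if (any(zero)) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[zero], collapse = ", "))
  }
  out <- center + scale * sweep(sweep(x, 2L, mu, `-`), 2L, sdv, `/`)
  dimnames(out) <- dimnames(x)
  out
}

#' Full normalization: raw volumes to T-scored TBV-proportions
#'
#' Convenience wrapper running [to_proportions()] then [to_tscores()].
#'
#' @inheritParams to_proportions
#' @param proportion If `FALSE`, skip the TBV-proportion step (sensitivity
#'   analysis) and T-score the raw volumes directly.
#' @return T-scored matrix aligned to `volumes`.
#' @export
normalize_volumes <- function(volumes, cohort, proportion = TRUE) {
  x <- if (proportion) to_proportions(volumes, cohort) else volumes
  to_tscores(x)
}
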