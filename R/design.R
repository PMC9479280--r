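#' Build a design matrix with a term map
#'
#' Constructs the regression design used by all distance-based analyses.
#' Model 1 is `~ group + age + sex`; model 2 adds the family income bracket;
#' model 3 adds parental education instead. Categorical covariates are
#' dummy-coded against a reference level (first level; `"missing"` is an
#' explicit level when present). Aliased (rank-deficient) columns are dropped
#' with a message, as happens e.g. for an empty sex-by-group cell.
#'
#' @param cohort A `cohort_table` (or data frame with the canonical columns).
#' @param model Covariate set: 1 (age + sex), 2 (+ income), 3 (+ education).
#' @param interaction Add the sex-by-group interaction term.
#' @param group_var Name of the grouping column (2 or 3 levels).
#' @return An object of class `mdmr_design`: list with `X` (numeric matrix,
#'   intercept first), `assign` (term index per column, 0 = intercept),
#'   `term_labels`, `formula`, and `n`.
#' @export
build_design <- function(cohort, model = 1, interaction = FALSE,
                         group_var = "group") {
  stopifnot(model %in% 1:3)
  df <- as.data.frame(cohort)
  df$group <- droplevels(factor(df[[group_var]]))
  rhs <- c("group", "age", "sex")
  if (model == 2) {
    if (!"income_bracket" %in% names(df)) {
      stop("model 2 requires an 'income_bracket' column in the cohort table")
    }
    rhs <- c(rhs, "income_bracket")
  }
  if (model == 3) {
    if (!"parental_education" %in% names(df)) {
      stop("model 3 requires a 'parental_education' column in the cohort table")
    }
    rhs <- c(rhs, "parental_education")
  }
  if (interaction) rhs <- c(rhs, "sex:group")
  fml <- stats::as.formula(paste("~", paste(rhs, collapse = " + ")))
  for (v in intersect(c("income_bracket", "parental_education"), rhs)) {
    df[[v]] <- droplevels(factor(df[[v]]))
  }
  X <- stats::model.matrix(fml, data = df)
  assign <- attr(X, "assign")
  labels <- attr(stats::terms(fml), "term.labels")

  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    keep <- sort(qrx$pivot[seq_len(qrx$rank)])
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    warning("dropping aliased design column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
    assign <- assign[keep]
  }
  structure(list(X = X, assign = assign, term_labels = labels,
                 formula = fml, n = nrow(X)),
            class = "mdmr_design")
}

#' @export
print.mdmr_design <- function(x, ...) {
  cat(sprintf("<mdmr_design> n = %d, %d columns; terms: %s\n",
              x$n, ncol(x$X), paste(x$term_labels, collapse = ", ")))
  invisible(x)
}

# orthonormal basis -> symmetric projection (hat) matrix
hat_matrix <- function(X) {
  qrx <- qr(X)
  Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  tcrossprod(Q)
}

# columns of the design excluding one term (by label)
design_drop_term <- function(design, term) {
  idx <- match(term, design$term_labels)
  if (is.na(idx)) stop("term '", term, "' is not in the design")
  keep <- design$assign != idx
  design$X[, keep, drop = FALSE]
}
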