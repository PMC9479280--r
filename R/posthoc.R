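#' Univariate post-hoc regressions for selected regions
#'
#' Ordinary least-squares follow-up for the regions the effect-size analysis
#' singles out: on the two-group subset defined by `contrast`, each selected
#' T-scored column is regressed on the group indicator plus covariates, and
#' the group coefficient is reported on the standardized (unit-SD, "Z score")
#' scale, i.e. the T-scored outcome is rescaled by `(y - center) / scale`
#' before fitting. The coefficient is the adjusted mean difference
#' `contrast[1] - contrast[2]` in SD units of the column.
#'
#' @param Y T-scored outcome matrix (participants x ROIs).
#' @param cohort Aligned `cohort_table`.
#' @param columns Column ids of `Y` to test (default all).
#' @param contrast Length-2 character vector `(level, reference)`; e.g.
#'   `c("changers", "P-high")` reports changers minus P-high. For the sex
#'   contrast use `term = "sex"` (female minus male, full sample).
#' @param term `"group"` (two-group subset) or `"sex"` (full sample).
#' @param covariates Adjustment covariates (columns of `cohort`).
#' @param center,scale Input standardization convention of `Y` (T-scores:
#'   50/10). Use `0/1` if `Y` is already z-scored.
#' @return Data frame of class `posthoc_result`: one row per column with
#'   `column_id`, `contrast`, `estimate`, `se`, `t`, `p_value`, `df`, `n`.
#' @export
univariate_regression <- function(Y, cohort, columns = colnames(Y),
                                  contrast = c("changers", "P-high"),
                                  term = c("group", "sex"),
                                  covariates = c("age", "sex"),
                                  center = 50, scale = 10) {
  term <- match.arg(term)
  stopifnot(is.matrix(Y), nrow(Y) == nrow(cohort))
  bad <- setdiff(columns, colnames(Y))
  if (length(bad)) stop("unknown column(s): ", paste(bad, collapse = ", "))
  df <- as.data.frame(cohort)
  if (term == "group") {
    stopifnot(length(contrast) == 2L)
    keep <- df$group %in% contrast
    if (!all(contrast %in% df$group)) {
      stop("contrast group(s) absent from the cohort")
    }
    df <- droplevels(df[keep, , drop = FALSE])
    Y <- Y[keep, , drop = FALSE]
    # reference = contrast[2] so the coefficient is contrast[1] - contrast[2]
    df$.pred <- stats::relevel(factor(df$group), ref = contrast[2])
    covariates <- setdiff(covariates, "group")
    label <- paste(contrast, collapse = " vs ")
  } else {
    df$.pred <- stats::relevel(factor(df$sex), ref = "male")
    covariates <- setdiff(covariates, "sex")
    label <- "female vs male"
  }
  rhs <- paste(c(".pred", covariates), collapse = " + ")
  rows <- lapply(columns, function(cid) {
    df$.y <- (Y[, cid] - center) / scale
    fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df)
    cf <- summary(fit)$coefficients
    slope <- grep("^\\.pred", rownames(cf), value = TRUE)[1L]
    data.frame(column_id = cid, contrast = label,
               estimate = cf[slope, 1L], se = cf[slope, 2L],
               t = cf[slope, 3L], p_value = cf[slope, 4L],
               df = fit$df.residual, n = nrow(df),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("posthoc_result", "data.frame")
  out
}

#' Cohort descriptives with group comparisons
#'
#' Produces a sample-characteristics report: participant counts per group and
#' sex, mean (SD) of continuous measures (age, TBV, and baseline DQ / ADOS
#' CSS when present) per group-by-sex cell, OLS pairwise group contrasts for
#' the continuous measures, an omnibus group ANOVA for TBV, and Pearson
#' chi-squared tests of independence between group and the ordinal
#' covariates (income bracket, parental education). A covariate observed at
#' a single level is reported as not applicable rather than tested.
#'
#' @param cohort A `cohort_table`.
#' @param continuous Continuous measures to summarize (present columns only).
#' @return A list of class `cohort_summary` with elements `counts`,
#'   `continuous` (named list of group-by-sex mean/SD tables), `contrasts`
#'   (pairwise OLS group differences), `tbv_anova`, and `chisq`.
#' @export
cohort_summary <- function(cohort,
                           continuous = c("age", "tbv", "dq_baseline",
                                          "ados_css")) {
  df <- as.data.frame(cohort)
  counts <- table(group = df$group, sex = df$sex)
  stopifnot(sum(counts) == nrow(df))
  continuous <- intersect(continuous, names(df))

  cell_stats <- lapply(continuous, function(v) {
    m <- tapply(df[[v]], list(df$group, df$sex), mean)
    s <- tapply(df[[v]], list(df$group, df$sex), stats::sd)
    list(mean = m, sd = s)
  })
  names(cell_stats) <- continuous

  lev <- levels(droplevels(factor(df$group)))
  pairs <- if (length(lev) >= 2L) utils::combn(lev, 2L, simplify = FALSE) else list()
  contrasts <- do.call(rbind, unlist(lapply(continuous, function(v) {
    lapply(pairs, function(pr) {
      sub <- droplevels(df[df$group %in% pr, , drop = FALSE])
      sub$.pred <- stats::relevel(factor(sub$group), ref = pr[2L])
      fit <- stats::lm(sub[[v]] ~ .pred, data = sub)
      cf <- summary(fit)$coefficients
      slope <- grep("^\\.pred", rownames(cf), value = TRUE)[1L]
      data.frame(measure = v, contrast = paste(pr, collapse = " vs "),
                 estimate = cf[slope, 1L], se = cf[slope, 2L],
                 p_value = cf[slope, 4L], stringsAsFactors = FALSE)
    })
  }), recursive = FALSE))

  tbv_anova <- if ("tbv" %in% names(df) && length(lev) >= 2L) {
    a <- stats::anova(stats::lm(tbv ~ group, data = df))
    data.frame(F = a$`F value`[1L], df1 = a$Df[1L], df2 = a$Df[2L],
               p_value = a$`Pr(>F)`[1L])
  } else NULL

  chisq <- lapply(intersect(c("income_bracket", "parental_education"),
                            names(df)), function(v) {
    lv <- droplevels(factor(df[[v]]))
    if (nlevels(lv) < 2L) {
      return(data.frame(covariate = v, statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_, note = "single observed level",
                        stringsAsFactors = FALSE))
    }
    ct <- suppressWarnings(stats::chisq.test(table(df$group, lv),
                                             correct = FALSE))
    data.frame(covariate = v, statistic = unname(ct$statistic),
               df = unname(ct$parameter), p_value = ct$p.value,
               note = "", stringsAsFactors = FALSE)
  })
  chisq <- if (length(chisq)) do.call(rbind, chisq) else NULL

  structure(list(counts = counts, continuous = cell_stats,
                 contrasts = contrasts, tbv_anova = tbv_anova,
                 chisq = chisq, n = nrow(df)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: %d participants\n\ncounts (group x sex):\n", x$n))
  print(x$counts)
  for (v in names(x$continuous)) {
    cat(sprintf("\n%s, mean (SD) by group x sex:\n", v))
    m <- x$continuous[[v]]$mean
    s <- x$continuous[[v]]$sd
    fmt <- matrix(sprintf("%.1f (%.1f)", m, s), nrow(m),
                  dimnames = dimnames(m))
    print(fmt, quote = FALSE)
  }
  if (!is.null(x$tbv_anova)) {
    cat(sprintf("\nTBV group ANOVA: F(%d, %d) = %.2f, p = %.3g\n",
                x$tbv_anova$df1, x$tbv_anova$df2, x$tbv_anova$F,
                x$tbv_anova$p_value))
  }
  if (!is.null(x$chisq)) {
    cat("\nchi-squared tests of independence with group:\n")
    print(x$chisq, row.names = FALSE)
  }
  invisible(x)
}
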