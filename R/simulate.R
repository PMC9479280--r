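#' Simulation configuration for a synthetic autism cohort
#'
#' Builds the configuration object consumed by [simulate_cohort()]. The
#' defaults reproduce the structure of the study cohort the analysis pipeline
#' was designed for: three IQ-trajectory groups of sizes 48 (P-high), 108
#' (P-low) and 109 (changers) with the published male/female split
#' (30/18, 76/32, 70/39), age about 3.2 (SD 0.5) years, group- and
#' sex-specific total brain volume distributions, structurally covarying ROI
#' volumes for the union of the FPN and DMN columns, and planted group/sex
#' shifts on named regions (see [default_planted_effects()]).
#'
#' ROI volumes are generated on a standardized latent scale: for participant
#' i and column q, `s_iq = rho * f_i + shift_iq + noise_sd * e_iq`, where
#' `f_i` is a single shared Gaussian factor inducing inter-regional
#' structural covariance and `shift_iq` is the planted effect (in SD units of
#' the standardized column). With the default `noise_sd = sqrt(1 - rho^2)`
#' each latent column has unit variance, so planted shifts equal the
#' standardized group differences recovered downstream. The latent score is
#' mapped to mm^3 as `TBV_mm3 * base_prop * (1 + roi_cv * s)`, so dividing by
#' TBV and T-scoring recovers an affine image of `s` exactly.
#'
#' @param n_per_group_by_sex 3x2 integer matrix of cell sizes; rows are the
#'   groups `P-high`, `P-low`, `changers`, columns `male`, `female`.
#' @param age_mean,age_sd Age distribution (years), common to all groups.
#' @param tbv_mean,tbv_sd 3x2 matrices of total brain volume mean/SD (cm^3)
#'   per group x sex; defaults follow the published cohort table.
#' @param roi_correlation Shared-factor loading `rho` in `[0, 1)`.
#' @param noise_sd Independent noise SD on the latent scale; `NULL` (default)
#'   uses `sqrt(1 - rho^2)` so latent columns have unit variance.
#' @param roi_cv Coefficient of variation of an ROI's TBV-proportion per unit
#'   latent score.
#' @param planted_effects Data frame with columns `column_id`, `term`
#'   (`"group"` or `"sex"`), `level`, `shift`, or `NULL` for a null cohort.
#' @param income_probs,education_probs Sampling probabilities for the 7
#'   family-income brackets and 4 parental-education levels, drawn
#'   independently of group (the study groups did not differ on either).
#' @param clinical_scores Also simulate baseline DQ and ADOS CSS columns from
#'   the published group x sex means/SDs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_group_by_sex = default_cell_sizes(),
                       age_mean = 3.2, age_sd = 0.5,
                       tbv_mean = default_tbv()$mean,
                       tbv_sd = default_tbv()$sd,
                       roi_correlation = 0.6,
                       noise_sd = NULL,
                       roi_cv = 0.08,
                       planted_effects = default_planted_effects(),
                       income_probs = c(0.08, 0.12, 0.15, 0.20, 0.20, 0.15, 0.10),
                       education_probs = c(0.15, 0.30, 0.35, 0.20),
                       clinical_scores = TRUE) {
  n <- as.matrix(n_per_group_by_sex)
  if (!all(dim(n) == c(3L, 2L)) || any(n < 0) || any(n != round(n))) {
    stop("n_per_group_by_sex must be a 3x2 matrix of non-negative integers")
  }
  dimnames(n) <- list(group_levels(), c("male", "female"))
  if (sum(n) == 0) stop("degenerate configuration: all cell sizes are zero")
  if (roi_correlation < 0 || roi_correlation >= 1) {
    stop("roi_correlation must lie in [0, 1)")
  }
  if (is.null(noise_sd)) noise_sd <- sqrt(1 - roi_correlation^2)
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (!is.null(planted_effects)) {
    stopifnot(all(c("column_id", "term", "level", "shift") %in%
                    names(planted_effects)))
    cols <- union(load_network_spec("FPN")$columns,
                  load_network_spec("DMN")$columns)
    bad <- setdiff(planted_effects$column_id, cols)
    if (length(bad)) stop("planted effect(s) reference unknown column(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(list(
    n_per_group_by_sex = n, age_mean = age_mean, age_sd = age_sd,
    tbv_mean = as.matrix(tbv_mean), tbv_sd = as.matrix(tbv_sd),
    roi_correlation = roi_correlation, noise_sd = noise_sd, roi_cv = roi_cv,
    planted_effects = planted_effects,
    income_probs = income_probs / sum(income_probs),
    education_probs = education_probs / sum(education_probs),
    clinical_scores = isTRUE(clinical_scores)
  ), class = "sim_config")
}

default_cell_sizes <- function() {
  matrix(c(30L, 76L, 70L, 18L, 32L, 39L), nrow = 3L,
         dimnames = list(group_levels(), c("male", "female")))
}

default_tbv <- function() {
  list(
    mean = matrix(c(1063, 1087, 1072, 1011, 1001, 1011), nrow = 3L,
                  dimnames = list(group_levels(), c("male", "female"))),
    sd = matrix(c(68, 103, 93, 90, 112, 121), nrow = 3L,
                dimnames = list(group_levels(), c("male", "female")))
  )
}

default_clinical <- function() {
  list(
    dq_mean = matrix(c(97.8, 46.5, 66.5, 97.3, 44.0, 70.3), nrow = 3L,
                     dimnames = list(group_levels(), c("male", "female"))),
    dq_sd = matrix(c(12.3, 10.7, 11.1, 11.8, 12.7, 11.1), nrow = 3L,
                   dimnames = list(group_levels(), c("male", "female"))),
    ados_mean = matrix(c(6.8, 7.9, 7.2, 6.3, 8.4, 7.0), nrow = 3L,
                       dimnames = list(group_levels(), c("male", "female"))),
    ados_sd = matrix(c(2.0, 1.7, 1.6, 1.7, 1.3, 1.3), nrow = 3L,
                     dimnames = list(group_levels(), c("male", "female")))
  )
}

#' Planted group and sex effects used by the default simulation scenario
#'
#' The default scenario plants standardized shifts, relative to the reference
#' levels `P-high` (group) and `male` (sex), on the regions the univariate
#' follow-up analyses single out: the left middle occipital gyrus is smaller
#' in changers (-0.65) and in P-low (-0.56) than in P-high; the left inferior
#' temporal gyrus is larger in changers (+0.44) and in P-low (+0.58); both
#' middle temporal gyri are smaller in changers (-0.35) than in the other
#' groups; and the right angular gyrus is larger in females (+0.29). Shifts
#' are in SD units of the standardized (T-scored TBV-proportion) column.
#'
#' @return A data frame with columns `column_id`, `term`, `level`, `shift`.
#' @export
default_planted_effects <- function() {
  data.frame(
    column_id = c("middle_occipital_gyrus_left", "middle_occipital_gyrus_left",
                  "inferior_temporal_gyrus_left", "inferior_temporal_gyrus_left",
                  "middle_temporal_gyrus_left", "middle_temporal_gyrus_right",
                  "angular_gyrus_right"),
    term = c("group", "group", "group", "group", "group", "group", "sex"),
    level = c("changers", "P-low", "changers", "P-low",
              "changers", "changers", "female"),
    shift = c(-0.65, -0.56, 0.44, 0.58, -0.35, -0.35, 0.29),
    stringsAsFactors = FALSE
  )
}

#' Simulate a cohort with known ground truth
#'
#' Draws a synthetic cohort under a [sim_config()]: participant metadata
#' (group, sex, age, TBV, income, education, optional clinical scores) and a
#' raw ROI-volume matrix (mm^3) over the union of the FPN and DMN columns.
#' Given the same config and seed the output is bit-identical.
#'
#' @param config A `sim_config` object.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list with elements `cohort` (a `cohort_table`), `volumes`
#'   (numeric matrix, participants x ROI columns, mm^3), and `truth` (the
#'   planted-effect table plus the latent scores' generating parameters, for
#'   recovery tests).
#' @examples
#' sim <- simulate_cohort(sim_config(), seed = 1)
#' table(sim$cohort$group, sim$cohort$sex)
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n_tab <- config$n_per_group_by_sex
  groups <- rep(rep(group_levels(), 2L), as.vector(n_tab))
  sexes <- rep(rep(c("male", "female"), each = 3L), as.vector(n_tab))
  n <- length(groups)
  if (n < 2L) stop("at least two participants are required")
  ord <- order(match(groups, group_levels()), match(sexes, c("male", "female")))
  groups <- factor(groups[ord], levels = group_levels())
  sexes <- factor(sexes[ord], levels = c("male", "female"))
  cell <- cbind(match(groups, group_levels()), as.integer(sexes))

  cohort <- data.frame(
    participant_id = sprintf("sub-%04d", seq_len(n)),
    group = groups, sex = sexes,
    age = pmax(stats::rnorm(n, config$age_mean, config$age_sd), 0.5),
    tbv = pmax(stats::rnorm(n, config$tbv_mean[cell], config$tbv_sd[cell]), 400),
    stringsAsFactors = FALSE
  )
  income <- sample(paste0("bracket_", 1:7), n, replace = TRUE,
                   prob = config$income_probs)
  education <- sample(c("no_college", "some_college", "bachelors", "graduate"),
                      n, replace = TRUE, prob = config$education_probs)
  cohort$income_bracket <- factor(income, levels = paste0("bracket_", 1:7))
  cohort$parental_education <- factor(
    education, levels = c("no_college", "some_college", "bachelors", "graduate"))
  if (config$clinical_scores) {
    cl <- default_clinical()
    cohort$dq_baseline <- stats::rnorm(n, cl$dq_mean[cell], cl$dq_sd[cell])
    cohort$ados_css <- pmin(pmax(stats::rnorm(n, cl$ados_mean[cell],
                                              cl$ados_sd[cell]), 1), 10)
  }

  fixture <- network_fixture()
  fixture <- fixture[!duplicated(fixture$column_id), ]
  cols <- fixture$column_id
  base_prop <- stats::setNames(fixture$base_prop, cols)
  q <- length(cols)

  shared <- stats::rnorm(n)
  latent <- config$roi_correlation * matrix(shared, n, q) +
    config$noise_sd * matrix(stats::rnorm(n * q), n, q)
  colnames(latent) <- cols
  pe <- config$planted_effects
  if (!is.null(pe) && nrow(pe)) {
    for (k in seq_len(nrow(pe))) {
      who <- if (pe$term[k] == "group") groups == pe$level[k]
             else sexes == pe$level[k]
      latent[who, pe$column_id[k]] <- latent[who, pe$column_id[k]] + pe$shift[k]
    }
  }

  tbv_mm3 <- cohort$tbv * 1000
  volumes <- tbv_mm3 * sweep(1 + config$roi_cv * latent, 2L, base_prop[cols], `*`)
  volumes <- pmax(volumes, 0)
  dimnames(volumes) <- list(cohort$participant_id, cols)

  class(cohort) <- c("cohort_table", "data.frame")
  list(
    cohort = cohort,
    volumes = volumes,
    truth = list(planted_effects = pe,
                 roi_correlation = config$roi_correlation,
                 noise_sd = config$noise_sd,
                 roi_cv = config$roi_cv,
                 base_prop = base_prop,
                 seed = seed)
  )
}
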