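# small in-code fixtures shared across tests

# minimal balanced three-group cohort with both sexes in every group
toy_cohort <- function(n_per_cell = 5L, seed = 1L) {
  set.seed(seed)
  g <- rep(rep(c("P-high", "P-low", "changers"), each = n_per_cell), 2L)
  s <- rep(c("male", "female"), each = 3L * n_per_cell)
  n <- length(g)
  as_cohort_table(data.frame(
    participant_id = sprintf("p%03d", seq_len(n)),
    group = g, sex = s,
    age = runif(n, 2.5, 4), tbv = runif(n, 900, 1150),
    stringsAsFactors = FALSE
  ), quiet = TRUE)
}

# random outcome matrix aligned to a cohort, optional per-group shifts on col 1
toy_outcomes <- function(cohort, q = 4L, shift = NULL, seed = 2L) {
  set.seed(seed)
  n <- nrow(cohort)
  Y <- matrix(rnorm(n * q), n, q,
              dimnames = list(cohort$participant_id, paste0("roi_", seq_len(q))))
  if (!is.null(shift)) {
    for (g in names(shift)) Y[cohort$group == g, 1L] <- Y[cohort$group == g, 1L] + shift[[g]]
  }
  Y
}

# small null simulation config (no planted effects), n = 60
null_config <- function() {
  sim_config(n_per_group_by_sex = matrix(10L, 3L, 2L),
             planted_effects = NULL, clinical_scores = FALSE)
}

expect_symmetric <- function(M, tol = 1e-10) {
  expect_lt(max(abs(M - t(M))), tol)
}
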