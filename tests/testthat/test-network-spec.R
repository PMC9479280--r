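test_that("network fixtures have the frozen region and column counts", {
  fpn <- load_network_spec("FPN")
  dmn <- load_network_spec("DMN")
  expect_length(fpn$regions, 11L)
  expect_length(fpn$columns, 22L)
  expect_length(dmn$regions, 12L)
  expect_length(dmn$columns, 24L)
  expect_false(anyDuplicated(fpn$columns) > 0)
  expect_false(anyDuplicated(dmn$columns) > 0)
  # both hemispheres for every region
  expect_true(all(table(fpn$table$region) == 2L))
  expect_true(all(table(dmn$table$region) == 2L))
  # shared membership: precuneus and angular gyrus belong to both networks
  shared <- intersect(fpn$regions, dmn$regions)
  expect_true(all(c("precuneus", "angular gyrus") %in% shared))
  expect_true(all(c("precuneus_left", "angular_gyrus_right") %in%
                    intersect(fpn$columns, dmn$columns)))
  # pure and total: repeated loads are identical, case-insensitive
  expect_identical(load_network_spec("fpn"), fpn)
  expect_error(load_network_spec("salience"), "unknown network")
})

test_that("cohort reading validates, normalises labels and maps schemas", {
  tmp <- tempfile(fileext = ".csv")
  df <- data.frame(subj = c("a", "b", "c"),
                   iq_group = c("phigh", "Persistent Low", "changer"),
                   sex = c("M", "female", "m"),
                   age = c(3.1, 2.9, 3.5), tbv_cm3 = c(1000, 1100, 980))
  write.csv(df, tmp, row.names = FALSE)
  co <- read_cohort(tmp, schema = c(participant_id = "subj",
                                    group = "iq_group", tbv = "tbv_cm3"),
                    quiet = TRUE)
  expect_s3_class(co, "cohort_table")
  expect_equal(as.character(co$group), c("P-high", "P-low", "changers"))
  expect_equal(as.character(co$sex), c("male", "female", "male"))

  # missing required column is named in the error
  df2 <- df[, setdiff(names(df), "tbv_cm3")]
  write.csv(df2, tmp, row.names = FALSE)
  expect_error(read_cohort(tmp, schema = c(participant_id = "subj",
                                           group = "iq_group",
                                           tbv = "tbv_cm3"), quiet = TRUE),
               "tbv_cm3")
  # non-positive age rejected
  df3 <- df; df3$age[2] <- -1
  write.csv(df3, tmp, row.names = FALSE)
  expect_error(read_cohort(tmp, schema = c(participant_id = "subj",
                                           group = "iq_group",
                                           tbv = "tbv_cm3"), quiet = TRUE),
               "age")
})

test_that("volume reading projects onto the spec and reports missing columns", {
  fpn <- load_network_spec("FPN")
  sim <- simulate_cohort(sim_config(n_per_group_by_sex = matrix(2L, 3, 2),
                                    planted_effects = NULL), seed = 9)
  tmp <- tempfile(fileext = ".csv")
  write_volumes(sim$volumes, tmp)  # union of both networks: extra columns
  vm <- read_volumes(tmp, fpn)
  expect_identical(colnames(vm), fpn$columns)
  expect_identical(rownames(vm), sim$cohort$participant_id)

  # column matching is case/punctuation-insensitive
  vm2 <- sim$volumes[, fpn$columns]
  colnames(vm2) <- gsub("_", " ", toupper(colnames(vm2)))
  write_volumes(vm2, tmp)
  expect_identical(colnames(read_volumes(tmp, fpn)), fpn$columns)

  # a missing spec column is listed by name
  write_volumes(sim$volumes[, setdiff(colnames(sim$volumes),
                                      "angular_gyrus_left")], tmp)
  expect_error(read_volumes(tmp, fpn), "angular_gyrus_left")
})

test_that("write-then-read round trip is bit-identical", {
  fpn <- load_network_spec("FPN")
  sim <- simulate_cohort(sim_config(n_per_group_by_sex = matrix(2L, 3, 2),
                                    planted_effects = NULL), seed = 5)
  tmp <- tempfile(fileext = ".csv")
  write_volumes(sim$volumes, tmp)
  back <- read_volumes(tmp, fpn)
  expect_identical(back, sim$volumes[, fpn$columns])
})
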