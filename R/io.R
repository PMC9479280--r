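#' Read and validate a participant (cohort) table
#'
#' Reads a delimited text file with one row per participant and validates it
#' against the cohort schema used throughout the package: a unique participant
#' id, an IQ-trajectory group (`P-high`, `P-low`, `changers`), sex
#' (`male`/`female`), age in years, total brain volume (TBV) in cm^3, and
#' optional ordinal covariates for family income bracket and parental
#' education. Common label variants (`"phigh"`, `"persistent low"`, `"m"`,
#' `"F"`, ...) are normalised to the canonical levels. A validation report
#' (participant counts per group and sex) is emitted as a message.
#'
#' @param path Path to a CSV/TSV file with a header row. The delimiter is
#'   auto-detected from the header line unless `sep` is given.
#' @param schema Optional named character vector mapping canonical field names
#'   (`participant_id`, `group`, `sex`, `age`, `tbv`, `income_bracket`,
#'   `parental_education`) to the column names used in the file. Fields not
#'   mentioned keep their canonical name.
#' @param sep Field delimiter; `NULL` (default) auto-detects `","` vs `"\t"`.
#' @param quiet Suppress the validation report.
#' @return A data frame of class `cohort_table` with canonical column names,
#'   `group` and `sex` as factors (levels `P-high`, `P-low`, `changers` and
#'   `male`, `female`), and optional `income_bracket` / `parental_education`
#'   factors (with `"missing"` as an explicit level when NAs are present).
#' @export
read_cohort <- function(path, schema = NULL, sep = NULL, quiet = FALSE) {
  raw <- read_delim_auto(path, sep)
  as_cohort_table(raw, schema = schema, quiet = quiet)
}

#' Coerce a data frame to a validated cohort table
#'
#' @param data A data frame holding the cohort fields.
#' @inheritParams read_cohort
#' @return A `cohort_table` data frame; see [read_cohort()].
#' @export
as_cohort_table <- function(data, schema = NULL, quiet = FALSE) {
  canonical <- c("participant_id", "group", "sex", "age", "tbv",
                 "income_bracket", "parental_education")
  required <- canonical[1:5]
  colmap <- stats::setNames(canonical, canonical)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), canonical)
    if (length(bad)) stop("unknown schema fields: ", paste(bad, collapse = ", "))
    colmap[names(schema)] <- unname(schema)
  }
  missing_cols <- colmap[required][!colmap[required] %in% names(data)]
  if (length(missing_cols)) {
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    participant_id = as.character(data[[colmap["participant_id"]]]),
    group = normalize_group(data[[colmap["group"]]]),
    sex = normalize_sex(data[[colmap["sex"]]]),
    age = as.numeric(data[[colmap["age"]]]),
    tbv = as.numeric(data[[colmap["tbv"]]]),
    stringsAsFactors = FALSE
  )
  for (opt in c("income_bracket", "parental_education")) {
    if (colmap[opt] %in% names(data)) {
      v <- factor(as.character(data[[colmap[opt]]]))
      if (anyNA(v)) {
        v <- addNA(v)
        levels(v)[is.na(levels(v))] <- "missing"
      }
      out[[opt]] <- v
    }
  }
  if (anyDuplicated(out$participant_id)) {
    stop("duplicate participant_id: ",
         paste(unique(out$participant_id[duplicated(out$participant_id)]),
               collapse = ", "))
  }
  if (anyNA(out$group)) stop("missing or unrecognised group label(s) in row(s): ",
                             paste(which(is.na(out$group)), collapse = ", "))
  if (anyNA(out$sex)) stop("missing or unrecognised sex label(s) in row(s): ",
                           paste(which(is.na(out$sex)), collapse = ", "))
  if (anyNA(out$age) || any(out$age <= 0)) stop("age must be strictly positive")
  if (anyNA(out$tbv) || any(out$tbv <= 0)) stop("tbv (cm^3) must be strictly positive")
  class(out) <- c("cohort_table", "data.frame")
  if (!quiet) {
    tab <- table(out$group, out$sex)
    message(sprintf("cohort: %d participants (%s)", nrow(out),
                    paste(sprintf("%s %d/%d", rownames(tab), tab[, "male"],
                                  tab[, "female"]), collapse = "; ")),
            " [counts are male/female]")
  }
  out
}

group_levels <- function() c("P-high", "P-low", "changers")

normalize_group <- function(x) {
  key <- gsub("[^a-z]", "", tolower(as.character(x)))
  lookup <- c(
    phigh = "P-high", persistenthigh = "P-high", persistentlyhigh = "P-high",
    high = "P-high",
    plow = "P-low", persistentlow = "P-low", persistentlylow = "P-low",
    low = "P-low",
    changers = "changers", changer = "changers", change = "changers"
  )
  factor(unname(lookup[key]), levels = group_levels())
}

normalize_sex <- function(x) {
  key <- gsub("[^a-z]", "", tolower(as.character(x)))
  lookup <- c(m = "male", male = "male", f = "female", female = "female")
  factor(unname(lookup[key]), levels = c("male", "female"))
}

#' Read a regional-volume matrix for one network
#'
#' Reads a delimited file with one row per participant and one column per
#' region-by-hemisphere ROI volume (mm^3), restricts it to the columns of a
#' [network_spec][load_network_spec] (in spec order), and validates it.
#' File column names are matched to spec column identifiers
#' case-insensitively with all punctuation/whitespace treated as `"_"`,
#' so `"Angular Gyrus left"` resolves to `angular_gyrus_left`.
#' Rows with any missing ROI value are rejected with an error listing the
#' offending participants (no imputation, no silent dropping).
#'
#' @inheritParams read_cohort
#' @param spec A `network_spec` from [load_network_spec()].
#' @param id_column Name of the participant-id column in the file.
#' @return A numeric matrix (participants x ROIs) with participant ids as row
#'   names and spec `column_id`s as column names.
#' @export
read_volumes <- function(path, spec, id_column = "participant_id", sep = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  raw <- read_delim_auto(path, sep)
  if (!id_column %in% names(raw)) {
    stop("volume table is missing the id column '", id_column, "'")
  }
  ids <- as.character(raw[[id_column]])
  if (anyDuplicated(ids)) {
    stop("duplicate participant rows in volume table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  have <- canon_colname(names(raw))
  want <- canon_colname(spec$columns)
  idx <- match(want, have)
  if (anyNA(idx)) {
    stop("volume table cannot be resolved to network ", spec$name,
         "; missing column(s): ",
         paste(spec$columns[is.na(idx)], collapse = ", "))
  }
  mat <- as.matrix(raw[, idx, drop = FALSE])
  storage.mode(mat) <- "double"
  dimnames(mat) <- list(ids, spec$columns)
  if (anyNA(mat)) {
    bad <- ids[apply(mat, 1L, anyNA)]
    stop("missing ROI volume(s) for participant(s): ",
         paste(bad, collapse = ", "),
         "; rows with incomplete data must be removed explicitly")
  }
  if (any(mat < 0)) stop("negative ROI volumes are not allowed")
  mat
}

#' Write a volume matrix or cohort table to CSV at full precision
#'
#' Values are serialised with 17 significant digits so that a write/read
#' round trip reproduces the numeric values bit-identically.
#'
#' @param x A numeric matrix with row names (volumes) or a `cohort_table`.
#' @param path Output file path.
#' @param id_column Name used for the participant-id column when writing a
#'   matrix.
#' @return `path`, invisibly.
#' @export
write_volumes <- function(x, path, id_column = "participant_id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  df <- data.frame(rownames(x), stringsAsFactors = FALSE)
  names(df) <- id_column
  for (j in colnames(x)) df[[j]] <- formatC(x[, j], digits = 17, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_volumes
#' @export
write_cohort <- function(x, path) {
  df <- as.data.frame(x)
  for (j in names(df)) {
    if (is.double(df[[j]])) df[[j]] <- formatC(df[[j]], digits = 17, format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_delim_auto <- function(path, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "", quote = "\"")
}

# align a volume matrix to a cohort table; the join must be exact
align_volumes <- function(volumes, cohort) {
  stopifnot(is.matrix(volumes), inherits(cohort, "data.frame"))
  missing_ids <- setdiff(rownames(volumes), cohort$participant_id)
  if (length(missing_ids)) {
    stop("volume rows without a cohort entry: ",
         paste(missing_ids, collapse = ", "))
  }
  cohort <- cohort[match(rownames(volumes), cohort$participant_id), , drop = FALSE]
  rownames(cohort) <- NULL
  list(volumes = volumes, cohort = cohort)
}
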