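#' Load a brain-network region specification
#'
#' Returns the fixed list of bilateral anatomical regions of interest (ROIs)
#' that make up either the fronto-parietal network (FPN, 11 regions, 22
#' region-by-hemisphere columns) or the default-mode network (DMN, 12 regions,
#' 24 columns). The membership lists are frozen package fixtures derived from
#' an LPBA40-style anatomical parcellation overlaid on canonical
#' intrinsic-connectivity network maps; the precuneus, angular gyrus and the
#' prefrontal segment of the superior frontal gyrus belong to both networks
#' and share column identifiers across the two specs.
#'
#' @param name Network name, `"FPN"` or `"DMN"` (case-insensitive).
#' @return An object of class `network_spec`: a list with elements
#'   `name`, `regions` (character vector of distinct region names),
#'   `table` (data frame with one row per region x hemisphere, columns
#'   `region`, `hemisphere`, `column_id`, `base_prop`), and `columns`
#'   (character vector of the region x hemisphere column identifiers, in
#'   fixture order). `base_prop` is the nominal mean volume of the ROI as a
#'   proportion of total brain volume, used only by the cohort simulator.
#' @examples
#' fpn <- load_network_spec("FPN")
#' length(fpn$regions)   # 11
#' length(fpn$columns)   # 22
#' @export
load_network_spec <- function(name) {
  if (!is.character(name) || length(name) != 1L) {
    stop("'name' must be a single character string")
  }
  name <- toupper(name)
  if (!name %in% c("FPN", "DMN")) {
    stop("unknown network '", name, "'; available networks: FPN, DMN")
  }
  tab <- network_fixture()
  tab <- tab[tab$network == name, c("region", "hemisphere", "column_id", "base_prop")]
  rownames(tab) <- NULL
  structure(
    list(
      name = name,
      regions = unique(tab$region),
      table = tab,
      columns = tab$column_id
    ),
    class = "network_spec"
  )
}

network_fixture <- function() {
  path <- system.file("extdata", "network_regions.csv", package = "mdmrvol",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %s: %d regions x 2 hemispheres (%d columns)\n",
              x$name, length(x$regions), length(x$columns)))
  cat(paste0("  ", x$regions, collapse = "\n"), "\n")
  invisible(x)
}

# canonical form used to match user-supplied column names to spec columns:
# case-insensitive, all non-alphanumeric runs collapsed to "_"
canon_colname <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_|_$", "", x)
}
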