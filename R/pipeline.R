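#' Run the full network-volumetrics analysis from a configuration
#'
#' End-to-end driver covering the canonical workflow: obtain data (either a
#' simulate block or paths to cohort/volume tables), normalize (TBV
#' proportions, T-scores), fit MDMR (omnibus, pairwise group contrasts,
#' sex-by-group interaction), decompose effects per region (jack-knife
#' deltas), ordinate (dbRDA scores, centroids, exact centroid distances),
#' and run univariate post-hoc regressions on the top-ranked regions —
#' separately for each requested network. All outputs are tidy CSV files
#' plus a JSON run manifest recording the seeds, permutation counts, input
#' hashes and package version, so any run can be replayed bit-identically.
#'
#' The YAML configuration has the shape:
#' ```yaml
#' simulate: {seed: 11, planted: default}   # or inputs: {cohort: ..., volumes: ...}
#' analysis:
#'   networks: [FPN, DMN]
#'   model: 1            # 1: age+sex; 2: +income; 3: +education
#'   metric: manhattan
#'   n_perm: 999
#'   K: 200              # jack-knife shuffles per region
#'   seed: 2024
#'   proportion: true    # divide by TBV before T-scoring
#'   top_k: 2            # regions carried to post-hoc regressions
#' ```
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly. On stage failure the run aborts with a
#'   stage-tagged error; partial outputs are retained next to a `.partial`
#'   marker file.
#' @export
run_full_analysis <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg))
  an <- cfg$analysis %||% list()
  networks <- an$networks %||% c("FPN", "DMN")
  model <- an$model %||% 1
  metric <- an$metric %||% "manhattan"
  n_perm <- an$n_perm %||% 999
  K <- an$K %||% 200
  seed <- an$seed %||% 1
  proportion <- an$proportion %||% TRUE
  top_k <- an$top_k %||% 2

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, ".partial")
  file.create(marker)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  input_hashes <- list()
  sim_truth <- NULL
  if (!is.null(cfg$simulate)) {
    dat <- stage("simulate", {
      planted <- cfg$simulate$planted %||% "default"
      pe <- if (identical(planted, "none")) NULL else default_planted_effects()
      simulate_cohort(sim_config(planted_effects = pe),
                      seed = cfg$simulate$seed %||% 1)
    })
    cohort <- dat$cohort
    volumes <- dat$volumes
    sim_truth <- dat$truth
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    write_volumes(volumes, file.path(out_dir, "volumes.csv"))
  } else if (!is.null(cfg$inputs)) {
    cohort <- stage("read_cohort", read_cohort(cfg$inputs$cohort, quiet = TRUE))
    spec_union <- stage("read_volumes", {
      vf <- lapply(networks, function(nw)
        read_volumes(cfg$inputs$volumes, load_network_spec(nw)))
      names(vf) <- networks
      vf
    })
    volumes <- do.call(cbind, unname(spec_union))
    volumes <- volumes[, !duplicated(colnames(volumes)), drop = FALSE]
    input_hashes <- as.list(tools::md5sum(c(cfg$inputs$cohort,
                                            cfg$inputs$volumes)))
  } else {
    stop("config needs either a 'simulate' or an 'inputs' block")
  }

  results <- list()
  for (nw in networks) {
    spec <- load_network_spec(nw)
    missing_cols <- setdiff(spec$columns, colnames(volumes))
    if (length(missing_cols)) {
      stop("stage 'normalize' failed: volume matrix lacks ", nw,
           " column(s): ", paste(missing_cols, collapse = ", "))
    }
    vols <- volumes[, spec$columns, drop = FALSE]
    Y <- stage("normalize", normalize_volumes(vols, cohort,
                                              proportion = proportion))
    pre <- paste0(tolower(nw), "_")
    utils::write.csv(round(Y, 10), file.path(out_dir, paste0(pre, "tscores.csv")))

    D <- stage("distances", pairwise_distances(Y, metric))
    G <- gower_center(D)
    design <- stage("design", build_design(cohort, model = model))

    omni <- stage("mdmr", mdmr_fit(G, design, terms = c("group", "sex"),
                                   n_perm = n_perm, seed = seed))
    utils::write.csv(as.data.frame(omni),
                     file.path(out_dir, paste0(pre, "mdmr_omnibus.csv")),
                     row.names = FALSE)

    pw <- stage("mdmr_pairwise",
                pairwise_group_contrasts(D, cohort, model = model,
                                         n_perm = n_perm, seed = seed + 1))
    utils::write.csv(as.data.frame(pw),
                     file.path(out_dir, paste0(pre, "mdmr_pairwise.csv")),
                     row.names = FALSE)

    ia <- stage("interaction", interaction_test(D, cohort, model = model,
                                                n_perm = n_perm,
                                                seed = seed + 2))
    utils::write.csv(as.data.frame(ia),
                     file.path(out_dir, paste0(pre, "mdmr_interaction.csv")),
                     row.names = FALSE)

    es <- stage("effect_size", {
      tasks <- list(
        list(term = "group", groups = c("P-high", "P-low")),
        list(term = "group", groups = c("P-high", "changers")),
        list(term = "group", groups = c("changers", "P-low")),
        list(term = "sex", groups = NULL)
      )
      do.call(rbind, lapply(seq_along(tasks), function(i) {
        t <- tasks[[i]]
        tab <- jackknife_effect_sizes(Y, cohort, term = t$term,
                                      groups = t$groups, model = model,
                                      metric = metric, K = K,
                                      seed = seed + 10 + i)
        tab$contrast <- attr(tab, "contrast") %||% NA_character_
        tab$contrast[is.na(tab$contrast)] <- "female vs male"
        tab$term <- t$term
        as.data.frame(tab)
      }))
    })
    utils::write.csv(es, file.path(out_dir, paste0(pre, "effect_sizes.csv")),
                     row.names = FALSE)

    ord <- stage("ordination", dbrda_fit(D, cohort, model = model))
    if (ord$status == "ok") {
      utils::write.csv(ord$scores,
                       file.path(out_dir, paste0(pre, "ordination_scores.csv")))
      cent <- cbind(as.data.frame(ord$centroids),
                    stats::setNames(as.data.frame(ord$centroid_se),
                                    paste0("se_", colnames(ord$centroids))))
      utils::write.csv(cent,
                       file.path(out_dir, paste0(pre, "ordination_centroids.csv")))
      utils::write.csv(ord$centroid_distances$distance,
                       file.path(out_dir, paste0(pre, "centroid_distances.csv")))
    }

    ph <- stage("posthoc", {
      do.call(rbind, lapply(split(es, es$contrast), function(tab) {
        cls <- structure(tab[order(-tab$delta, tab$column_id), ],
                         class = c("effect_size_table", "data.frame"))
        top <- utils::head(cls$column_id, top_k)
        if (tab$term[1L] == "sex") {
          univariate_regression(Y, cohort, columns = top, term = "sex")
        } else {
          pairlv <- strsplit(tab$contrast[1L], " vs ", fixed = TRUE)[[1L]]
          univariate_regression(Y, cohort, columns = top,
                                contrast = c(pairlv[2L], pairlv[1L]))
        }
      }))
    })
    utils::write.csv(ph, file.path(out_dir, paste0(pre, "posthoc.csv")),
                     row.names = FALSE)

    results[[nw]] <- list(omnibus = omni, pairwise = pw, interaction = ia)
  }

  manifest <- list(
    package = "mdmrvol",
    version = as.character(utils::packageVersion("mdmrvol")),
    config = cfg,
    networks = networks, model = model, metric = metric,
    n_perm = n_perm, K = K, seed = seed,
    tscore_convention = "mean 50, SD 10, sample (n-1) SD",
    permutation_scheme = "freedman_lane",
    input_hashes = input_hashes,
    simulated = !is.null(sim_truth)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(sim_truth)) {
    jsonlite::write_json(sim_truth[c("planted_effects", "roi_correlation",
                                     "noise_sd", "roi_cv", "seed")],
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
  }
  unlink(marker)
  invisible(out_dir)
}
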