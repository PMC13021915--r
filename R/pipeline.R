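#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end run. All randomness flows from
#' the single `seed`.
#'
#' @param seed Integer seed for the whole run.
#' @param design A [cohort_design()] for the simulation stage.
#' @param control,onj [cohort_params()] for the two arms.
#' @param transform A [transform_params()].
#' @param rules A `gating_rules` tibble.
#' @param threshold_method `"gmm2"` or `"fixed"`.
#' @param fixed_thresholds Named numeric overrides for thresholds.
#' @param radii Interaction radii in micrometres (default c(50, 100)).
#' @param min_count Minimum cells per type per ROI for a valid score.
#' @param interaction_levels Classification levels to score interactions
#'   at.
#' @param diff_levels Classification levels for differential composition.
#' @param functional_markers Markers for positive-fraction differentials.
#' @param alpha BH-adjusted significance level.
#' @param embedding List: `enabled`, `n_neighbors`, `min_dist`,
#'   `max_cells` (cells subsampled for the embedding).
#' @param out_dir Optional output directory for [write_results()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, design = cohort_design(),
                       control = cohort_params("Control"),
                       onj = cohort_params("ONJ"),
                       transform = transform_params(),
                       rules = default_gating_rules(),
                       threshold_method = "gmm2", fixed_thresholds = NULL,
                       radii = c(50, 100), min_count = 10,
                       interaction_levels = c("level1", "level2"),
                       diff_levels = c("level1", "level2", "level4"),
                       functional_markers = c("PD1", "YAP1", "BNIP3", "pNFkB",
                                              "Caveolin", "Ki67", "pERK",
                                              "IntegrinB1", "pSTAT3"),
                       alpha = 0.05,
                       embedding = list(enabled = FALSE, n_neighbors = 30,
                                        min_dist = 0.3, max_cells = 5000),
                       out_dir = NULL) {
  if (any(radii <= 0)) stop("radii must be positive", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  structure(list(
    seed = seed, design = design, control = control, onj = onj,
    transform = transform, rules = rules,
    threshold_method = threshold_method, fixed_thresholds = fixed_thresholds,
    radii = radii, min_count = min_count,
    interaction_levels = interaction_levels, diff_levels = diff_levels,
    functional_markers = functional_markers, alpha = alpha,
    embedding = embedding, out_dir = out_dir
  ), class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages: simulate -> preprocess -> regions -> classify -> spatial ->
#' diffstats (-> embed, optional) -> write. Identical config + seed give
#' identical outputs. Any stage failure aborts with the stage name.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-generated `imc_cohort` (skips the
#'   simulation stage).
#' @return A list of class `imc_run`: `cells` (classified table),
#'   `cohort`, `thresholds`, `scores`, `contrasts`, `diff`, `fractions`,
#'   `embedding`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  timings <- list()
  warnings_log <- character()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log,
                           paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  cohort <- stage("simulate", {
    if (is.null(cohort)) {
      generate_cohort(design = config$design, control = config$control,
                      onj = config$onj, seed = config$seed)
    } else cohort
  })

  cells <- stage("preprocess", preprocess_table(cohort$cells, config$transform))

  cells <- stage("regions", {
    cells <- assign_region(cells, cohort$maps)
    cells$signed_distance <- signed_distance(cells, cohort$maps, "epithelium")
    cells
  })

  thresholds <- stage("thresholds", {
    estimate_thresholds(cells, method = config$threshold_method,
                        fixed = config$fixed_thresholds,
                        seed = config$seed)
  })
  cells <- stage("classify", classify_cells(cells, rules = config$rules,
                                            thresholds = thresholds))

  spatial <- stage("spatial", {
    out <- list()
    for (lev in config$interaction_levels) {
      sc <- interaction_scores(cells, level = lev, radii = config$radii,
                               windows = cohort$maps,
                               min_count = config$min_count)
      agg <- aggregate_to_sample(sc)
      out[[lev]] <- list(scores = sc, sample_u = agg,
                         contrast = contrast_groups(agg, alpha = config$alpha))
    }
    out
  })

  diffs <- stage("diffstats", {
    out <- list()
    for (lev in config$diff_levels) {
      props <- dplyr::bind_rows(
        per_sample_proportions(cells, level = lev, stratum = "all"),
        per_sample_proportions(cells, level = lev, stratum = "region")
      )
      out[[lev]] <- differential_table(props, alpha = config$alpha)
    }
    out
  })
  fractions <- stage("functional", {
    fr <- positive_fraction(cells, config$functional_markers, thresholds,
                            by = "region")
    differential_table(fr, alpha = config$alpha)
  })

  embedding <- NULL
  if (isTRUE(config$embedding$enabled)) {
    embedding <- stage("embed", {
      emb_cells <- cells
      if (nrow(emb_cells) > config$embedding$max_cells) {
        idx <- local_rng(config$seed,
                         sample.int(nrow(emb_cells), config$embedding$max_cells))
        emb_cells <- restore_ct(tibble::as_tibble(emb_cells)[sort(idx), ], cells)
      }
      embed_cells(emb_cells, n_neighbors = config$embedding$n_neighbors,
                  min_dist = config$embedding$min_dist, seed = config$seed)
    })
  }

  manifest <- list(
    package = "tidyimc",
    version = as.character(utils::packageVersion("tidyimc")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_cells = nrow(cells),
    n_rois = length(cohort$maps),
    n_samples = length(unique(cells$sample_id)),
    embedding_params = if (isTRUE(config$embedding$enabled)) {
      config$embedding[c("n_neighbors", "min_dist")]
    } else NULL,
    stages = names(timings),
    timings_sec = timings,
    warnings = warnings_log
  )

  run <- structure(list(cells = cells, cohort = cohort,
                        thresholds = thresholds, spatial = spatial,
                        diff = diffs, fractions = fractions,
                        embedding = embedding, manifest = manifest),
                   class = "imc_run")

  if (!is.null(config$out_dir)) {
    tables <- c(
      list(cells = tibble::as_tibble(cells), thresholds = thresholds),
      stats::setNames(
        lapply(spatial, function(x) x$contrast),
        paste0("interactions_", names(spatial))),
      stats::setNames(lapply(diffs, tibble::as_tibble),
                      paste0("diff_", names(diffs))),
      list(diff_functional = tibble::as_tibble(fractions))
    )
    if (!is.null(embedding)) tables$embedding <- embedding
    run$files <- write_results(tables, config$out_dir, manifest = manifest)
  }
  run
}

#' @export
print.imc_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("# imc_run: %d cells / %d ROIs / %d samples (seed %s)\n",
              m$n_cells, m$n_rois, m$n_samples, format(m$seed)))
  cat("  stages:", paste(m$stages, collapse = " -> "), "\n")
  invisible(x)
}

#' Write result tables and a run manifest
#'
#' One CSV per table plus `manifest.json` recording the config hash,
#' seed, package version and stage timings. Re-running with identical
#' config and seed reproduces the CSVs byte for byte.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param manifest Optional manifest list to serialize alongside.
#' @return Tibble manifest of written files (`name`, `path`, `n_rows`).
#' @export
write_results <- function(tables, out_dir, manifest = NULL) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2) != 0) {
    stop("output directory '", out_dir, "' is not writable", call. = FALSE)
  }
  files <- purrr::imap(tables, function(tb, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(tibble::as_tibble(tb), path, progress = FALSE)
    tibble::tibble(name = name, path = path, n_rows = nrow(tb))
  })
  meta_path <- file.path(out_dir, "manifest.json")
  meta <- manifest %||% list(package = "tidyimc",
                             version = as.character(utils::packageVersion("tidyimc")))
  meta$files <- names(tables)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  dplyr::bind_rows(files) |>
    dplyr::bind_rows(tibble::tibble(name = "manifest", path = meta_path,
                                    n_rows = NA_integer_))
}

#' UMAP embedding of cells by marker expression
#'
#' Two-dimensional UMAP of arcsinh-transformed lineage + functional
#' intensities (defaults n_neighbors = 30, min_dist = 0.3), run
#' single-threaded under a fixed seed for reproducibility.
#'
#' @param cells An arcsinh-transformed `cell_table`.
#' @param n_neighbors,min_dist UMAP parameters.
#' @param seed RNG seed.
#' @param markers Markers to embed on (default lineage + functional).
#' @return A tibble `cell_id`, `umap1`, `umap2`.
#' @export
embed_cells <- function(cells, n_neighbors = 30, min_dist = 0.3, seed = 1,
                        markers = NULL) {
  if (!requireNamespace("uwot", quietly = TRUE)) {
    stop("embed_cells() requires the 'uwot' package", call. = FALSE)
  }
  if (ct_state(cells) != "arcsinh") {
    stop("embedding expects arcsinh-transformed intensities", call. = FALSE)
  }
  if (nrow(cells) < n_neighbors) {
    stop("need at least n_neighbors = ", n_neighbors, " cells", call. = FALSE)
  }
  panel <- ct_panel(cells)
  if (is.null(markers)) markers <- marker_names(panel, c("lineage", "functional"))
  mat <- intensity_matrix(cells, markers)
  coords <- local_rng(seed, {
    uwot::umap(mat, n_neighbors = n_neighbors, min_dist = min_dist,
               n_threads = 1, n_sgd_threads = 1, batch = TRUE)
  })
  tibble::tibble(cell_id = cells$cell_id,
                 umap1 = coords[, 1], umap2 = coords[, 2])
}
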