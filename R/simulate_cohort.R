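#' Catalogue of simulated cell types
#'
#' One row per true cell type the generator can plant: its level-1 class,
#' level-2 immune subtype (if any), marker signature, and how its cells
#' are spread over tissue regions. Signatures follow the marker
#' definitions used for jaw-mucosa IMC: epithelial cells E-cadherin/EGFR,
#' blood endothelium CD31/CD146/CD140b, lymphatic endothelium Podoplanin,
#' fibroblasts Collagen-1/CD90/aSMA, and immune subtypes gated from their
#' lineage markers (M2 macrophages CD68/CD163/Arginase1, Tregs CD4/FoxP3,
#' exhausted T cells CD8/PD1, ...).
#'
#' @return A tibble with columns `type`, `level1`, `level2`, `signature`
#'   (list), `region_weights` (list of named numeric).
#' @export
default_cell_types <- function() {
  imm <- c(epithelium = 0.2, stroma = 0.7, vessel = 0.1)
  tibble::tribble(
    ~type,            ~level1,        ~level2,       ~signature,                          ~region_weights,
    "epithelial",     "epithelial",   NA_character_, c("Ecad", "EGFR"),                   c(epithelium = 1),
    "fibroblast",     "fibroblast",   NA_character_, c("Collagen1", "CD90", "aSMA",
                                                       "Vimentin", "FSP1"),               c(stroma = 1),
    "endo_blood",     "endothelial",  NA_character_, c("CD31", "CD146", "CD140b"),        c(vessel = 0.8, stroma = 0.2),
    "endo_lymph",     "endothelial",  NA_character_, c("Podoplanin"),                     c(vessel = 0.5, stroma = 0.5),
    "B",              "immune",       "B",           c("CD20", "HLADR", "CD38"),          imm,
    "CD4T",           "immune",       "CD4 T",       c("CD4", "CD27"),                    imm,
    "CD8T",           "immune",       "CD8 T",       c("CD8", "CD27"),                    imm,
    "BnT",            "immune",       "BnT",         c("CD20", "CD4", "CD27"),            imm,
    "Treg",           "immune",       "Treg",        c("CD4", "FoxP3", "CD27"),           imm,
    "macrophage",     "immune",       "macrophage",  c("CD68", "HLADR", "CD15",
                                                       "CD11c"),                          imm,
    "M2",             "immune",       "M2",          c("CD68", "CD163", "Arginase1",
                                                       "HLADR", "CD11c"),                 imm,
    "NK",             "immune",       "NK",          c("CD56"),                           imm,
    "exhaustedT",     "immune",       "exhausted T", c("CD8", "PD1", "CD27"),             imm,
    "DC",             "immune",       "DC",          c("CD11c", "HLADR"),                 imm,
    "functional",     "functional",   NA_character_, c("Ki67"),                           c(epithelium = 0.4, stroma = 0.6),
    "unclassified",   "unclassified", NA_character_, character(0),                        c(epithelium = 0.3, stroma = 0.55, vessel = 0.15)
  )
}

#' Planted group parameters for a synthetic cohort
#'
#' The per-group study conditions the generator plants: overall cell-type
#' proportions, per-type spatial modes, and functional-marker positivity
#' rates. The `"ONJ"` set carries the planted disease effects —
#' composition (Treg 0.02 -> 0.06, exhausted T 0.015 -> 0.03, B cells
#' 0.005 -> 0.02, epithelial 0.30 -> 0.24), spatial mode switches (Treg
#' and exhausted T cells CSR -> Thomas self-clustering), and raised
#' functional positivity (e.g. Ki67/BNIP3/Caveolin in epithelium, pNFkB
#' in fibroblasts and endothelium). The `"Control"` set is the baseline.
#' Planted unclassified filler is 4% in both groups.
#'
#' @param group `"Control"` or `"ONJ"` (a null cohort is obtained by
#'   passing the Control set as the ONJ arm of [generate_cohort()]).
#' @return A list of class `cohort_params` with elements `proportions`
#'   (named, sums to 1), `modes` (named list of [spatial_mode()]),
#'   `functional_rates` (tibble `type`, `marker`, `rate`).
#' @export
cohort_params <- function(group = c("Control", "ONJ")) {
  group <- match.arg(group)
  props <- c(
    epithelial = 0.30, fibroblast = 0.250, endo_blood = 0.06, endo_lymph = 0.02,
    macrophage = 0.05, M2 = 0.03, CD4T = 0.06, CD8T = 0.05, B = 0.008,
    BnT = 0.015, NK = 0.02, Treg = 0.02, exhaustedT = 0.015, DC = 0.012,
    functional = 0.05, unclassified = 0.04
  )
  modes <- stats::setNames(
    replicate(length(props), spatial_mode("csr"), simplify = FALSE),
    names(props)
  )
  base_rates <- tibble::tribble(
    ~marker,      ~rate,
    "Ki67",        0.08,
    "pERK",        0.05,
    "BNIP3",       0.03,
    "Caveolin",    0.04,
    "pNFkB",       0.04,
    "IntegrinB1",  0.05,
    "pSTAT3",      0.04,
    "YAP1",        0.05
  )
  types <- setdiff(names(props), c("unclassified", "functional"))
  rates <- tidyr::crossing(type = types, base_rates)
  rate_set <- function(rates, type, marker, value) {
    hit <- rates$type == type & rates$marker == marker
    rates$rate[hit] <- value
    rates
  }
  rates <- rate_set(rates, "epithelial", "YAP1", 0.35)
  rates <- rate_set(rates, "epithelial", "Ki67", 0.12)
  # Tregs express PD1 at a baseline rate; the Treg gate outranks the
  # exhausted-T gate, so this does not move labels
  rates <- dplyr::bind_rows(rates,
                            tibble::tibble(type = "Treg", marker = "PD1",
                                           rate = 0.25))
  if (group == "ONJ") {
    props["Treg"] <- 0.06
    props["exhaustedT"] <- 0.03
    props["B"] <- 0.02
    props["epithelial"] <- 0.24
    props["fibroblast"] <- 0.243
    modes$Treg <- spatial_mode("thomas", mu = 20, sigma = 15)
    modes$exhaustedT <- spatial_mode("thomas", mu = 20, sigma = 15)
    rates <- rate_set(rates, "epithelial", "Ki67", 0.25)
    rates <- rate_set(rates, "epithelial", "pERK", 0.15)
    rates <- rate_set(rates, "epithelial", "BNIP3", 0.12)
    rates <- rate_set(rates, "epithelial", "Caveolin", 0.10)
    rates <- rate_set(rates, "epithelial", "pSTAT3", 0.10)
    rates <- rate_set(rates, "epithelial", "IntegrinB1", 0.12)
    rates <- rate_set(rates, "epithelial", "YAP1", 0.55)
    rates <- rate_set(rates, "fibroblast", "pNFkB", 0.15)
    rates <- rate_set(rates, "endo_blood", "pNFkB", 0.12)
    rates <- rate_set(rates, "endo_blood", "BNIP3", 0.10)
  }
  stopifnot(abs(sum(props) - 1) < 1e-12)
  structure(list(group = group, proportions = props, modes = modes,
                 functional_rates = rates), class = "cohort_params")
}

#' Synthetic cohort design
#'
#' Cohort shape and imaging geometry: 8 Control and 6 ONJ individuals with
#' 2-5 regions of interest (ROIs) each, 1000 x 1000 um windows at
#' 1 um/pixel, and an overall cell density of 0.0025 cells per square
#' micrometre (2500 cells per ROI). `sample_sd` is the between-individual
#' log-scale variability applied to cell-type proportions (biological
#' replicate noise).
#'
#' @param n_control,n_onj Individuals per group.
#' @param rois Length-2 integer range of ROIs per individual.
#' @param width,height,pixel_size ROI window geometry in micrometres.
#' @param total_density Overall expected cells per square micrometre.
#' @param sample_sd Between-sample lognormal sd on type proportions.
#' @param band_depth,n_vessels,vessel_radius Region-map layout parameters
#'   passed to [generate_region_map()].
#' @param co_expression Named per-region probability that an immune cell
#'   co-expresses the region's lineage marker (epithelium -> Ecad,
#'   vessel -> CD31, stroma -> Collagen1), feeding level-3 infiltration
#'   phenotypes.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_control = 8, n_onj = 6, rois = c(2, 5),
                          width = 1000, height = 1000, pixel_size = 1,
                          total_density = 0.0025, sample_sd = 0.3,
                          band_depth = 200, n_vessels = 4,
                          vessel_radius = c(20, 40),
                          co_expression = c(epithelium = 0.3, vessel = 0.3,
                                            stroma = 0.08)) {
  structure(list(
    n_control = n_control, n_onj = n_onj, rois = rois,
    width = width, height = height, pixel_size = pixel_size,
    total_density = total_density, sample_sd = sample_sd,
    band_depth = band_depth, n_vessels = n_vessels,
    vessel_radius = vessel_radius, co_expression = co_expression
  ), class = "cohort_design")
}

# map functional-marker flags to level-4 state flags
default_functional_map <- function() {
  list(
    proliferation = c("Ki67", "pERK"),
    apoptosis = "BNIP3",
    autophagy = "Caveolin",
    "pro-inflammatory" = "pNFkB",
    migration = "IntegrinB1",
    transcriptional = "pSTAT3"
  )
}

# dominant-state reduction for visualization/composition; fixed precedence
dominant_state <- function(state_flags) {
  order <- c("proliferation", "apoptosis", "autophagy", "pro-inflammatory",
             "migration", "transcriptional")
  out <- rep("non-functional", nrow(state_flags))
  for (s in rev(intersect(order, colnames(state_flags)))) {
    out[state_flags[, s]] <- s
  }
  out
}

state_flags_from_markers <- function(flags, fmap = default_functional_map()) {
  out <- matrix(FALSE, nrow = nrow(flags), ncol = length(fmap),
                dimnames = list(NULL, names(fmap)))
  for (s in names(fmap)) {
    ms <- intersect(fmap[[s]], colnames(flags))
    if (length(ms) > 0) out[, s] <- rowSums(flags[, ms, drop = FALSE]) > 0
  }
  out
}

#' Generate a synthetic IMC cohort with planted ground truth
#'
#' Draws a full cohort — region rasters, cell positions, raw marker
#' intensities — under per-group planted parameters, and records every
#' planted value in a truth table for recovery testing. Per individual,
#' type proportions are jittered on the log scale (`sample_sd`) and
#' renormalized, modelling biological replicate variation; ROIs within an
#' individual share the individual's proportions (technical replicates).
#'
#' @param design A [cohort_design()].
#' @param control,onj [cohort_params()] for the two arms. Passing the
#'   Control set as `onj` yields a null cohort.
#' @param model An [intensity_model()].
#' @param panel A [marker_panel()].
#' @param types Cell-type catalogue, see [default_cell_types()].
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of it.
#' @return A list of class `imc_cohort`: `cells` (raw `cell_table`),
#'   `maps` (named list of `region_map`, one per sample/ROI, names
#'   `<sample>_<roi>`), `truth` (per-cell true labels + per-cell planted
#'   type), `planted` (per-group planted proportions, modes and rates),
#'   `design`, `seed`.
#' @export
generate_cohort <- function(design = cohort_design(),
                            control = cohort_params("Control"),
                            onj = cohort_params("ONJ"),
                            model = intensity_model(),
                            panel = default_marker_panel(),
                            types = default_cell_types(),
                            seed = 1) {
  for (p in list(control, onj)) {
    undeclared <- setdiff(
      unique(c(names(p$proportions), names(p$modes), p$functional_rates$type)),
      types$type
    )
    if (length(undeclared) > 0) {
      stop("planted effect references undeclared type(s): ",
           paste(undeclared, collapse = ", "), call. = FALSE)
    }
  }
  signatures <- stats::setNames(types$signature, types$type)
  samples <- tibble::tibble(
    sample_id = c(paste0("C", seq_len(design$n_control)),
                  paste0("P", seq_len(design$n_onj))),
    group = rep(c("Control", "ONJ"), c(design$n_control, design$n_onj))
  )
  local_rng(seed, {
    maps <- list()
    all_cells <- list()
    for (s in seq_len(nrow(samples))) {
      pars <- if (samples$group[s] == "Control") control else onj
      props <- pars$proportions[types$type]
      props[is.na(props)] <- 0
      names(props) <- types$type
      jit <- props * exp(stats::rnorm(length(props), 0, design$sample_sd))
      jit <- jit / sum(jit)
      n_roi <- sample(seq(design$rois[1], design$rois[2]), 1L)
      for (r in seq_len(n_roi)) {
        rm_ <- generate_region_map(
          width = design$width, height = design$height,
          pixel_size = design$pixel_size, band_depth = design$band_depth,
          n_vessels = design$n_vessels, vessel_radius = design$vessel_radius
        )
        areas <- region_areas(rm_)
        n_total <- design$total_density * design$width * design$height
        spec_rows <- purrr::map(seq_len(nrow(types)), function(k) {
          ty <- types$type[k]
          w <- types$region_weights[[k]]
          w <- w[names(w) %in% names(areas) & areas[names(w)] > 0]
          if (length(w) == 0 || jit[[ty]] == 0) return(NULL)
          w <- w / sum(w)
          tibble::tibble(
            type = ty, region = names(w),
            density = jit[[ty]] * n_total * as.numeric(w) / areas[names(w)],
            mode = list(pars$modes[[ty]] %||% spatial_mode("csr"))
          )
        })
        placed <- place_cells(rm_, dplyr::bind_rows(spec_rows))
        roi_id <- paste0("ROI", r)
        key <- paste0(samples$sample_id[s], "_", roi_id)
        maps[[key]] <- rm_
        if (nrow(placed) > 0) {
          placed$sample_id <- samples$sample_id[s]
          placed$roi_id <- roi_id
          placed$group <- samples$group[s]
          all_cells[[key]] <- placed
        }
      }
    }
    cells <- dplyr::bind_rows(all_cells)
    cells$cell_id <- sprintf("%s_%s_c%05d", cells$sample_id, cells$roi_id,
                             stats::ave(seq_len(nrow(cells)),
                                        paste(cells$sample_id, cells$roi_id),
                                        FUN = seq_along))

    # per-group functional rates -> flags, drawn group by group
    flags <- matrix(FALSE, nrow = nrow(cells), ncol = nrow(panel),
                    dimnames = list(NULL, panel$name))
    for (g in c("Control", "ONJ")) {
      rows <- which(cells$group == g)
      if (length(rows) == 0) next
      pars <- if (g == "Control") control else onj
      flags[rows, ] <- positivity_flags(cells[rows, , drop = FALSE],
                                        signatures, panel,
                                        rates = pars$functional_rates)
    }

    # level-3 infiltration: immune cells may co-express the lineage marker
    # of the region they sit in
    co <- design$co_expression
    co_marker <- c(epithelium = "Ecad", vessel = "CD31", stroma = "Collagen1")
    level1_of <- stats::setNames(types$level1, types$type)
    imm_rows <- which(level1_of[cells$type] == "immune")
    co_flag <- rep(NA_character_, nrow(cells))
    for (reg in names(co_marker)) {
      rows <- imm_rows[cells$region[imm_rows] == reg]
      if (length(rows) == 0 || is.na(co[reg]) || co[reg] <= 0) next
      hit <- rows[stats::runif(length(rows)) < co[reg]]
      flags[hit, co_marker[[reg]]] <- TRUE
      co_flag[hit] <- co_marker[[reg]]
    }

    table <- draw_intensities(cells, flags, model, panel)

    level2_of <- stats::setNames(types$level2, types$type)
    sflags <- state_flags_from_markers(flags)
    co_level3 <- dplyr::case_when(
      !(seq_len(nrow(cells)) %in% imm_rows) ~ NA_character_,
      co_flag == "Ecad" ~ "immune-in-epithelial",
      co_flag == "CD31" ~ "immune-in-endothelial",
      co_flag == "Collagen1" ~ "immune-in-fibroblast",
      TRUE ~ "immune"
    )
    truth <- tibble::tibble(
      cell_id = cells$cell_id, sample_id = cells$sample_id,
      roi_id = cells$roi_id, group = cells$group,
      true_type = cells$type, true_region = cells$region,
      true_level1 = unname(level1_of[cells$type]),
      true_level2 = unname(level2_of[cells$type]),
      true_level3 = co_level3,
      true_level4 = dominant_state(sflags)
    )
    planted <- list(
      proportions = list(Control = control$proportions, ONJ = onj$proportions),
      modes = list(Control = control$modes, ONJ = onj$modes),
      functional_rates = list(Control = control$functional_rates,
                              ONJ = onj$functional_rates)
    )
    structure(list(cells = table, maps = maps, truth = truth,
                   planted = planted, design = design, seed = seed),
              class = "imc_cohort")
  })
}

#' @export
print.imc_cohort <- function(x, ...) {
  cat(sprintf("# imc_cohort: %d cells, %d ROIs, %d samples (seed %s)\n",
              nrow(x$cells), length(x$maps),
              length(unique(x$truth$sample_id)), format(x$seed)))
  invisible(x)
}
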