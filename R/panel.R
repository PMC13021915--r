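#' Construct a marker panel
#'
#' A marker panel describes the antibody channels measured per cell: the
#' marker name, its role in the analysis, and the cellular compartment the
#' signal is read from. Lineage markers drive cell-type gating, functional
#' markers drive functional-state calls, and dna/segmentation channels are
#' carried as opaque metadata.
#'
#' @param name Character vector of unique marker names.
#' @param role One of `"lineage"`, `"functional"`, `"segmentation"`, `"dna"`
#'   per marker (recycled if length 1).
#' @param compartment `"whole-cell"` or `"nuclear"` per marker. Nuclear
#'   markers are quantified from the nuclear channel (column `nuc_<marker>`
#'   in a cell table) when one is present.
#'
#' @return A tibble of class `marker_panel` with columns `name`, `role`,
#'   `compartment`.
#' @examples
#' marker_panel(c("Ecad", "Ki67"), role = c("lineage", "functional"))
#' @export
marker_panel <- function(name, role, compartment = "whole-cell") {
  panel <- tibble::tibble(
    name = as.character(name),
    role = vctrs_recycle(as.character(role), length(name), "role"),
    compartment = vctrs_recycle(as.character(compartment), length(name), "compartment")
  )
  validate_marker_panel(panel)
}

vctrs_recycle <- function(x, n, what) {
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n) {
    stop(sprintf("`%s` must have length 1 or %d", what, n), call. = FALSE)
  }
  x
}

validate_marker_panel <- function(panel) {
  roles <- c("lineage", "functional", "segmentation", "dna")
  comps <- c("whole-cell", "nuclear")
  if (anyDuplicated(panel$name)) {
    stop("marker names must be unique", call. = FALSE)
  }
  if (!all(panel$role %in% roles)) {
    stop("marker role must be one of: ", paste(roles, collapse = ", "), call. = FALSE)
  }
  if (!all(panel$compartment %in% comps)) {
    stop("marker compartment must be 'whole-cell' or 'nuclear'", call. = FALSE)
  }
  if (!any(panel$role == "lineage") || !any(panel$role == "functional")) {
    stop("panel needs at least one lineage and one functional marker", call. = FALSE)
  }
  if ("YAP1" %in% panel$name &&
      panel$compartment[panel$name == "YAP1"] != "nuclear") {
    stop("YAP1 must be quantified in the nuclear compartment", call. = FALSE)
  }
  class(panel) <- c("marker_panel", class(tibble::tibble()))
  panel
}

#' Default 38-marker IMC panel
#'
#' A synthetic stand-in for a 38-channel jaw-mucosa IMC panel: epithelial
#' (E-cadherin, EGFR), endothelial (CD31, Podoplanin, CD140b, CD146),
#' fibroblast (Collagen-1, CD90, aSMA, Vimentin, FSP1) and immune lineage
#' markers, nine functional markers (PD1, YAP1, BNIP3, pNFkB, Caveolin,
#' Ki67, pERK, IntegrinB1, pSTAT3; YAP1 scored in the nucleus), two DNA
#' intercalators and three opaque segmentation channels. CD3/CD45 are
#' deliberately absent; immune cells are gated directly from subtype
#' lineage markers.
#'
#' @return A `marker_panel` of 38 markers.
#' @export
default_marker_panel <- function() {
  lineage <- c(
    "Ecad", "EGFR",
    "CD31", "Podoplanin", "CD140b", "CD146",
    "Collagen1", "CD90", "aSMA", "Vimentin", "FSP1",
    "CD20", "CD4", "CD8", "CD68", "CD163", "FoxP3", "CD56",
    "CD11c", "Arginase1", "HLADR", "CD27", "CD38", "CD15"
  )
  functional <- c(
    "PD1", "YAP1", "BNIP3", "pNFkB", "Caveolin",
    "Ki67", "pERK", "IntegrinB1", "pSTAT3"
  )
  marker_panel(
    name = c(lineage, functional, "DNA1", "DNA2",
             "SegMarker1", "SegMarker2", "SegMarker3"),
    role = c(rep("lineage", length(lineage)),
             rep("functional", length(functional)),
             rep("dna", 2L), rep("segmentation", 3L)),
    compartment = ifelse(c(lineage, functional, "DNA1", "DNA2",
                           "SegMarker1", "SegMarker2", "SegMarker3") == "YAP1",
                         "nuclear", "whole-cell")
  )
}

#' Marker names of a panel, optionally filtered by role
#'
#' @param panel A `marker_panel`.
#' @param role Optional role filter.
#' @return Character vector of marker names.
#' @export
marker_names <- function(panel, role = NULL) {
  if (is.null(role)) return(panel$name)
  panel$name[panel$role %in% role]
}

nuclear_markers <- function(panel) {
  panel$name[panel$compartment == "nuclear"]
}
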