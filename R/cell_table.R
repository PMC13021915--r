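#' Construct a cell table
#'
#' A cell table holds one row per segmented cell: identifiers
#' (`cell_id`, `sample_id`, `roi_id`, `group`), centroid coordinates in
#' micrometres (`x`, `y`; per-ROI frame, origin top-left, y downward),
#' one intensity column per panel marker, and optional `nuc_<marker>`
#' columns for nuclear-compartment signal. Downstream stages add `region`,
#' `signed_distance` and `level1`..`level4` label columns.
#'
#' The table tracks its transform state (`raw` -> `winsorized` -> `arcsinh`)
#' so that preprocessing and gating can refuse inputs in the wrong state.
#'
#' @param df A data frame with the mandatory columns and marker columns.
#' @param panel The `marker_panel` the intensity columns are indexed by.
#' @param transform_state One of `"raw"`, `"winsorized"`, `"arcsinh"`.
#' @return A tibble of class `cell_table` carrying `panel` and
#'   `transform_state` attributes.
#' @export
cell_table <- function(df, panel, transform_state = "raw") {
  df <- tibble::as_tibble(df)
  mandatory <- c("cell_id", "sample_id", "roi_id", "group", "x", "y")
  missing_cols <- setdiff(c(mandatory, panel$name), names(df))
  if (length(missing_cols) > 0) {
    stop("cell table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad_group <- setdiff(unique(df$group), c("Control", "ONJ", "Tonsil"))
  if (length(bad_group) > 0) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         " (allowed: Control, ONJ, Tonsil)", call. = FALSE)
  }
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    stop("cell coordinates must be finite", call. = FALSE)
  }
  if (transform_state == "raw") {
    for (m in intersect(c(panel$name, paste0("nuc_", nuclear_markers(panel))),
                        names(df))) {
      bad <- which(df[[m]] < 0)
      if (length(bad) > 0) {
        stop(sprintf("negative raw intensity for marker '%s' at cell_id %s",
                     m, paste(utils::head(df$cell_id[bad], 5), collapse = ", ")),
             call. = FALSE)
      }
    }
  }
  new_cell_table(df, panel, transform_state)
}

# fast-path constructor, no validation
new_cell_table <- function(df, panel, transform_state) {
  stopifnot(transform_state %in% c("raw", "winsorized", "arcsinh"))
  df <- tibble::as_tibble(df)
  attr(df, "panel") <- panel
  attr(df, "transform_state") <- transform_state
  class(df) <- unique(c("cell_table", class(df)))
  df
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("# cell_table: %d cells, %d markers, transform_state = %s\n",
              nrow(x), nrow(ct_panel(x)), ct_state(x)))
  NextMethod()
}

#' Panel and transform state of a cell table
#' @param x A `cell_table`.
#' @return `ct_panel()` returns the `marker_panel`; `ct_state()` the
#'   transform state string.
#' @export
ct_panel <- function(x) {
  p <- attr(x, "panel", exact = TRUE)
  if (is.null(p)) stop("not a cell_table: no panel attribute", call. = FALSE)
  p
}

#' @rdname ct_panel
#' @export
ct_state <- function(x) {
  s <- attr(x, "transform_state", exact = TRUE)
  if (is.null(s)) stop("not a cell_table: no transform_state attribute", call. = FALSE)
  s
}

# carry cell_table attributes through a plain-tibble operation
restore_ct <- function(df, template, transform_state = ct_state(template)) {
  new_cell_table(df, ct_panel(template), transform_state)
}

#' Read a cell table from CSV
#'
#' Expects a comma-separated, "."-decimal, UTF-8 file with a header row
#' containing `cell_id`, `sample_id`, `roi_id`, `group`, `x`, `y` and one
#' column per panel marker. Raw intensities must be non-negative.
#'
#' @param path CSV file path.
#' @param panel The `marker_panel` to index intensity columns by.
#' @param transform_state State to stamp on the table (default `"raw"`;
#'   use `"arcsinh"` when re-reading a transformed export).
#' @return A `cell_table`.
#' @export
read_cell_table <- function(path, panel, transform_state = "raw") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cell_table(df, panel, transform_state)
}

#' Write a cell table to CSV
#'
#' Numeric columns are written with shortest round-trip representation
#' (full double precision), so read/write round-trips are lossless.
#'
#' @param table A `cell_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

# intensity matrix for a marker set, honouring nuclear compartments
intensity_matrix <- function(table, markers = NULL, use_compartment = TRUE) {
  panel <- ct_panel(table)
  if (is.null(markers)) markers <- panel$name
  cols <- vapply(markers, function(m) {
    comp <- panel$compartment[panel$name == m]
    nuc <- paste0("nuc_", m)
    if (use_compartment && length(comp) == 1 && comp == "nuclear") {
      if (nuc %in% names(table)) return(nuc)
      warning(sprintf(
        "nuclear channel '%s' missing; falling back to whole-cell '%s'",
        nuc, m), call. = FALSE)
    }
    m
  }, character(1))
  mat <- as.matrix(tibble::as_tibble(table)[, cols, drop = FALSE])
  colnames(mat) <- markers
  mat
}
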