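# resolve a cells/maps pairing: `maps` is a single region_map applied to
# all cells, or a named list keyed "<sample_id>_<roi_id>"
map_for_roi <- function(maps, sample_id, roi_id) {
  if (inherits(maps, "region_map")) return(maps)
  key <- paste0(sample_id, "_", roi_id)
  m <- maps[[key]]
  if (is.null(m)) stop("no region map for ROI '", key, "'", call. = FALSE)
  m
}

roi_keys <- function(cells) unique(paste0(cells$sample_id, "_", cells$roi_id))

#' Assign each cell to the tissue region containing its centroid
#'
#' Region = legend label of the raster pixel containing the cell centroid;
#' cells on background pixels get region `"none"`.
#'
#' @param cells A `cell_table`.
#' @param maps A `region_map` (single ROI) or a named list of maps keyed
#'   `<sample_id>_<roi_id>`.
#' @return The `cell_table` with a `region` column.
#' @export
assign_region <- function(cells, maps) {
  df <- tibble::as_tibble(cells)
  reg <- rep(NA_character_, nrow(df))
  key <- paste0(df$sample_id, "_", df$roi_id)
  for (k in unique(key)) {
    rows <- which(key == k)
    rm_ <- map_for_roi(maps, df$sample_id[rows[1]], df$roi_id[rows[1]])
    reg[rows] <- lookup_region(rm_, df$x[rows], df$y[rows])
  }
  if (anyNA(reg)) {
    bad <- df$cell_id[is.na(reg)]
    stop("cell centroid(s) outside raster bounds: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "",
         call. = FALSE)
  }
  df$region <- reg
  restore_ct(df, cells)
}

# distance (in raster pixels) from every pixel to the nearest boundary
# pixel of `region`; boundary = region pixels 4-adjacent to a non-region
# pixel (the raster edge counts as non-region)
boundary_distance_map <- function(rm, region) {
  codes <- as.integer(names(rm$legend)[rm$legend == region])
  inside <- matrix(rm$labels %in% codes, nrow = nrow(rm$labels))
  if (!any(inside)) {
    stop("region '", region, "' is absent from the raster", call. = FALSE)
  }
  pad <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow = nrow(m), ncol = ncol(m))
    rs <- seq_len(nrow(m)) + dr
    cs <- seq_len(ncol(m)) + dc
    ok_r <- rs >= 1 & rs <= nrow(m)
    ok_c <- cs >= 1 & cs <= ncol(m)
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  has_outside_nbr <- (!pad(inside, 1L, 0L)) | (!pad(inside, -1L, 0L)) |
    (!pad(inside, 0L, 1L)) | (!pad(inside, 0L, -1L))
  boundary <- inside & has_outside_nbr
  z <- matrix(1L, nrow = nrow(inside), ncol = ncol(inside))
  z[boundary] <- 0L
  d <- EBImage::distmap(z, metric = "euclidean")
  list(dist = as.matrix(d), inside = inside)
}

#' Signed distance from cells to a region boundary
#'
#' Euclidean distance (micrometres) from each cell to the nearest boundary
#' pixel of `target_region`, computed by a distance transform on the
#' raster and read at the cell's pixel. Sign convention: negative inside
#' the region, positive outside (flip with `negative_inside = FALSE`).
#' Agrees with the brute-force minimum over all boundary pixels to within
#' one pixel diagonal.
#'
#' @param cells A `cell_table` (single or multi ROI).
#' @param maps A `region_map` or named list keyed `<sample_id>_<roi_id>`.
#' @param target_region `"epithelium"`, `"stroma"` or `"vessel"`.
#' @param negative_inside Sign convention flag (default TRUE).
#' @return Numeric vector of signed distances, one per cell, in
#'   micrometres.
#' @export
signed_distance <- function(cells, maps, target_region,
                            negative_inside = TRUE) {
  df <- tibble::as_tibble(cells)
  out <- rep(NA_real_, nrow(df))
  key <- paste0(df$sample_id, "_", df$roi_id)
  for (k in unique(key)) {
    rows <- which(key == k)
    rm_ <- map_for_roi(maps, df$sample_id[rows[1]], df$roi_id[rows[1]])
    if (!target_region %in% unname(rm_$legend)) {
      stop("target region '", target_region, "' not in map legend", call. = FALSE)
    }
    bd <- boundary_distance_map(rm_, target_region)
    j <- pmin(pmax(floor(df$x[rows] / rm_$pixel_size) + 1L, 1L), ncol(bd$dist))
    i <- pmin(pmax(floor(df$y[rows] / rm_$pixel_size) + 1L, 1L), nrow(bd$dist))
    d <- bd$dist[cbind(i, j)] * rm_$pixel_size
    sgn <- ifelse(bd$inside[cbind(i, j)], -1, 1)
    if (!negative_inside) sgn <- -sgn
    out[rows] <- sgn * d
  }
  out
}

#' Region-by-label composition of a classified cell table
#'
#' Counts and densities of each classification label within each tissue
#' region. Densities are per square millimetre, using region areas summed
#' over the region maps of the ROIs present in `cells`.
#'
#' @param cells A `cell_table` with a `region` column and the label column
#'   named by `level`.
#' @param maps A `region_map` or named list keyed `<sample_id>_<roi_id>`.
#' @param level Label column to tabulate (default `"level1"`).
#' @return A tibble `region`, `label`, `n`, `area_mm2`, `density_mm2`.
#' @export
region_composition <- function(cells, maps, level = "level1") {
  df <- tibble::as_tibble(cells)
  if (!"region" %in% names(df)) {
    stop("cells must carry a 'region' column; run assign_region() first",
         call. = FALSE)
  }
  if (!level %in% names(df)) {
    stop("label column '", level, "' not found; classify cells first",
         call. = FALSE)
  }
  n_none <- sum(df$region == "none" | is.na(df[[level]]))
  if (n_none > 0) {
    warning(n_none, " cell(s) unassigned (background region or unlabeled); ",
            "excluded from composition", call. = FALSE)
  }
  keep <- df$region != "none" & !is.na(df[[level]])
  counts <- dplyr::count(df[keep, ],
                         region = .data$region, label = .data[[level]])
  areas <- c(epithelium = 0, stroma = 0, vessel = 0)
  for (k in roi_keys(df)) {
    rm_ <- if (inherits(maps, "region_map")) maps else maps[[k]]
    if (is.null(rm_)) stop("no region map for ROI '", k, "'", call. = FALSE)
    a <- region_areas(rm_)
    a <- a[names(a) != "none"]
    areas[names(a)] <- areas[names(a)] + a
  }
  counts$area_mm2 <- unname(areas[counts$region]) / 1e6
  counts$density_mm2 <- counts$n / counts$area_mm2
  counts
}
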