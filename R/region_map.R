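#' Construct a region map
#'
#' A region map is an integer label raster with a physical pixel size and a
#' legend mapping nonzero labels to the three tissue regions (epithelium,
#' stroma, vessel). Label 0 is background. The raster is stored as a matrix
#' with rows indexing y (downward) and columns indexing x, matching the
#' cell-table coordinate frame: pixel `[i, j]` covers
#' x in `[(j-1), j) * pixel_size`, y in `[(i-1), i) * pixel_size`.
#'
#' @param labels Integer matrix of region labels.
#' @param pixel_size Pixel edge length in micrometres (> 0).
#' @param legend Named character vector mapping label integers (names) to
#'   region names.
#' @return An object of class `region_map`.
#' @export
region_map <- function(labels, pixel_size,
                       legend = c("1" = "epithelium", "2" = "stroma", "3" = "vessel")) {
  if (!is.matrix(labels)) stop("labels must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop("pixel_size must be a single positive number (um/pixel)", call. = FALSE)
  }
  present <- setdiff(sort(unique(as.integer(labels))), 0L)
  unknown <- setdiff(as.character(present), names(legend))
  if (length(unknown) > 0) {
    stop("raster label(s) without legend entry: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad_region <- setdiff(unname(legend), c("epithelium", "stroma", "vessel"))
  if (length(bad_region) > 0) {
    stop("legend region(s) not recognised: ", paste(bad_region, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(labels = labels, pixel_size = pixel_size, legend = legend),
    class = "region_map"
  )
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("# region_map: %d x %d px @ %g um/px; regions: %s\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size,
              paste(unique(unname(x$legend)), collapse = ", ")))
  invisible(x)
}

#' Physical dimensions and region areas of a region map
#'
#' @param rm A `region_map`.
#' @return `map_window()` returns `c(width, height)` in micrometres;
#'   `region_areas()` a named numeric vector of region areas in square
#'   micrometres (including `"none"` for background).
#' @export
map_window <- function(rm) {
  c(width = ncol(rm$labels) * rm$pixel_size,
    height = nrow(rm$labels) * rm$pixel_size)
}

#' @rdname map_window
#' @export
region_areas <- function(rm) {
  px_area <- rm$pixel_size^2
  counts <- table(factor(as.integer(rm$labels)))
  nm <- ifelse(names(counts) == "0", "none",
               unname(rm$legend[names(counts)]))
  stats::setNames(as.numeric(counts) * px_area, nm)
}

#' Read a region map from a single-channel integer TIFF
#'
#' @param path TIFF file path.
#' @param pixel_size Pixel size in micrometres.
#' @param legend Label legend (default 1 = epithelium, 2 = stroma,
#'   3 = vessel, 0 = background).
#' @return A `region_map`.
#' @export
read_region_map <- function(path, pixel_size,
                            legend = c("1" = "epithelium", "2" = "stroma", "3" = "vessel")) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) != 2) {
    stop("region map TIFF must be single-channel (got ",
         paste(dim(img), collapse = "x"), ")", call. = FALSE)
  }
  region_map(img, pixel_size = pixel_size, legend = legend)
}

#' Write a region map to a single-channel integer TIFF
#'
#' Labels are stored as 8-bit (or 16-bit when any label exceeds 255), so
#' write/read round-trips preserve every pixel exactly.
#'
#' @param rm A `region_map`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_region_map <- function(rm, path) {
  mx <- max(rm$labels)
  bits <- if (mx > 255L) 16L else 8L
  tiff::writeTIFF(rm$labels / (2^bits - 1), path, bits.per.sample = bits)
  invisible(path)
}

# region name at each (x, y) position; "none" on background
lookup_region <- function(rm, x, y) {
  j <- floor(x / rm$pixel_size) + 1L
  i <- floor(y / rm$pixel_size) + 1L
  oob <- j < 1L | j > ncol(rm$labels) | i < 1L | i > nrow(rm$labels)
  lab <- rep(NA_integer_, length(x))
  lab[!oob] <- rm$labels[cbind(i[!oob], j[!oob])]
  out <- rep(NA_character_, length(x))
  out[!oob] <- ifelse(lab[!oob] == 0L, "none",
                      unname(rm$legend[as.character(lab[!oob])]))
  out
}
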