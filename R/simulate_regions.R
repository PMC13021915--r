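# deterministic RNG scope: run expr under a seed, restore global RNG state
local_rng <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic tissue region map
#'
#' Emulates the anatomy of an oral-mucosa IMC section: a connected
#' epithelial band along the top edge with a gently undulating
#' epithelial-stromal junction, stroma below, and circular vessel
#' cross-sections placed inside the stroma (optionally one inside the
#' epithelium). Pixel labels: 1 = epithelium, 2 = stroma, 3 = vessel.
#'
#' @param width,height Window size in micrometres (each >= 200).
#' @param pixel_size Pixel edge in micrometres (default 1).
#' @param band_depth Mean epithelial band depth in micrometres.
#' @param n_vessels Number of vessel disks (0 allowed).
#' @param vessel_radius Length-2 range of vessel radii in micrometres.
#' @param vessel_in_epithelium If `TRUE`, the first vessel is placed inside
#'   the epithelial band.
#' @param wave_amp Relative amplitude of the epithelial junction undulation.
#' @param seed Optional RNG seed; identical seeds give identical rasters.
#' @return A `region_map`.
#' @export
generate_region_map <- function(width = 1000, height = 1000, pixel_size = 1,
                                band_depth = 200, n_vessels = 4,
                                vessel_radius = c(20, 40),
                                vessel_in_epithelium = FALSE,
                                wave_amp = 0.15, seed = NULL) {
  if (width < 200 || height < 200) {
    stop("window must be at least 200 x 200 um", call. = FALSE)
  }
  vessel_radius <- rep(vessel_radius, length.out = 2)
  max_depth <- band_depth * (1 + wave_amp)
  stroma_depth <- height - max_depth
  if (n_vessels > 0 && 2 * max(vessel_radius) >= stroma_depth) {
    stop("vessel radius exceeds stroma depth", call. = FALSE)
  }
  local_rng(seed, {
    nx <- round(width / pixel_size)
    ny <- round(height / pixel_size)
    xc <- (seq_len(nx) - 0.5) * pixel_size
    yc <- (seq_len(ny) - 0.5) * pixel_size
    depth_at <- band_depth * (1 + wave_amp * sin(2 * pi * 3 * xc / width))
    labels <- matrix(2L, nrow = ny, ncol = nx)
    labels[outer(yc, depth_at, `<`)] <- 1L

    if (n_vessels > 0) {
      centers <- matrix(numeric(0), ncol = 3)  # x, y, r
      for (v in seq_len(n_vessels)) {
        in_epi <- vessel_in_epithelium && v == 1L
        placed <- FALSE
        for (try in seq_len(500)) {
          r <- stats::runif(1, vessel_radius[1], vessel_radius[2])
          cx <- stats::runif(1, r + 2 * pixel_size, width - r - 2 * pixel_size)
          if (in_epi) {
            d_here <- band_depth * (1 + wave_amp * sin(2 * pi * 3 * cx / width))
            if (d_here < 2 * (r + 2 * pixel_size)) next
            cy <- stats::runif(1, r + 2 * pixel_size, d_here - r - 2 * pixel_size)
          } else {
            cy <- stats::runif(1, max_depth + r + 2 * pixel_size,
                               height - r - 2 * pixel_size)
          }
          ok <- nrow(centers) == 0 ||
            all(sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2) >
                  centers[, 3] + r + 3 * pixel_size)
          if (ok) {
            centers <- rbind(centers, c(cx, cy, r))
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not place vessel ", v,
               " without overlap; reduce n_vessels or radii", call. = FALSE)
        }
      }
      for (v in seq_len(nrow(centers))) {
        dx2 <- (xc - centers[v, 1])^2
        dy2 <- (yc - centers[v, 2])^2
        inside <- outer(dy2, dx2, `+`) <= centers[v, 3]^2
        labels[inside] <- 3L
      }
    }
    region_map(labels, pixel_size = pixel_size)
  })
}
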