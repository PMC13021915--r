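#' Spatial arrangement mode for a simulated cell type
#'
#' Three second-order behaviours are supported: complete spatial
#' randomness (`csr`), a Thomas cluster process (`thomas`: Poisson parents
#' with Gaussian-dispersed offspring, modelling self-attraction), and
#' sequential hard-core inhibition (`inhibition`: no two cells closer than
#' `r_min`, modelling self-avoidance).
#'
#' @param kind `"csr"`, `"thomas"` or `"inhibition"`.
#' @param mu Mean offspring per parent (thomas).
#' @param sigma Offspring dispersion in micrometres (thomas).
#' @param r_min Hard-core radius in micrometres (inhibition).
#' @return A list of class `spatial_mode`.
#' @export
spatial_mode <- function(kind = c("csr", "thomas", "inhibition"),
                         mu = 20, sigma = 15, r_min = 10) {
  kind <- match.arg(kind)
  if (kind == "thomas" && (mu <= 0 || sigma <= 0)) {
    stop("thomas mode needs mu > 0 and sigma > 0", call. = FALSE)
  }
  if (kind == "inhibition" && r_min <= 0) {
    stop("inhibition mode needs r_min > 0", call. = FALSE)
  }
  structure(list(kind = kind, mu = mu, sigma = sigma, r_min = r_min),
            class = "spatial_mode")
}

# pixel indices (i = row, j = col) of one region of a region_map
region_pixels <- function(rm, region) {
  code <- as.integer(names(rm$legend)[rm$legend == region])
  if (length(code) == 0) return(matrix(integer(0), ncol = 2))
  idx <- if (length(code) == 1L) which(rm$labels == code) else
    which(rm$labels %in% code)
  cbind(((idx - 1L) %% nrow(rm$labels)) + 1L,
        ((idx - 1L) %/% nrow(rm$labels)) + 1L)
}

# n uniform points over the given pixel set (pixel + in-pixel jitter)
sample_in_pixels <- function(px, n, pixel_size) {
  k <- sample.int(nrow(px), n, replace = TRUE)
  cbind(x = (px[k, 2] - 1L + stats::runif(n)) * pixel_size,
        y = (px[k, 1] - 1L + stats::runif(n)) * pixel_size)
}

points_in_region <- function(rm, xy, region) {
  lookup_region(rm, xy[, 1], xy[, 2]) %in% region
}

sample_csr <- function(rm, region, n, px = region_pixels(rm, region)) {
  sample_in_pixels(px, n, rm$pixel_size)
}

# Thomas offspring truncated to the region, thinned to exactly n points;
# uniform thinning of a Thomas process keeps the cluster structure.
sample_thomas <- function(rm, region, n, mu, sigma,
                          px = region_pixels(rm, region)) {
  pts <- matrix(numeric(0), ncol = 2)
  rounds <- 0L
  while (nrow(pts) < n && rounds < 60L) {
    rounds <- rounds + 1L
    n_par <- max(1L, ceiling((n - nrow(pts)) / mu) + 1L)
    parents <- sample_in_pixels(px, n_par, rm$pixel_size)
    n_off <- stats::rpois(n_par, mu)
    if (sum(n_off) == 0) next
    off <- cbind(
      rep(parents[, 1], n_off) + stats::rnorm(sum(n_off), 0, sigma),
      rep(parents[, 2], n_off) + stats::rnorm(sum(n_off), 0, sigma)
    )
    keep <- points_in_region(rm, off, region)
    pts <- rbind(pts, off[keep, , drop = FALSE])
  }
  if (nrow(pts) < n) {
    stop("thomas sampler could not reach the target count; ",
         "check sigma against the region size", call. = FALSE)
  }
  pts[sample.int(nrow(pts), n), , drop = FALSE]
}

# sequential hard-core: accept uniform proposals at least r_min apart
sample_inhibition <- function(rm, region, n, r_min,
                              px = region_pixels(rm, region)) {
  acc <- matrix(NA_real_, nrow = n, ncol = 2)
  n_acc <- 0L
  budget <- 80L * n
  while (n_acc < n && budget > 0L) {
    budget <- budget - 1L
    p <- sample_in_pixels(px, 1L, rm$pixel_size)
    if (n_acc == 0L ||
        min((acc[seq_len(n_acc), 1] - p[1])^2 +
              (acc[seq_len(n_acc), 2] - p[2])^2) >= r_min^2) {
      n_acc <- n_acc + 1L
      acc[n_acc, ] <- p
    }
  }
  if (n_acc < n) {
    warning(sprintf(
      "hard-core packing saturated: placed %d of %d requested points", n_acc, n),
      call. = FALSE)
  }
  acc[seq_len(n_acc), , drop = FALSE]
}

#' Place cells of multiple types in a region map
#'
#' For each row of `types`, a Poisson count with mean
#' `density x region area` is drawn and that many points are laid out in
#' the named region according to the row's `spatial_mode`. Every returned
#' point lies inside its region's pixels.
#'
#' @param region_map A `region_map`.
#' @param types A tibble with columns `type` (label), `region`
#'   (epithelium/stroma/vessel), `density` (cells per square micrometre,
#'   >= 0) and `mode` (list column of `spatial_mode`).
#' @param seed Optional RNG seed.
#' @return A tibble with columns `type`, `region`, `x`, `y` (micrometres).
#' @export
place_cells <- function(region_map, types, seed = NULL) {
  stopifnot(all(c("type", "region", "density", "mode") %in% names(types)))
  if (any(types$density < 0)) stop("densities must be >= 0", call. = FALSE)
  areas <- region_areas(region_map)
  px_cache <- lapply(
    stats::setNames(nm = unique(types$region)),
    function(reg) region_pixels(region_map, reg)
  )
  local_rng(seed, {
    out <- purrr::pmap(types, function(type, region, density, mode, ...) {
      area <- if (region %in% names(areas)) unname(areas[[region]]) else 0
      if (area == 0) {
        if (density > 0) {
          stop(sprintf("region '%s' has zero area but positive density for type '%s'",
                       region, type), call. = FALSE)
        }
        return(NULL)
      }
      n <- stats::rpois(1L, density * area)
      if (n == 0L) return(NULL)
      px <- px_cache[[region]]
      xy <- switch(mode$kind,
        csr = sample_csr(region_map, region, n, px = px),
        thomas = sample_thomas(region_map, region, n, mode$mu, mode$sigma,
                               px = px),
        inhibition = sample_inhibition(region_map, region, n, mode$r_min,
                                       px = px)
      )
      tibble::tibble(type = type, region = region, x = xy[, 1], y = xy[, 2])
    })
    dplyr::bind_rows(out)
  })
}
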