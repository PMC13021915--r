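as_xy <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) >= 2)
    return(unname(p[, 1:2, drop = FALSE]))
  }
  stopifnot(all(c("x", "y") %in% names(p)))
  cbind(p$x, p$y)
}

#' Cross-type Ripley K estimator on a rectangular window
#'
#' `K_ab(r) = |W| / (n_a n_b) * sum_ij e_ij 1[d_ij <= r]`, the expected
#' area per type-b point around a type-a point. With
#' `correction = "translation"` each pair is weighted by
#' `e_ij = |W| / ((w - |dx|)(h - |dy|))`, the reciprocal fraction of the
#' window overlapping its own translate — the closed-form edge correction
#' for rectangles, symmetric in (a, b). With `correction = "none"`,
#' `e_ij = 1`. For a pattern against itself self-pairs are excluded and
#' the denominator is `n (n - 1)`.
#'
#' @param a,b Point patterns: matrices or data frames with `x`, `y`
#'   columns (micrometres, inside the window).
#' @param window `c(width, height)` of the observation rectangle in
#'   micrometres (origin at 0).
#' @param r Radius (or vector of radii) in micrometres, each > 0.
#' @param correction `"translation"` (default) or `"none"`.
#' @param same Treat `a` and `b` as the same pattern. Default `NULL`
#'   auto-detects by coordinate equality.
#' @return Numeric vector of K estimates (square micrometres), one per
#'   radius.
#' @export
cross_k <- function(a, b, window, r, correction = c("translation", "none"),
                    same = NULL) {
  correction <- match.arg(correction)
  A <- as_xy(a); B <- as_xy(b)
  w <- window[1]; h <- window[2]
  if (w <= 0 || h <= 0) stop("window must have positive area", call. = FALSE)
  if (any(r <= 0)) stop("radii must be positive", call. = FALSE)
  if (any(r > min(w, h) / 2)) {
    warning("radius exceeds half the window size; edge correction unreliable",
            call. = FALSE)
  }
  if (is.null(same)) {
    same <- nrow(A) == nrow(B) && isTRUE(all.equal(A, B))
  }
  n_a <- nrow(A); n_b <- nrow(B)
  if (n_a < 1 || n_b < 1) stop("both patterns need at least one point", call. = FALSE)
  area <- w * h
  r2 <- r^2
  acc <- numeric(length(r))
  # chunk over rows of A to bound memory at ~chunk x n_b doubles
  chunk <- max(1L, floor(4e6 / n_b))
  for (start in seq(1L, n_a, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_a)
    dx <- abs(outer(A[idx, 1], B[, 1], `-`))
    dy <- abs(outer(A[idx, 2], B[, 2], `-`))
    d2 <- dx^2 + dy^2
    if (same) {
      d2[cbind(seq_along(idx), idx)] <- Inf  # drop self-pairs i == j
    }
    if (correction == "translation") {
      e <- area / ((w - dx) * (h - dy))
      for (k in seq_along(r)) {
        acc[k] <- acc[k] + sum(e[d2 <= r2[k]])
      }
    } else {
      for (k in seq_along(r)) {
        acc[k] <- acc[k] + sum(d2 <= r2[k])
      }
    }
  }
  denom <- if (same) n_a * (n_a - 1) else n_a * n_b
  area * acc / denom
}

#' Cross-type interaction score u = L(r) - r
#'
#' `u = sqrt(K_ab(r) / pi) - r`: zero in expectation under complete
#' spatial randomness, positive for attraction (clustering of b around
#' a), negative for avoidance. Scores are invalid (u = NA) when either
#' pattern has fewer than `min_count` points.
#'
#' @inheritParams cross_k
#' @param min_count Minimum points per type (default 10).
#' @return A tibble with one row per radius: `radius`, `n_a`, `n_b`, `u`,
#'   `valid`.
#' @export
interaction_score <- function(a, b, window, r = c(50, 100), min_count = 10,
                              correction = "translation", same = NULL) {
  A <- as_xy(a); B <- as_xy(b)
  if (is.null(same)) {
    same <- nrow(A) == nrow(B) && isTRUE(all.equal(A, B))
  }
  n_a <- nrow(A); n_b <- nrow(B)
  valid <- n_a >= min_count && n_b >= min_count
  if (!valid) {
    return(tibble::tibble(radius = r, n_a = n_a, n_b = n_b,
                          u = NA_real_, valid = FALSE))
  }
  k <- cross_k(A, B, window, r, correction = correction, same = same)
  tibble::tibble(radius = r, n_a = n_a, n_b = n_b,
                 u = sqrt(k / pi) - r, valid = TRUE)
}

# label sets for each interaction analysis level
interaction_labels <- function(cells, level) {
  switch(level,
    level1 = setdiff(unique(cells$level1), c("unclassified", NA)),
    level2 = setdiff(unique(cells$level2), c(NA, "immune-other")),
    level4 = setdiff(unique(cells$level4), c("non-functional", NA)),
    stop("unknown interaction level '", level, "'", call. = FALSE)
  )
}

#' Per-ROI interaction scores for all type pairs
#'
#' Computes `interaction_score()` for every unordered pair (including
#' self-pairs) of labels at the chosen classification level, in every
#' ROI, at every radius. `level = "immune_vs_basic"` scores ordered pairs
#' of immune subtypes (level 2) against non-immune basic types (level 1).
#'
#' @param cells A classified `cell_table`.
#' @param level `"level1"`, `"level2"`, `"level4"` or `"immune_vs_basic"`.
#' @param radii Radii in micrometres (default c(50, 100)).
#' @param windows Named list of `c(width, height)` keyed
#'   `<sample_id>_<roi_id>`, a single window recycled for all ROIs, or a
#'   named list of `region_map`s whose windows are used.
#' @param min_count Minimum cells per type per ROI (default 10).
#' @param correction Edge correction for [cross_k()].
#' @return A tibble of class `interaction_scores`: `sample_id`, `roi_id`,
#'   `group`, `type_a`, `type_b`, `radius`, `n_a`, `n_b`, `u`, `valid`.
#' @export
interaction_scores <- function(cells, level = "level1", radii = c(50, 100),
                               windows, min_count = 10,
                               correction = "translation") {
  df <- tibble::as_tibble(cells)
  get_window <- function(key) {
    if (is.numeric(windows)) return(windows)
    wk <- windows[[key]]
    if (is.null(wk)) stop("no window for ROI '", key, "'", call. = FALSE)
    if (inherits(wk, "region_map")) unname(map_window(wk)) else wk
  }
  if (level == "immune_vs_basic") {
    la <- setdiff(unique(df$level2), c(NA, "immune-other"))
    lb <- setdiff(unique(df$level1), c("immune", "unclassified", NA))
    pairs <- tidyr::crossing(type_a = la, type_b = lb)
    col_a <- "level2"; col_b <- "level1"
  } else {
    labs <- sort(interaction_labels(df, level))
    pairs <- tidyr::crossing(type_a = labs, type_b = labs) |>
      dplyr::filter(.data$type_a <= .data$type_b)
    col_a <- col_b <- level
  }
  out <- df |>
    dplyr::group_by(.data$sample_id, .data$roi_id, .data$group) |>
    dplyr::group_map(function(roi, keys) {
      win <- get_window(paste0(keys$sample_id, "_", keys$roi_id))
      res <- purrr::pmap(pairs, function(type_a, type_b) {
        A <- roi[!is.na(roi[[col_a]]) & roi[[col_a]] == type_a, c("x", "y")]
        B <- roi[!is.na(roi[[col_b]]) & roi[[col_b]] == type_b, c("x", "y")]
        same <- col_a == col_b && type_a == type_b
        if (nrow(A) == 0 || nrow(B) == 0) {
          sc <- tibble::tibble(radius = radii, n_a = nrow(A), n_b = nrow(B),
                               u = NA_real_, valid = FALSE)
        } else {
          sc <- interaction_score(A, B, win, r = radii,
                                  min_count = min_count,
                                  correction = correction, same = same)
        }
        sc$type_a <- type_a
        sc$type_b <- type_b
        sc
      })
      dplyr::bind_rows(res) |>
        dplyr::mutate(sample_id = keys$sample_id, roi_id = keys$roi_id,
                      group = keys$group)
    }) |>
    dplyr::bind_rows() |>
    dplyr::select("sample_id", "roi_id", "group", "type_a", "type_b",
                  "radius", "n_a", "n_b", "u", "valid")
  class(out) <- unique(c("interaction_scores", class(out)))
  out
}

#' Aggregate per-ROI interaction scores to biological replicates
#'
#' Technical replicates (ROIs) of a sample are combined into one score
#' per (sample, pair, radius) by a weighted mean of the valid ROI scores
#' with weights `n_a * n_b`. Samples with no valid ROI for a pair are
#' excluded (and reported via a message).
#'
#' @param scores An `interaction_scores` tibble.
#' @return A tibble `sample_id`, `group`, `type_a`, `type_b`, `radius`,
#'   `u`, `weight`.
#' @export
aggregate_to_sample <- function(scores) {
  valid <- dplyr::filter(scores, .data$valid, is.finite(.data$u))
  dropped <- scores |>
    dplyr::distinct(.data$sample_id, .data$type_a, .data$type_b, .data$radius) |>
    dplyr::anti_join(valid, by = c("sample_id", "type_a", "type_b", "radius"))
  if (nrow(dropped) > 0) {
    message(nrow(dropped),
            " sample-pair-radius combination(s) had no valid ROI and were excluded")
  }
  valid |>
    dplyr::group_by(.data$sample_id, .data$group, .data$type_a, .data$type_b,
                    .data$radius) |>
    dplyr::summarise(
      u = stats::weighted.mean(.data$u, .data$n_a * .data$n_b),
      weight = sum(.data$n_a * .data$n_b), .groups = "drop")
}

#' Group contrasts of spatial interaction scores
#'
#' For each (type pair, radius), compares per-sample interaction scores
#' between Control and ONJ with a two-sided Wilcoxon rank-sum test
#' (exact when sample sizes permit and there are no ties), reports
#' `diff = mean(ONJ) - mean(Control)`, and adjusts p-values by
#' Benjamini-Hochberg within each radius. Pairs with fewer than 3 valid
#' samples in either group get `p = NA`.
#'
#' @param sample_u Output of [aggregate_to_sample()].
#' @param alpha Significance level applied to adjusted p-values.
#' @return A tibble of class `interaction_contrast`: `type_a`, `type_b`,
#'   `radius`, `n_control`, `n_onj`, `mean_u_control`, `mean_u_onj`,
#'   `diff`, `p`, `p_adj`, `significant`.
#' @export
contrast_groups <- function(sample_u, alpha = 0.05) {
  res <- sample_u |>
    dplyr::group_by(.data$type_a, .data$type_b, .data$radius) |>
    dplyr::summarise(
      n_control = sum(.data$group == "Control"),
      n_onj = sum(.data$group == "ONJ"),
      mean_u_control = mean(.data$u[.data$group == "Control"]),
      mean_u_onj = mean(.data$u[.data$group == "ONJ"]),
      diff = mean_u_onj - mean_u_control,
      p = if (n_control >= 3 && n_onj >= 3) {
        wilcoxon_rank_sum(.data$u[.data$group == "Control"],
                          .data$u[.data$group == "ONJ"])$p.value
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$radius) |>
    dplyr::mutate(p_adj = bh_adjust(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = !is.na(.data$p_adj) & .data$p_adj < alpha)
  class(res) <- unique(c("interaction_contrast", class(res)))
  attr(res, "alpha") <- alpha
  res
}
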