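#' Intensity transform parameters
#'
#' Defaults follow standard IMC practice: winsorize each marker at the
#' 0.1th and 99.5th empirical percentiles, then apply
#' `asinh(x / cofactor)` with cofactor 5.
#'
#' @param lower_pct,upper_pct Winsorization percentiles (percent,
#'   `0 <= lower_pct < upper_pct <= 100`).
#' @param cofactor arcsinh cofactor (> 0).
#' @return A list of class `transform_params`.
#' @export
transform_params <- function(lower_pct = 0.1, upper_pct = 99.5, cofactor = 5) {
  if (!(lower_pct >= 0 && lower_pct < upper_pct && upper_pct <= 100)) {
    stop("need 0 <= lower_pct < upper_pct <= 100", call. = FALSE)
  }
  if (!(is.numeric(cofactor) && cofactor > 0)) {
    stop("cofactor must be > 0", call. = FALSE)
  }
  structure(list(lower_pct = lower_pct, upper_pct = upper_pct,
                 cofactor = cofactor), class = "transform_params")
}

#' Winsorize a numeric vector at empirical percentiles
#'
#' The empirical quantiles `Q(lower_pct/100)` and `Q(upper_pct/100)` are
#' computed with linear interpolation between order statistics
#' (`stats::quantile` type 7) and then snapped to the nearest attained
#' data values inside the retained range (the smallest observation at or
#' above the lower quantile; the largest at or below the upper). Values
#' outside `[lo, hi]` are clipped to those bounds. Snapping to attained
#' order statistics is what makes the operation exactly idempotent:
#' clipping at interpolated bounds would move the bounds inward again on
#' every re-application. Order-preserving (non-strict).
#'
#' @param x Non-empty numeric vector.
#' @inheritParams transform_params
#' @return Clipped numeric vector of the same length.
#' @export
winsorize <- function(x, lower_pct = 0.1, upper_pct = 99.5) {
  if (length(x) == 0) stop("cannot winsorize an empty vector", call. = FALSE)
  transform_params(lower_pct, upper_pct)  # bounds validation
  q <- stats::quantile(x, probs = c(lower_pct, upper_pct) / 100,
                       names = FALSE, type = 7, na.rm = FALSE)
  lo <- min(x[x >= q[1]])
  hi <- max(x[x <= q[2]])
  pmin(pmax(x, lo), hi)
}

#' arcsinh intensity transform
#'
#' Elementwise `asinh(x / cofactor)`: strictly increasing, odd, and
#' approximately logarithmic for large x — the standard
#' variance-stabilizing transform for cytometry intensities.
#'
#' @param x Numeric vector.
#' @param cofactor Positive cofactor (default 5).
#' @return Transformed vector.
#' @export
arcsinh_transform <- function(x, cofactor = 5) {
  if (!(is.numeric(cofactor) && length(cofactor) == 1 && cofactor > 0)) {
    stop("cofactor must be a single positive number", call. = FALSE)
  }
  asinh(x / cofactor)
}

#' Winsorize and arcsinh-transform a cell table
#'
#' Applies `winsorize()` per marker (quantiles pooled over all cells in the
#' table by default, or computed within each ROI with `pool = "roi"`),
#' then `arcsinh_transform()`. Nuclear channels (`nuc_<marker>`) are
#' transformed identically with their own quantiles. The table must be in
#' `raw` state and comes back in `arcsinh` state.
#'
#' @param table A raw `cell_table`.
#' @param params A `transform_params`.
#' @param pool `"cohort"` (default) pools quantiles over all cells;
#'   `"roi"` computes them within each ROI.
#' @return The transformed `cell_table`.
#' @export
preprocess_table <- function(table, params = transform_params(),
                             pool = c("cohort", "roi")) {
  pool <- match.arg(pool)
  if (ct_state(table) != "raw") {
    stop("preprocess_table() expects a raw table (transform_state = '",
         ct_state(table), "')", call. = FALSE)
  }
  panel <- ct_panel(table)
  cols <- intersect(c(panel$name, paste0("nuc_", nuclear_markers(panel))),
                    names(table))
  df <- tibble::as_tibble(table)
  one_marker <- function(v, roi) {
    if (pool == "cohort") {
      w <- winsorize(v, params$lower_pct, params$upper_pct)
    } else {
      w <- unlist(lapply(split(v, roi), winsorize,
                         lower_pct = params$lower_pct,
                         upper_pct = params$upper_pct), use.names = FALSE)
      w <- w[order(order(roi))]  # restore original row order
    }
    arcsinh_transform(w, params$cofactor)
  }
  roi_key <- paste(df$sample_id, df$roi_id)
  for (m in cols) df[[m]] <- one_marker(df[[m]], roi_key)
  restore_ct(df, table, transform_state = "arcsinh")
}
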