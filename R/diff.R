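#' Per-sample cell-class proportions
#'
#' Aggregates single-cell labels to per-sample (biological replicate)
#' proportions, pooling the ROIs of each sample. The denominator is all
#' cells of the sample within the stratum, including unclassified cells.
#' Labels absent from a sample get proportion 0, so every sample reports
#' the full label set. Samples with zero cells in a stratum are excluded
#' with a message.
#'
#' @param cells A classified `cell_table`.
#' @param level Label column to aggregate (`"level1"`, `"level2"`,
#'   `"level3"`, `"level4"`).
#' @param stratum `"all"` (whole section), one region name, or
#'   `"region"` to stratify by every region.
#' @return A tibble `sample_id`, `group`, `stratum`, `label`, `n_cells`,
#'   `proportion`. Within each sample-stratum the proportions sum to 1.
#' @export
per_sample_proportions <- function(cells, level = "level1", stratum = "all") {
  df <- tibble::as_tibble(cells)
  if (!level %in% names(df)) {
    stop("label column '", level, "' not found; classify cells first",
         call. = FALSE)
  }
  if (stratum == "all") {
    df$stratum <- "all"
  } else if (stratum == "region") {
    if (!"region" %in% names(df)) {
      stop("region column required for region strata", call. = FALSE)
    }
    df$stratum <- df$region
    df <- df[df$stratum != "none", ]
  } else {
    if (!"region" %in% names(df)) {
      stop("region column required for region strata", call. = FALSE)
    }
    df <- df[df$region == stratum, ]
    df$stratum <- stratum
  }
  # denominator: every cell in the stratum; cells without a label at this
  # level (e.g. non-immune cells at level 2) count toward it
  df$label <- dplyr::coalesce(df[[level]], "unlabeled")
  totals <- df |>
    dplyr::count(.data$sample_id, .data$group, .data$stratum, name = "n_total")
  if (nrow(totals) == 0) {
    message("no cells in stratum '", stratum, "'")
    return(tibble::tibble(sample_id = character(), group = character(),
                          stratum = character(), label = character(),
                          n_cells = integer(), proportion = numeric()))
  }
  out <- df |>
    dplyr::count(.data$sample_id, .data$group, .data$stratum, .data$label,
                 name = "n_cells") |>
    tidyr::complete(
      tidyr::nesting(sample_id, group, stratum),
      label = unique(df$label), fill = list(n_cells = 0L)) |>
    dplyr::left_join(totals, by = c("sample_id", "group", "stratum")) |>
    dplyr::mutate(proportion = .data$n_cells / .data$n_total) |>
    dplyr::select(-"n_total")
  out
}

#' Per-sample functional-marker positive fractions
#'
#' Fraction of cells positive for each marker within a stratum (tissue
#' region, level-1 cell type, or the whole section), per sample.
#'
#' @param cells An arcsinh-transformed `cell_table`.
#' @param markers Marker names to score.
#' @param thresholds A `positivity_thresholds` covering `markers`.
#' @param by `"region"`, `"level1"` or `"all"` — what defines the
#'   stratum.
#' @return A tibble `sample_id`, `group`, `stratum`, `marker`, `n_cells`,
#'   `fraction`.
#' @export
positive_fraction <- function(cells, markers, thresholds,
                              by = c("region", "level1", "all")) {
  by <- match.arg(by)
  thr <- thresholds[thresholds$marker %in% markers, ]
  missing <- setdiff(markers, thr$marker)
  if (length(missing) > 0) {
    stop("no threshold for marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pos <- call_positivity(cells, thr)
  df <- tibble::as_tibble(cells)
  df$stratum <- switch(by,
    all = "all",
    region = df$region,
    level1 = df$level1
  )
  if (by == "region") df <- df[df$stratum != "none", ]
  purrr::map(markers, function(m) {
    df$positive <- pos[df$cell_id, m]
    df |>
      dplyr::group_by(.data$sample_id, .data$group, .data$stratum) |>
      dplyr::summarise(marker = m, n_cells = dplyr::n(),
                       fraction = mean(.data$positive), .groups = "drop")
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("sample_id", "group", "stratum", "marker", "n_cells",
                  "fraction")
}

#' Wilcoxon rank-sum test with an exact small-sample path
#'
#' Two-sided by default. Uses the exact null distribution when the
#' combined sample size is at most 14 and there are no ties; otherwise
#' the normal approximation with tie and continuity correction.
#'
#' @param x,y Non-empty numeric vectors.
#' @param alternative Passed to [stats::wilcox.test()].
#' @return A list: `statistic` (W), `p.value`, `exact` (logical path
#'   flag).
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided") {
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 14
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  p <- res$p.value
  # fully tied data degenerates the normal approximation (0/0); there is
  # no evidence against the null, so report 1
  if (is.nan(p)) p <- 1
  list(statistic = unname(res$statistic), p.value = p, exact = exact)
}

#' Welch two-sample t-test (confirmation test)
#'
#' @param x,y Numeric vectors of length >= 2.
#' @return Two-sided Welch p-value. When both groups have zero variance
#'   the test is degenerate: returns 1 for equal means, 0 otherwise, with
#'   a warning.
#' @export
t_test_two_sample <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    warning("zero variance in both groups; degenerate t-test", call. = FALSE)
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, alternative = "two.sided", var.equal = FALSE)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' `p_adj(i) = min_{j >= rank(i)} (m p_(j) / j)`, capped at 1.
#' Order-preserving and never smaller than the input. NAs pass through.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

signif_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "ns.",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns."
  )
}

#' Differential table of per-sample values between groups
#'
#' One row per (stratum, label-or-marker): per-group median and
#' interquartile range, two-sided Wilcoxon rank-sum p (primary),
#' Welch t-test p (confirmation), BH-adjusted Wilcoxon p (family = all
#' rows within a stratum of this table), and significance stars derived
#' from the adjusted p (`***` < 0.001, `**` < 0.01, `*` < 0.05, `ns.`).
#' Comparisons with fewer than 3 samples in either group are reported
#' with NA p-values.
#'
#' @param values A long tibble from [per_sample_proportions()] or
#'   [positive_fraction()] (or any tibble with `sample_id`, `group`,
#'   `stratum`, a key column and a value column).
#' @param key,value Names of the key (label/marker) and value
#'   (proportion/fraction) columns; auto-detected for the two standard
#'   inputs.
#' @param alpha Unused for stars (fixed thresholds) but recorded.
#' @return A tibble of class `diff_result`.
#' @export
differential_table <- function(values, key = NULL, value = NULL, alpha = 0.05) {
  if (is.null(key)) key <- if ("label" %in% names(values)) "label" else "marker"
  if (is.null(value)) {
    value <- if ("proportion" %in% names(values)) "proportion" else "fraction"
  }
  stopifnot(all(c("sample_id", "group", "stratum", key, value) %in% names(values)))
  res <- values |>
    dplyr::group_by(.data$stratum, key = .data[[key]]) |>
    dplyr::summarise(
      n_control = sum(.data$group == "Control" & !is.na(.data[[value]])),
      n_onj = sum(.data$group == "ONJ" & !is.na(.data[[value]])),
      median_control = stats::median(.data[[value]][.data$group == "Control"],
                                     na.rm = TRUE),
      iqr_control = stats::IQR(.data[[value]][.data$group == "Control"],
                               na.rm = TRUE),
      median_onj = stats::median(.data[[value]][.data$group == "ONJ"],
                                 na.rm = TRUE),
      iqr_onj = stats::IQR(.data[[value]][.data$group == "ONJ"], na.rm = TRUE),
      p_wilcoxon = if (n_control >= 3 && n_onj >= 3) {
        wilcoxon_rank_sum(
          stats::na.omit(.data[[value]][.data$group == "Control"]),
          stats::na.omit(.data[[value]][.data$group == "ONJ"]))$p.value
      } else NA_real_,
      p_ttest = if (n_control >= 3 && n_onj >= 3) {
        t_test_two_sample(
          stats::na.omit(.data[[value]][.data$group == "Control"]),
          stats::na.omit(.data[[value]][.data$group == "ONJ"]))
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(p_adj = bh_adjust(.data$p_wilcoxon)) |>
    dplyr::ungroup() |>
    dplyr::mutate(stars = signif_stars(.data$p_adj))
  names(res)[names(res) == "key"] <- key
  class(res) <- unique(c("diff_result", class(res)))
  attr(res, "alpha") <- alpha
  res
}
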