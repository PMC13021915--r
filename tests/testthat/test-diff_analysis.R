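make_labeled_cohort <- function(seed = 17) {
  co <- generate_cohort(design = small_design(n_control = 3, n_onj = 3),
                        seed = seed)
  cells <- preprocess_table(co$cells)
  cells <- assign_region(cells, co$maps)
  df <- tibble::as_tibble(cells)
  df$level1 <- co$truth$true_level1
  df$level2 <- co$truth$true_level2
  tidyimc:::restore_ct(df, cells)
}

test_that("per-sample proportions are exact fractions that sum to one", {
  cells <- make_labeled_cohort()
  props <- per_sample_proportions(cells, level = "level1", stratum = "all")
  sums <- props |>
    dplyr::summarise(s = sum(proportion), .by = c(sample_id, stratum))
  expect_true(all(abs(sums$s - 1) < 1e-12))
  # group-by / total oracle
  df <- tibble::as_tibble(cells)
  one <- df[df$sample_id == df$sample_id[1], ]
  got <- props[props$sample_id == one$sample_id[1] &
                 props$label == "epithelial", "proportion", drop = TRUE]
  expect_equal(got, mean(one$level1 == "epithelial"))
  # worked example: 50 epithelial of 200 cells -> 0.25
  toy <- tibble::tibble(
    cell_id = as.character(1:200), sample_id = "S", roi_id = "R",
    group = "Control", x = 1, y = 1,
    level1 = rep(c("epithelial", "fibroblast"), c(50, 150)))
  toy <- cell_table(dplyr::mutate(toy, Ecad = 1, Ki67 = 1),
                    marker_panel(c("Ecad", "Ki67"), c("lineage", "functional")))
  p <- per_sample_proportions(toy, stratum = "all")
  expect_equal(p$proportion[p$label == "epithelial"], 0.25)
})

test_that("region-stratified proportions use the stratum denominator", {
  cells <- make_labeled_cohort()
  props <- per_sample_proportions(cells, level = "level1", stratum = "region")
  sums <- props |>
    dplyr::summarise(s = sum(proportion), .by = c(sample_id, stratum))
  expect_true(all(abs(sums$s - 1) < 1e-12))
  expect_setequal(unique(props$stratum),
                  c("epithelium", "stroma", "vessel"))
})

test_that("positive fractions equal the boolean-mean oracle", {
  cells <- make_labeled_cohort()
  thr <- estimate_thresholds(
    cells, method = "fixed",
    fixed = model_thresholds(intensity_model(), c("Ki67", "pNFkB")))
  fr <- positive_fraction(cells, c("Ki67", "pNFkB"), thr, by = "region")
  pos <- call_positivity(cells, thr)
  df <- tibble::as_tibble(cells)
  one <- fr[1, ]
  rows <- df$sample_id == one$sample_id & df$region == one$stratum
  expect_equal(one$fraction, mean(pos[rows, one$marker]))
  # degenerate fractions
  hi <- estimate_thresholds(cells, method = "fixed", fixed = c(Ki67 = 1e6))
  expect_true(all(positive_fraction(cells, "Ki67", hi, by = "all")$fraction == 0))
  lo <- estimate_thresholds(cells, method = "fixed", fixed = c(Ki67 = -1))
  expect_true(all(positive_fraction(cells, "Ki67", lo, by = "all")$fraction == 1))
})

test_that("wilcoxon exact path matches full enumeration", {
  # worked case: {1,2,3} vs {4,5,6} -> 2/20
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact)
  expect_equal(res$p.value, 0.1)
  expect_equal(res$p.value, enum_wilcoxon_p(c(1, 2, 3), c(4, 5, 6)))
  # identical sets (ties) -> approximation path, p = 1
  tied <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_false(tied$exact)
  expect_equal(tied$p.value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
  # random tie-free datasets, all n, m <= 7
  set.seed(23)
  for (i in 1:60) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    v <- sample(1000, n + m)  # distinct -> tie-free
    x <- v[seq_len(n)]; y <- v[-seq_len(n)]
    expect_equal(wilcoxon_rank_sum(x, y)$p.value, enum_wilcoxon_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("welch t-test matches the closed form and handles degeneracy", {
  x <- c(1.1, 2.3, 3.7, 2.2, 4.1)
  y <- c(5.0, 6.2, 4.8, 7.7)
  t_stat <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  df_w <- (var(x) / length(x) + var(y) / length(y))^2 /
    ((var(x) / length(x))^2 / (length(x) - 1) +
       (var(y) / length(y))^2 / (length(y) - 1))
  expect_equal(t_test_two_sample(x, y), 2 * pt(-abs(t_stat), df_w))
  expect_equal(t_test_two_sample(x, x), 1)
  expect_warning(p0 <- t_test_two_sample(rep(1, 3), rep(2, 3)), "zero variance")
  expect_equal(p0, 0)
  expect_warning(p1 <- t_test_two_sample(rep(1, 3), rep(1, 3)), "zero variance")
  expect_equal(p1, 1)
  # p decreases monotonically with a growing planted shift
  set.seed(5)
  base <- rnorm(8)
  ps <- vapply(c(0.5, 1.5, 3), function(d) t_test_two_sample(base, rnorm(6) + d),
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("BH adjustment matches the hand-applied step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(3:20, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_by_hand(p), tolerance = 1e-12)
    # never decreases any p; order-invariant
    expect_true(all(adj >= p))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
})

test_that("the planted Treg proportion shift is detected with the right sign", {
  design <- cohort_design(n_control = 8, n_onj = 6, rois = c(1, 1),
                          width = 600, height = 600, pixel_size = 2,
                          n_vessels = 2, vessel_radius = c(15, 25))
  hits <- vapply(1:20, function(s) {
    co <- generate_cohort(design = design, seed = 300 + s)
    df <- tibble::as_tibble(co$cells)
    df$level2 <- co$truth$true_level2
    cells <- tidyimc:::restore_ct(df, co$cells)
    props <- per_sample_proportions(cells, level = "level2", stratum = "all")
    dt <- quiet(differential_table(props))
    row <- dt[dt$label == "Treg", ]
    isTRUE(row$p_adj < 0.05 && row$median_onj > row$median_control)
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})

test_that("differential tables report stars consistent with adjusted p", {
  set.seed(41)
  vals <- tidyr::crossing(
    sample_id = c(paste0("C", 1:8), paste0("P", 1:6)),
    label = c("epithelial", "Treg", "NK")) |>
    dplyr::mutate(group = ifelse(grepl("^C", sample_id), "Control", "ONJ"),
                  stratum = "all",
                  proportion = runif(dplyr::n()))
  # plant a fully separated label
  vals$proportion[vals$label == "Treg" & vals$group == "ONJ"] <-
    vals$proportion[vals$label == "Treg" & vals$group == "ONJ"] + 5
  dt <- quiet(differential_table(vals))
  expect_s3_class(dt, "diff_result")
  expect_equal(dt$p_adj, bh_adjust(dt$p_wilcoxon))
  star_oracle <- function(p) {
    if (is.na(p)) "ns." else if (p < 0.001) "***" else if (p < 0.01) "**"
    else if (p < 0.05) "*" else "ns."
  }
  expect_identical(dt$stars, vapply(dt$p_adj, star_oracle, character(1)))
  treg <- dt[dt$label == "Treg", ]
  expect_true(treg$p_adj < 0.05)
  expect_gt(treg$median_onj, treg$median_control)
  # fewer than 3 samples per group -> NA p-values
  small <- quiet(differential_table(vals[vals$sample_id %in%
                                           c("C1", "C2", "P1", "P2", "P3"), ]))
  expect_true(all(is.na(small$p_wilcoxon)))
})
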