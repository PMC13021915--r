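test_that("cross_k reproduces the hand-computed two-point case", {
  A <- cbind(c(400, 410), c(500, 500))  # two points 10 um apart
  k <- cross_k(A, A, window = c(1000, 1000), r = 50, correction = "none")
  # 2 ordered pairs within r, denominator n(n-1) = 2: K = |W| = 1e6
  expect_equal(k, 1e6)
  # no pair within r -> 0
  far <- cbind(c(100, 900), c(100, 900))
  expect_equal(cross_k(far, far, c(1000, 1000), r = 50, correction = "none"), 0)
})

test_that("cross_k equals the brute-force pair oracle on random patterns", {
  set.seed(20)
  for (i in 1:15) {
    n_a <- sample(20:120, 1); n_b <- sample(20:120, 1)
    w <- c(runif(1, 300, 800), runif(1, 300, 800))
    A <- cbind(runif(n_a, 0, w[1]), runif(n_a, 0, w[2]))
    B <- cbind(runif(n_b, 0, w[1]), runif(n_b, 0, w[2]))
    r <- runif(1, 20, min(w) / 2)
    for (corr in c("translation", "none")) {
      got <- cross_k(A, B, w, r, correction = corr)
      want <- bf_cross_k(A, B, w, r, correction = corr)
      expect_equal(got, want, tolerance = 1e-12)
    }
    # same-pattern path excludes self pairs
    got_s <- cross_k(A, A, w, r)
    want_s <- bf_cross_k(A, A, w, r, same = TRUE)
    expect_equal(got_s, want_s, tolerance = 1e-12)
  }
})

test_that("translation-corrected cross_k is symmetric and translation-invariant", {
  set.seed(8)
  A <- cbind(runif(60, 0, 500), runif(60, 0, 500))
  B <- cbind(runif(40, 0, 500), runif(40, 0, 500))
  expect_equal(cross_k(A, B, c(500, 500), 50), cross_k(B, A, c(500, 500), 50))
  # rigid translation of all points leaves u unchanged
  A2 <- cbind(runif(60, 100, 400), runif(60, 100, 400))
  B2 <- cbind(runif(40, 100, 400), runif(40, 100, 400))
  s1 <- interaction_score(A2, B2, c(500, 500), r = 50)
  s2 <- interaction_score(A2 + 60, B2 + 60, c(500, 500), r = 50)
  expect_equal(s1$u, s2$u)
  expect_error(cross_k(A, B, c(500, 500), r = -5), "positive")
  expect_warning(cross_k(A, B, c(500, 500), r = 300), "edge correction")
})

test_that("interaction scores are calibrated: CSR ~ 0, clustering > 0, inhibition < 0", {
  set.seed(99)
  n_sim <- 80
  u_csr <- vapply(seq_len(n_sim), function(i) {
    A <- cbind(runif(300, 0, 1000), runif(300, 0, 1000))
    B <- cbind(runif(300, 0, 1000), runif(300, 0, 1000))
    interaction_score(A, B, c(1000, 1000), r = 50)$u
  }, numeric(1))
  expect_lt(abs(mean(u_csr)), 3 * sd(u_csr) / sqrt(n_sim))

  rm_ <- region_map(matrix(2L, 250, 250), pixel_size = 2)  # 500x500 um
  u_th <- vapply(1:40, function(s) {
    tt <- tibble::tibble(type = "A", region = "stroma", density = 200 / 25e4,
                         mode = list(spatial_mode("thomas", mu = 20, sigma = 15)))
    p <- place_cells(rm_, tt, seed = s)
    interaction_score(cbind(p$x, p$y), cbind(p$x, p$y), c(500, 500), r = 50)$u
  }, numeric(1))
  expect_gt(mean(u_th), 0)

  u_in <- vapply(1:40, function(s) {
    tt <- tibble::tibble(type = "A", region = "stroma", density = 150 / 25e4,
                         mode = list(spatial_mode("inhibition", r_min = 12)))
    p <- place_cells(rm_, tt, seed = s + 99)
    interaction_score(cbind(p$x, p$y), cbind(p$x, p$y), c(500, 500), r = 50)$u
  }, numeric(1))
  expect_lt(mean(u_in), 0)
})

test_that("scores below min_count are invalid, not errors", {
  A <- cbind(runif(5, 0, 100), runif(5, 0, 100))
  B <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  s <- interaction_score(A, B, c(100, 100), r = c(20, 40), min_count = 10)
  expect_false(any(s$valid))
  expect_true(all(is.na(s$u)))
  expect_equal(s$n_a, rep(5, 2))
})

test_that("sample aggregation is the n_a*n_b-weighted mean of valid ROIs", {
  sc <- tibble::tibble(
    sample_id = c("C1", "C1", "C1", "C2"),
    roi_id = c("ROI1", "ROI2", "ROI3", "ROI1"),
    group = "Control", type_a = "A", type_b = "B", radius = 50,
    n_a = c(10, 20, 5, 15), n_b = c(10, 10, 5, 15),
    u = c(1, 4, 99, 7), valid = c(TRUE, TRUE, FALSE, TRUE))
  agg <- aggregate_to_sample(sc)
  # explicit sum(w u) / sum(w) oracle; the invalid ROI is ignored
  expect_equal(agg$u[agg$sample_id == "C1"],
               (100 * 1 + 200 * 4) / 300)
  expect_equal(agg$u[agg$sample_id == "C2"], 7)
  # equal weights reduce to the arithmetic mean
  sc2 <- dplyr::mutate(sc[1:2, ], n_a = 10, n_b = 10)
  expect_equal(aggregate_to_sample(sc2)$u, mean(c(1, 4)))
  # a sample with zero valid ROIs is dropped and logged
  sc3 <- dplyr::mutate(sc, valid = c(FALSE, FALSE, FALSE, TRUE))
  expect_message(agg3 <- aggregate_to_sample(sc3), "no valid ROI")
  expect_identical(agg3$sample_id, "C2")
})

test_that("group contrasts use exact Wilcoxon p-values and BH within radius", {
  mk_u <- function(u_ctrl, u_onj, radius = 50, pair = c("A", "A")) {
    tibble::tibble(
      sample_id = c(paste0("C", seq_along(u_ctrl)), paste0("P", seq_along(u_onj))),
      group = rep(c("Control", "ONJ"), c(length(u_ctrl), length(u_onj))),
      type_a = pair[1], type_b = pair[2], radius = radius,
      u = c(u_ctrl, u_onj), weight = 1)
  }
  # fully separated 8 vs 6: exact two-sided p = 2 / C(14, 6)
  sep <- contrast_groups(mk_u(1:8, 101:106))
  expect_equal(sep$p, 2 / choose(14, 6))
  expect_equal(sep$diff, mean(101:106) - mean(1:8))
  # identical groups (with ties) -> p = 1 on the approximation path
  same <- contrast_groups(mk_u(rep(1, 8), rep(1, 6)))
  expect_equal(same$p, 1)
  # fewer than 3 samples per group -> NA
  small <- contrast_groups(mk_u(1:2, 3:4))
  expect_true(is.na(small$p))
  # BH is applied within radius across pairs
  two <- dplyr::bind_rows(mk_u(1:8, 101:106, pair = c("A", "A")),
                          mk_u(rnorm(8), rnorm(6), pair = c("A", "B")))
  ct <- contrast_groups(two)
  expect_equal(ct$p_adj, bh_adjust(ct$p))
  expect_true(all(ct$p_adj >= ct$p, na.rm = TRUE))
})

test_that("per-ROI interaction tables cover all pairs and levels", {
  co <- generate_cohort(design = small_design(), seed = 55)
  cells <- preprocess_table(co$cells)
  df <- tibble::as_tibble(cells)
  df$level1 <- co$truth$true_level1
  df$level2 <- co$truth$true_level2
  cells <- tidyimc:::restore_ct(df, cells)
  sc <- interaction_scores(cells, level = "level1", radii = c(50, 100),
                           windows = co$maps)
  labs <- setdiff(unique(df$level1), "unclassified")
  n_pairs <- length(labs) * (length(labs) + 1) / 2
  n_rois <- length(unique(paste(df$sample_id, df$roi_id)))
  expect_equal(nrow(sc), n_pairs * n_rois * 2)
  expect_true(all(is.na(sc$u[!sc$valid])))
  ivb <- interaction_scores(cells, level = "immune_vs_basic", radii = 50,
                            windows = co$maps)
  expect_true(all(ivb$type_b %in% c("epithelial", "endothelial",
                                    "fibroblast", "functional")))
})
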