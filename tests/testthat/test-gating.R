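# positivity matrix builder for rule tests
pos_matrix <- function(..., markers = default_marker_panel()$name) {
  rows <- list(...)
  m <- matrix(FALSE, nrow = length(rows), ncol = length(markers),
              dimnames = list(NULL, markers))
  for (i in seq_along(rows)) m[i, rows[[i]]] <- TRUE
  m
}

test_that("gmm2 thresholds recover a planted decision boundary", {
  panel <- tiny_panel()
  set.seed(10)
  # well-separated mixture on the arcsinh scale: means 0.3 / 2.5, sd 0.2
  x <- c(rnorm(4000, 0.3, 0.2), rnorm(1000, 2.5, 0.2))
  mat <- matrix(x, ncol = 1, dimnames = list(NULL, "Ecad"))
  ct <- make_cells(mat, panel, state = "arcsinh")
  thr <- quiet(estimate_thresholds(ct, markers = "Ecad"))
  expect_false(thr$fallback)
  expect_gt(thr$threshold, 1.0)
  expect_lt(thr$threshold, 1.8)
})

test_that("fixed thresholds are returned verbatim and degenerate fits fall back", {
  panel <- tiny_panel()
  set.seed(2)
  mat <- matrix(rnorm(5000, 1, 0.3), ncol = 1, dimnames = list(NULL, "Ecad"))
  ct <- make_cells(mat, panel, state = "arcsinh")
  fx <- estimate_thresholds(ct, method = "fixed", fixed = c(Ecad = 1.5))
  expect_equal(fx$threshold, 1.5)
  expect_identical(fx$method, "fixed")
  # unimodal input triggers the documented 10th/90th-percentile fallback
  expect_message(thr <- estimate_thresholds(ct, markers = "Ecad"),
                 "degenerate mixture")
  expect_true(thr$fallback)
  expect_equal(thr$threshold,
               mean(quantile(mat[, 1], c(0.1, 0.9), names = FALSE)),
               tolerance = 1e-6)
  expect_error(estimate_thresholds(ct[1:50, ], markers = "Ecad"),
               "at least 200")
})

test_that("positivity calls use strict thresholds and the right compartment", {
  panel <- tiny_panel()
  mat <- matrix(c(1.0, 1.5, 0), ncol = 1, dimnames = list(NULL, "Ecad"))
  ct <- make_cells(mat, panel, state = "arcsinh")
  thr <- estimate_thresholds(ct, method = "fixed", fixed = c(Ecad = 1.0))
  pos <- call_positivity(ct, thr)
  # exactly at threshold -> negative (strict >); all-zero cell negative
  expect_identical(unname(pos[, "Ecad"]), c(FALSE, TRUE, FALSE))
  # elementwise oracle on random data
  set.seed(6)
  mat2 <- matrix(runif(300 * 2, 0, 3), 300,
                 dimnames = list(NULL, c("Ecad", "Ki67")))
  ct2 <- make_cells(mat2, panel, state = "arcsinh")
  thr2 <- estimate_thresholds(ct2, method = "fixed",
                              fixed = c(Ecad = 1.2, Ki67 = 0.7))
  pos2 <- call_positivity(ct2, thr2)
  expect_identical(unname(pos2),
                   unname(cbind(mat2[, "Ecad"] > 1.2, mat2[, "Ki67"] > 0.7)))

  # nuclear marker reads the nuclear channel...
  nuc <- matrix(2, 1, 1, dimnames = list(NULL, "YAP1"))
  ct3 <- make_cells(matrix(0, 1, 1, dimnames = list(NULL, "YAP1")),
                    panel, state = "arcsinh", nuc = nuc)
  thr3 <- estimate_thresholds(ct3, method = "fixed", fixed = c(YAP1 = 1))
  expect_true(call_positivity(ct3, thr3)[, "YAP1"])
  # ...and falls back to whole-cell with a warning when it is missing
  ct4 <- make_cells(matrix(2, 1, 1, dimnames = list(NULL, "YAP1")),
                    panel, state = "arcsinh")
  expect_warning(p4 <- call_positivity(ct4, thr3), "falling back to whole-cell")
  expect_true(p4[, "YAP1"])
})

test_that("level-1 rules gate the five basic types with priority", {
  pos <- pos_matrix(
    c("Ecad", "EGFR"),                 # epithelial
    "Podoplanin",                      # endothelial
    character(0),                      # unclassified
    c("CD68", "Ecad"),                 # immune beats epithelial
    "Ki67",                            # functional only
    c("Collagen1", "Ki67")             # fibroblast beats functional
  )
  l1 <- classify_level1(pos)
  expect_identical(l1, c("epithelial", "endothelial", "unclassified",
                         "immune", "functional", "fibroblast"))
  expect_error(classify_level1(pos, rules = dplyr::filter(
    default_gating_rules(), level == 2)), "no level-1 rules")
})

test_that("level-2 subtypes resolve by specificity among immune cells", {
  pos <- pos_matrix(
    c("CD68", "CD163"),        # M2 beats macrophage
    c("CD4", "FoxP3"),         # Treg beats CD4 T
    c("CD4", "PD1"),           # exhausted T
    c("CD20", "CD4"),          # BnT beats B and CD4 T
    "CD56",                    # NK
    "CD4",                     # CD4 T
    "Ecad"                     # not immune: no level-2 label
  )
  l1 <- classify_level1(pos)
  l2 <- classify_level2(pos, l1)
  expect_identical(l2, c("M2", "Treg", "exhausted T", "BnT", "NK", "CD4 T", NA))
})

test_that("level-3 infiltration phenotypes follow co-expression precedence", {
  pos <- pos_matrix(
    c("CD4", "Ecad"),               # immune-in-epithelial
    c("CD4", "CD31"),               # immune-in-endothelial
    c("CD4", "Collagen1"),          # immune-in-fibroblast
    c("CD4", "Ecad", "CD31"),       # epithelial wins over endothelial
    "CD4",                          # plain immune
    "Ecad"                          # non-immune: NA
  )
  l1 <- classify_level1(pos)
  l3 <- classify_level3(pos, l1)
  expect_identical(l3, c("immune-in-epithelial", "immune-in-endothelial",
                         "immune-in-fibroblast", "immune-in-epithelial",
                         "immune", NA))
  # counts equal the brute-force boolean-conjunction oracle
  set.seed(13)
  rpos <- matrix(runif(200 * 38) < 0.1, 200,
                 dimnames = list(NULL, default_marker_panel()$name))
  rl1 <- classify_level1(rpos)
  rl3 <- classify_level3(rpos, rl1)
  imm <- rl1 == "immune"
  oracle_epi <- imm & (rpos[, "Ecad"] | rpos[, "EGFR"])
  expect_equal(sum(rl3 == "immune-in-epithelial", na.rm = TRUE),
               sum(oracle_epi))
})

test_that("level-4 states are non-exclusive flags with a dominant reduction", {
  pos <- pos_matrix(
    "Ki67",                         # proliferation
    c("BNIP3", "Caveolin"),         # apoptosis + autophagy
    character(0)                    # non-functional
  )
  l4 <- classify_level4(pos)
  expect_true(l4$flags[1, "proliferation"])
  expect_identical(sum(l4$flags[1, ]), 1L)
  expect_true(all(l4$flags[2, c("apoptosis", "autophagy")]))
  expect_identical(l4$dominant,
                   c("proliferation", "apoptosis", "non-functional"))
})

test_that("classification is deterministic and order-invariant", {
  co <- generate_cohort(design = small_design(), seed = 3)
  cells <- preprocess_table(co$cells)
  thr <- estimate_thresholds(
    cells, method = "fixed",
    fixed = model_thresholds(intensity_model(),
                             marker_names(ct_panel(cells),
                                          c("lineage", "functional"))))
  a <- quiet(classify_cells(cells, thresholds = thr))
  b <- quiet(classify_cells(cells, thresholds = thr))
  expect_identical(a$level1, b$level1)
  perm <- sample(nrow(cells))
  cp <- tidyimc:::restore_ct(tibble::as_tibble(cells)[perm, ], cells)
  c2 <- quiet(classify_cells(cp, thresholds = thr))
  expect_identical(c2$level1, a$level1[perm])
  expect_identical(c2$level2, a$level2[perm])
})
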