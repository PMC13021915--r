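test_that("region map generator plants the requested anatomy", {
  rm_ <- generate_region_map(1000, 1000, 1, band_depth = 200, n_vessels = 3,
                             vessel_radius = c(40, 40), seed = 5)
  labs <- sort(unique(as.integer(rm_$labels)))
  expect_setequal(labs, 1:3)
  # vessel disks are disjoint by construction: count connected components
  comp <- EBImage::bwlabel(rm_$labels == 3L)
  expect_equal(max(comp), 3)
  # epithelial band is connected and touches the top edge
  epi <- EBImage::bwlabel(rm_$labels == 1L)
  expect_equal(max(epi), 1)
  expect_true(all(rm_$labels[1, ] == 1L))

  rm0 <- generate_region_map(600, 600, 1, n_vessels = 0, seed = 1)
  expect_setequal(sort(unique(as.integer(rm0$labels))), 1:2)

  expect_identical(generate_region_map(400, 400, 1, n_vessels = 2, seed = 9)$labels,
                   generate_region_map(400, 400, 1, n_vessels = 2, seed = 9)$labels)
  expect_error(generate_region_map(150, 400, 1), "at least 200")
  expect_error(generate_region_map(300, 300, 1, band_depth = 180,
                                   vessel_radius = c(60, 60)),
               "vessel radius")
})

test_that("place_cells respects regions, densities and spatial modes", {
  rm_ <- region_map(matrix(2L, 300, 300), pixel_size = 1)  # pure stroma
  csr <- tibble::tibble(type = "A", region = "stroma", density = 100 / 9e4,
                        mode = list(spatial_mode("csr")))
  # Poisson mean: average count over seeds within 3 standard errors
  counts <- vapply(1:100, function(s) nrow(place_cells(rm_, csr, seed = s)),
                   numeric(1))
  lambda <- 100
  se <- sqrt(lambda / 100)
  expect_lt(abs(mean(counts) - lambda), 3 * se)

  # all points inside their region
  rm_mixed <- generate_region_map(400, 400, 1, n_vessels = 2,
                                  vessel_radius = c(20, 25), seed = 3)
  types <- tibble::tibble(
    type = c("A", "B"), region = c("epithelium", "vessel"),
    density = c(5e-4, 1e-3),
    mode = list(spatial_mode("csr"), spatial_mode("csr")))
  pts <- place_cells(rm_mixed, types, seed = 4)
  looked <- tidyimc:::lookup_region(rm_mixed, pts$x, pts$y)
  expect_identical(looked, pts$region)

  # zero density places nothing; zero-area region errors
  none <- tibble::tibble(type = "A", region = "stroma", density = 0,
                         mode = list(spatial_mode("csr")))
  expect_equal(nrow(place_cells(rm_, none, seed = 1)), 0)
  bad <- tibble::tibble(type = "A", region = "vessel", density = 1e-3,
                        mode = list(spatial_mode("csr")))
  expect_error(place_cells(rm_, bad, seed = 1), "zero area")
})

test_that("thomas clustering shrinks nearest-neighbour distances vs CSR", {
  rm_ <- region_map(matrix(2L, 400, 400), pixel_size = 1)
  mean_nn <- function(mode, seed) {
    tt <- tibble::tibble(type = "A", region = "stroma",
                         density = 200 / 16e4, mode = list(mode))
    pts <- place_cells(rm_, tt, seed = seed)
    if (nrow(pts) < 10) return(NA_real_)
    d <- as.matrix(stats::dist(cbind(pts$x, pts$y)))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  nn_csr <- vapply(1:60, function(s) mean_nn(spatial_mode("csr"), s), numeric(1))
  nn_th <- vapply(1:60, function(s)
    mean_nn(spatial_mode("thomas", mu = 20, sigma = 15), s + 500), numeric(1))
  expect_lt(mean(nn_th, na.rm = TRUE), mean(nn_csr, na.rm = TRUE))
})

test_that("hard-core inhibition enforces the minimum spacing", {
  rm_ <- region_map(matrix(2L, 400, 400), pixel_size = 1)
  tt <- tibble::tibble(type = "A", region = "stroma", density = 150 / 16e4,
                       mode = list(spatial_mode("inhibition", r_min = 10)))
  pts <- place_cells(rm_, tt, seed = 8)
  d <- stats::dist(cbind(pts$x, pts$y))
  expect_gte(min(d), 10)
})

test_that("intensity draws follow the two-population lognormal model", {
  panel <- tiny_panel()
  model <- intensity_model(pos_meanlog = 3, pos_sdlog = 0.4)
  cells <- tibble::tibble(
    cell_id = sprintf("c%05d", 1:10000), sample_id = "S1", roi_id = "ROI1",
    group = "Control", x = 1, y = 1,
    type = "epi")
  sig <- list(epi = c("Ecad", "EGFR"))
  flags <- positivity_flags(cells, sig, panel, seed = 2)
  tab <- draw_intensities(cells, flags, model, panel, seed = 3)
  # closed-form lognormal mean exp(m + s^2/2), 10k draws within 1%
  expect_lt(abs(mean(tab$Ecad) / exp(3 + 0.4^2 / 2) - 1), 0.01)
  # negative population for a marker outside the signature
  expect_lt(mean(tab$CD31), exp(0 + 0.35^2 / 2) * 1.05)
  # degenerate model: positive fraction 1 with zero log-sd is constant
  nf <- noise_free_model(pos_meanlog = 3)
  tabc <- draw_intensities(cells[1:50, ], flags[1:50, , drop = FALSE], nf,
                           panel, seed = 4)
  expect_true(all(tabc$Ecad == exp(3)))
  # nuclear channel populated for YAP1
  expect_true("nuc_YAP1" %in% names(tab))
  # unknown type errors
  expect_error(positivity_flags(dplyr::mutate(cells[1, ], type = "mystery"),
                                sig, panel),
               "without an intensity signature")
})

test_that("cohort generation is deterministic and honours null effects", {
  d <- small_design()
  co1 <- generate_cohort(design = d, seed = 77)
  co2 <- generate_cohort(design = d, seed = 77)
  expect_identical(tibble::as_tibble(co1$cells), tibble::as_tibble(co2$cells))
  expect_identical(co1$maps[[1]]$labels, co2$maps[[1]]$labels)
  expect_identical(co1$truth, co2$truth)

  # null cohort: both arms drawn from identical parameters
  null_co <- generate_cohort(design = d, onj = cohort_params("Control"),
                             seed = 5)
  expect_identical(null_co$planted$proportions$Control,
                   null_co$planted$proportions$ONJ)

  # effects on undeclared types are refused
  bad <- cohort_params("ONJ")
  bad$proportions <- c(bad$proportions, martian = 0.01)
  expect_error(generate_cohort(design = d, onj = bad, seed = 1),
               "undeclared type")
})

test_that("planted group proportions are recovered in expectation", {
  d <- small_design(n_control = 3, n_onj = 3)
  treg_prop <- function(co, grp) {
    tr <- co$truth[co$truth$group == grp, ]
    props <- tapply(tr$true_type == "Treg", tr$sample_id, mean)
    mean(props)
  }
  props <- vapply(1:10, function(s) {
    co <- generate_cohort(design = d, seed = s)
    c(treg_prop(co, "Control"), treg_prop(co, "ONJ"))
  }, numeric(2))
  # planted 0.02 vs 0.06; sample jitter (sd 0.3 log-scale) inflates the SE
  expect_lt(abs(mean(props[1, ]) - 0.02), 3 * stats::sd(props[1, ]) / sqrt(10) + 0.002)
  expect_lt(abs(mean(props[2, ]) - 0.06), 3 * stats::sd(props[2, ]) / sqrt(10) + 0.006)
  expect_gt(mean(props[2, ]), mean(props[1, ]))
})

test_that("every generated cell lies inside its recorded region", {
  co <- generate_cohort(design = small_design(), seed = 12)
  cells <- assign_region(co$cells, co$maps)
  expect_identical(cells$region, co$truth$true_region)
})
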