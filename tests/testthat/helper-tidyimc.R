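# shared fixtures and independent oracles, all built in code

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_panel <- function() {
  nm <- c("Ecad", "EGFR", "CD31", "Podoplanin", "CD4", "FoxP3",
          "Ki67", "YAP1", "DNA1")
  marker_panel(
    name = nm,
    role = c(rep("lineage", 6), "functional", "functional", "dna"),
    compartment = ifelse(nm == "YAP1", "nuclear", "whole-cell")
  )
}

# wrap a marker intensity matrix into a minimal cell table
make_cells <- function(mat, panel = tiny_panel(), state = "raw",
                       group = "Control", x = NULL, y = NULL,
                       nuc = NULL) {
  n <- nrow(mat)
  df <- tibble::tibble(
    cell_id = sprintf("c%04d", seq_len(n)),
    sample_id = "S1", roi_id = "ROI1", group = group,
    x = x %||% runif(n, 0, 100), y = y %||% runif(n, 0, 100)
  )
  for (m in colnames(mat)) df[[m]] <- unname(mat[, m])
  for (m in setdiff(panel$name, colnames(mat))) df[[m]] <- 0
  if (!is.null(nuc)) for (m in colnames(nuc)) df[[paste0("nuc_", m)]] <- nuc[, m]
  cell_table(df, panel, transform_state = state)
}

# small cohort design used across tests (kept fast)
small_design <- function(n_control = 2, n_onj = 2, ...) {
  cohort_design(n_control = n_control, n_onj = n_onj, rois = c(1, 1),
                width = 600, height = 600, n_vessels = 2,
                vessel_radius = c(15, 25), ...)
}

# O(n_a x n_b) independent cross-K oracle: per-point loop, explicit
# translation weights
bf_cross_k <- function(A, B, window, r, correction = "translation",
                       same = FALSE) {
  w <- window[1]; h <- window[2]
  total <- 0
  for (i in seq_len(nrow(A))) {
    dx <- abs(A[i, 1] - B[, 1])
    dy <- abs(A[i, 2] - B[, 2])
    d <- sqrt(dx^2 + dy^2)
    keep <- d <= r
    if (same) keep[i] <- FALSE
    e <- if (correction == "translation") {
      (w * h) / ((w - dx) * (h - dy))
    } else rep(1, nrow(B))
    total <- total + sum(e[keep])
  }
  denom <- if (same) nrow(A) * (nrow(A) - 1) else nrow(A) * nrow(B)
  (w * h) * total / denom
}

# brute-force signed distance: explicit boundary pixel scan (4-adjacency,
# raster edge counts as outside), exact Euclidean minimum over boundary
# pixel centers
bf_signed_distance <- function(rm, x, y, region) {
  codes <- as.integer(names(rm$legend)[rm$legend == region])
  inside <- matrix(rm$labels %in% codes, nrow = nrow(rm$labels))
  nr <- nrow(inside); nc <- ncol(inside)
  bpix <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!inside[i, j]) next
      nbr_out <- (i == 1) || (i == nr) || (j == 1) || (j == nc) ||
        !inside[i - 1, j] || !inside[i + 1, j] ||
        !inside[i, j - 1] || !inside[i, j + 1]
      if (nbr_out) bpix <- rbind(bpix, c(i, j))
    }
  }
  bx <- (bpix[, 2] - 0.5) * rm$pixel_size
  by <- (bpix[, 1] - 0.5) * rm$pixel_size
  vapply(seq_along(x), function(k) {
    d <- min(sqrt((bx - x[k])^2 + (by - y[k])^2))
    j <- floor(x[k] / rm$pixel_size) + 1
    i <- floor(y[k] / rm$pixel_size) + 1
    if (inside[i, j]) -d else d
  }, numeric(1))
}

# exact two-sided Wilcoxon rank-sum p by full enumeration of group
# assignments (tie-free data)
enum_wilcoxon_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  w_all <- apply(combos, 2, function(idx) sum(ranks[idx]) - n * (n + 1) / 2)
  mu <- n * m / 2
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  min(1, p)
}

# step-up BH applied literally from the definition
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  run <- Inf
  for (i in m:1) {
    run <- min(run, m * sorted[i] / i)
    adj[i] <- min(1, run)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
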