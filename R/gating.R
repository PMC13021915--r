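#' Gating rule set for hierarchical cell classification
#'
#' A rule set is a tibble with one row per rule: `level` (1-4), `label`,
#' `require_positive` / `require_negative` (list columns of marker names),
#' `parent` (level-2 rules must have parent `"immune"`), and `priority`
#' (integer rank, unique within a level; lower rank wins when several
#' rules match a cell).
#'
#' @param level,label,require_positive,require_negative,parent,priority
#'   Rule fields; `require_positive`/`require_negative` are lists of
#'   character vectors.
#' @return A tibble of class `gating_rules`.
#' @export
gating_rules <- function(level, label, require_positive,
                         require_negative = NULL, parent = NA_character_,
                         priority = seq_along(label)) {
  n <- length(label)
  if (is.null(require_negative)) require_negative <- rep(list(character(0)), n)
  rules <- tibble::tibble(
    level = as.integer(level), label = as.character(label),
    require_positive = require_positive, require_negative = require_negative,
    parent = vctrs_recycle(parent, n, "parent"),
    priority = as.integer(priority)
  )
  validate_gating_rules(rules)
}

validate_gating_rules <- function(rules) {
  if (nrow(rules) == 0) stop("empty gating rule set", call. = FALSE)
  dup <- rules |>
    dplyr::count(.data$level, .data$priority) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate priorities within level(s): ",
         paste(unique(dup$level), collapse = ", "), call. = FALSE)
  }
  bad_parent <- rules$level == 2L & !is.na(rules$parent) & rules$parent != "immune"
  if (any(bad_parent | (rules$level == 2L & is.na(rules$parent)))) {
    stop("level-2 rules must declare parent = 'immune'", call. = FALSE)
  }
  class(rules) <- unique(c("gating_rules", class(rules)))
  rules
}

#' Default gating rules
#'
#' Reads the rule file shipped with the package
#' (`inst/extdata/gating_rules.yaml`). Level 1 gates the five basic types
#' with priority immune > endothelial > epithelial > fibroblast >
#' functional; any-of-several-markers gates are expressed as one rule per
#' marker sharing a label. Level 2 resolves immune subtypes with
#' compound gates ranked most-specific-first (Treg before CD4 T, M2
#' before macrophage, BnT before B, ...).
#'
#' @return A `gating_rules` tibble.
#' @export
default_gating_rules <- function() {
  read_gating_rules(system.file("extdata", "gating_rules.yaml",
                                package = "tidyimc", mustWork = TRUE))
}

#' Read / write gating rules as YAML
#'
#' One block per rule with fields `level`, `label`, `require_positive`,
#' `require_negative`, `parent`, `priority`.
#'
#' @param path YAML file path.
#' @return `read_gating_rules()` a `gating_rules` tibble;
#'   `write_gating_rules()` the path, invisibly.
#' @export
read_gating_rules <- function(path) {
  raw <- yaml::read_yaml(path)$rules
  gating_rules(
    level = vapply(raw, function(r) r$level, numeric(1)),
    label = vapply(raw, function(r) r$label, character(1)),
    require_positive = lapply(raw, function(r) as.character(unlist(r$require_positive))),
    require_negative = lapply(raw, function(r) as.character(unlist(r$require_negative))),
    parent = vapply(raw, function(r) r$parent %||% NA_character_, character(1)),
    priority = vapply(raw, function(r) r$priority, numeric(1))
  )
}

#' @rdname read_gating_rules
#' @param rules A `gating_rules` tibble.
#' @export
write_gating_rules <- function(rules, path) {
  blocks <- purrr::pmap(rules, function(level, label, require_positive,
                                        require_negative, parent, priority) {
    b <- list(level = level, label = label,
              require_positive = as.list(require_positive),
              require_negative = as.list(require_negative),
              priority = priority)
    if (!is.na(parent)) b$parent <- parent
    b
  })
  yaml::write_yaml(list(rules = blocks), path)
  invisible(path)
}

#' Estimate per-marker positivity thresholds
#'
#' With `method = "gmm2"`, fits a two-component Gaussian mixture (unequal
#' variances) to each marker's arcsinh intensities and places the
#' threshold at the equal-posterior crossing between the component means.
#' Degenerate fits — component means closer than 0.1 or than twice the
#' geometric-mean component sd (an unimodal distribution split down the
#' middle), or a crossing above which the upper component carries less
#' than 80% of the mass (a tail fitted as a mode) — fall back to the
#' midpoint of the 10th and 90th percentiles,
#' flagged in the output and reported via a message. A small component
#' weight alone does not trigger the fallback: rare cell types produce
#' sparse but well-separated positive modes that the mixture resolves
#' reliably. With `method = "fixed"`, the values
#' in `fixed` are returned verbatim. Values in `fixed` always override the
#' mixture estimate for those markers.
#'
#' @param table An arcsinh-transformed `cell_table` (>= 200 cells for
#'   gmm2).
#' @param method `"gmm2"` or `"fixed"`.
#' @param fixed Named numeric vector of fixed thresholds.
#' @param markers Markers to threshold (default: lineage + functional).
#' @param subsample Cap on cells used per mixture fit (deterministic
#'   subsample; default 5000).
#' @param seed Seed for the subsample.
#' @return A tibble of class `positivity_thresholds`: `marker`,
#'   `threshold`, `method`, `fallback`.
#' @export
estimate_thresholds <- function(table, method = c("gmm2", "fixed"),
                                fixed = NULL, markers = NULL,
                                subsample = 5000, seed = 1) {
  method <- match.arg(method)
  panel <- ct_panel(table)
  if (is.null(markers)) markers <- marker_names(panel, c("lineage", "functional"))
  if (method == "fixed") {
    if (is.null(fixed) || is.null(names(fixed))) {
      stop("method = 'fixed' needs a named `fixed` vector", call. = FALSE)
    }
    markers <- intersect(markers, names(fixed))
    out <- tibble::tibble(marker = markers,
                          threshold = unname(fixed[markers]),
                          method = "fixed", fallback = FALSE)
    class(out) <- unique(c("positivity_thresholds", class(out)))
    return(out)
  }
  if (ct_state(table) != "arcsinh") {
    stop("thresholds are estimated on arcsinh-transformed intensities",
         call. = FALSE)
  }
  if (nrow(table) < 200) {
    stop("gmm2 thresholding needs at least 200 cells", call. = FALSE)
  }
  mat <- intensity_matrix(table, markers)
  out <- purrr::map(markers, function(m) {
    if (!is.null(fixed) && m %in% names(fixed)) {
      return(tibble::tibble(marker = m, threshold = unname(fixed[m]),
                            method = "fixed", fallback = FALSE))
    }
    x <- mat[, m]
    if (length(x) > subsample) {
      x <- local_rng(seed, sample(x, subsample))
    }
    # mclust draws a random initialization subset for large n
    thr <- local_rng(seed, gmm2_threshold(x))
    if (is.na(thr)) {
      thr <- mean(stats::quantile(x, c(0.10, 0.90), names = FALSE, type = 7))
      message("marker ", m,
              ": degenerate mixture, falling back to 10th/90th percentile midpoint")
      return(tibble::tibble(marker = m, threshold = thr,
                            method = "gmm2", fallback = TRUE))
    }
    tibble::tibble(marker = m, threshold = thr, method = "gmm2",
                   fallback = FALSE)
  }) |> dplyr::bind_rows()
  class(out) <- unique(c("positivity_thresholds", class(out)))
  out
}

# equal-posterior crossing of a 2-component unequal-variance GMM;
# NA when the fit is degenerate
gmm2_threshold <- function(x) {
  # mclust resolves helpers via the caller frame, so calls are evaluated
  # inside its namespace rather than attaching the package. The default
  # hierarchical initialization can miss a minority positive mode behind
  # a skewed background, so EM restarts initialized from high-quantile
  # cuts compete with it; the best log-likelihood wins.
  ns <- asNamespace("mclust")
  fits <- list(tryCatch(
    eval(as.call(list(quote(Mclust), data = x, G = 2, modelNames = "V",
                      verbose = FALSE)), envir = ns),
    error = function(e) NULL
  ))
  for (q in c(0.90, 0.98)) {
    cut <- stats::quantile(x, q, names = FALSE)
    if (cut >= max(x)) next
    z0 <- cbind(as.numeric(x <= cut), as.numeric(x > cut))
    fits <- c(fits, list(tryCatch(
      eval(as.call(list(quote(me), modelName = "V", data = x, z = z0)),
           envir = ns),
      error = function(e) NULL
    )))
  }
  fits <- Filter(function(f) !is.null(f) && is.finite(f$loglik %||% NA), fits)
  if (length(fits) == 0) return(NA_real_)
  fit <- fits[[which.max(vapply(fits, function(f) f$loglik, numeric(1)))]]
  p <- fit$parameters
  mu <- as.numeric(p$mean)
  s <- sqrt(as.numeric(p$variance$sigmasq))
  if (length(s) == 1) s <- rep(s, 2)
  w <- as.numeric(p$pro)
  o <- order(mu)
  mu <- mu[o]; s <- s[o]; w <- w[o]
  # degenerate when the components are not separated (unimodal input
  # split down the middle): means closer than 0.1 or than twice the
  # geometric-mean component sd. A small component weight alone is not
  # degeneracy — rare cell types legitimately give sparse but
  # well-separated positive modes.
  if (abs(diff(mu)) < max(0.1, 2 * sqrt(s[1] * s[2]))) {
    return(NA_real_)
  }
  f <- function(t) w[1] * stats::dnorm(t, mu[1], s[1]) -
    w[2] * stats::dnorm(t, mu[2], s[2])
  lo <- mu[1]; hi <- mu[2]
  thr <- if (f(lo) * f(hi) > 0) mean(mu) else stats::uniroot(f, c(lo, hi))$root
  # purity check: above the threshold the upper component must carry at
  # least 80% of the mass, otherwise the "positive mode" is just the tail
  # of an unimodal distribution
  pos_mass <- w[2] * stats::pnorm(thr, mu[2], s[2], lower.tail = FALSE)
  neg_mass <- w[1] * stats::pnorm(thr, mu[1], s[1], lower.tail = FALSE)
  if (pos_mass < 4 * neg_mass) return(NA_real_)
  thr
}

#' Call per-cell marker positivity
#'
#' A cell is positive for a marker iff its compartment-appropriate
#' arcsinh intensity is strictly greater than the marker's threshold
#' (values exactly at threshold are negative). Nuclear-compartment
#' markers are read from `nuc_<marker>`; if that channel is missing the
#' whole-cell channel is used with a warning.
#'
#' @param table An arcsinh-transformed `cell_table`.
#' @param thresholds A `positivity_thresholds` tibble.
#' @return Logical matrix, cells x markers, rownames = `cell_id`.
#' @export
call_positivity <- function(table, thresholds) {
  if (ct_state(table) != "arcsinh") {
    stop("positivity is called on arcsinh-transformed intensities",
         call. = FALSE)
  }
  mat <- intensity_matrix(table, thresholds$marker)
  pos <- sweep(mat, 2, thresholds$threshold, `>`)
  rownames(pos) <- table$cell_id
  pos
}

# rows of `pos` matching a rule (all require_positive TRUE, all
# require_negative FALSE)
rule_matches <- function(pos, require_positive, require_negative) {
  ok <- rep(TRUE, nrow(pos))
  rp <- intersect(require_positive, colnames(pos))
  rn <- intersect(require_negative, colnames(pos))
  if (length(rp) < length(require_positive) ||
      length(rn) < length(require_negative)) {
    stop("gating rule references marker(s) absent from the positivity matrix: ",
         paste(setdiff(c(require_positive, require_negative), colnames(pos)),
               collapse = ", "), call. = FALSE)
  }
  if (length(rp) > 0) {
    ok <- ok & rowSums(pos[, rp, drop = FALSE]) == length(rp)
  }
  if (length(rn) > 0) {
    ok <- ok & rowSums(pos[, rn, drop = FALSE]) == 0
  }
  ok
}

# generic priority-resolved rule application
apply_rules <- function(pos, rules, fallback) {
  rules <- dplyr::arrange(rules, dplyr::desc(.data$priority))
  out <- rep(fallback, nrow(pos))
  for (k in seq_len(nrow(rules))) {  # lowest priority first; best overwrites
    hit <- rule_matches(pos, rules$require_positive[[k]],
                        rules$require_negative[[k]])
    out[hit] <- rules$label[k]
  }
  out
}

#' Level-1 classification into basic cell types
#'
#' Each cell receives the label of the highest-priority level-1 rule whose
#' positivity requirements it meets; cells matching no rule are
#' `"unclassified"`.
#'
#' @param pos Positivity matrix from [call_positivity()].
#' @param rules A `gating_rules` tibble (its level-1 rows are used).
#' @return Character vector of level-1 labels.
#' @export
classify_level1 <- function(pos, rules = default_gating_rules()) {
  r1 <- dplyr::filter(rules, .data$level == 1L)
  if (nrow(r1) == 0) stop("no level-1 rules configured", call. = FALSE)
  apply_rules(pos, r1, fallback = "unclassified")
}

#' Level-2 classification of immune cells into subtypes
#'
#' Only cells with level-1 label `"immune"` receive a subtype; immune
#' cells matching no level-2 rule are `"immune-other"`, non-immune cells
#' get `NA`.
#'
#' @inheritParams classify_level1
#' @param level1 Level-1 labels.
#' @return Character vector of subtypes (NA for non-immune cells).
#' @export
classify_level2 <- function(pos, level1, rules = default_gating_rules()) {
  r2 <- dplyr::filter(rules, .data$level == 2L)
  if (nrow(r2) == 0) stop("no level-2 rules configured", call. = FALSE)
  out <- rep(NA_character_, nrow(pos))
  imm <- which(level1 == "immune")
  if (length(imm) > 0) {
    out[imm] <- apply_rules(pos[imm, , drop = FALSE], r2,
                            fallback = "immune-other")
  }
  out
}

#' Level-3 infiltration phenotype of immune cells
#'
#' Immune cells co-expressing a compartment lineage marker are labelled
#' `immune-in-epithelial` / `immune-in-endothelial` /
#' `immune-in-fibroblast`, with precedence epithelial > endothelial >
#' fibroblast when several co-expressions occur; immune cells without
#' co-expression stay `"immune"`; non-immune cells get `NA`.
#'
#' @inheritParams classify_level2
#' @param compartment_markers Named list mapping the three phenotypes to
#'   their lineage markers.
#' @return Character vector of level-3 labels.
#' @export
classify_level3 <- function(pos, level1,
                            compartment_markers = list(
                              epithelial = c("Ecad", "EGFR"),
                              endothelial = c("CD31", "Podoplanin", "CD140b", "CD146"),
                              fibroblast = c("Collagen1", "CD90", "aSMA"))) {
  out <- rep(NA_character_, nrow(pos))
  imm <- level1 == "immune"
  out[imm] <- "immune"
  for (comp in rev(c("epithelial", "endothelial", "fibroblast"))) {
    ms <- intersect(compartment_markers[[comp]], colnames(pos))
    if (length(ms) == 0) next
    hit <- imm & rowSums(pos[, ms, drop = FALSE]) > 0
    out[hit] <- paste0("immune-in-", comp)
  }
  out
}

#' Level-4 functional states
#'
#' Non-exclusive functional flags per cell: proliferation (Ki67 or pERK),
#' apoptosis (BNIP3), autophagy (Caveolin), pro-inflammatory (pNFkB),
#' migration (IntegrinB1), transcriptional activity (pSTAT3). Cells with
#' no flag are `"non-functional"`. A dominant-state reduction (fixed
#' precedence proliferation > apoptosis > autophagy > pro-inflammatory >
#' migration > transcriptional) is returned for visualization and
#' composition summaries.
#'
#' @inheritParams classify_level1
#' @param fmap Named list state -> marker vector.
#' @return A list: `flags` (logical cells x states matrix), `dominant`
#'   (character vector).
#' @export
classify_level4 <- function(pos, fmap = default_functional_map()) {
  unmapped <- setdiff(unlist(fmap), colnames(pos))
  if (length(unmapped) > 0) {
    warning("functional marker(s) not in positivity matrix: ",
            paste(unmapped, collapse = ", "), call. = FALSE)
  }
  flags <- state_flags_from_markers(pos, fmap)
  list(flags = flags, dominant = dominant_state(flags))
}

#' Run the full four-level classification on a cell table
#'
#' Estimates thresholds (unless given), calls positivity, and adds
#' `level1`..`level4` columns plus one logical `fs_<state>` column per
#' functional state.
#'
#' @param cells An arcsinh-transformed `cell_table`.
#' @param rules A `gating_rules` tibble.
#' @param thresholds Optional `positivity_thresholds`; estimated with
#'   `method` when missing.
#' @param method Threshold method passed to [estimate_thresholds()].
#' @param fixed Optional named threshold overrides.
#' @return The `cell_table` with label columns added.
#' @export
classify_cells <- function(cells, rules = default_gating_rules(),
                           thresholds = NULL, method = "gmm2", fixed = NULL) {
  if (is.null(thresholds)) {
    thresholds <- estimate_thresholds(cells, method = method, fixed = fixed)
  }
  pos <- call_positivity(cells, thresholds)
  df <- tibble::as_tibble(cells)
  df$level1 <- classify_level1(pos, rules)
  df$level2 <- classify_level2(pos, df$level1, rules)
  df$level3 <- classify_level3(pos, df$level1)
  l4 <- classify_level4(pos)
  df$level4 <- l4$dominant
  for (s in colnames(l4$flags)) {
    df[[paste0("fs_", gsub("-", "_", s))]] <- l4$flags[, s]
  }
  restore_ct(df, cells)
}
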