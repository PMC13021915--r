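#' Two-population lognormal marker intensity model
#'
#' Marker intensities are drawn from one of two lognormal populations:
#' a positive (stained) and a negative (background) population. Which
#' population a cell draws from is decided by its true type's marker
#' signature and by per-(type, marker) positivity rates. Lognormal is the
#' standard cytometry intensity assumption and has closed-form moments
#' (`E[X] = exp(meanlog + sdlog^2 / 2)`) used by the generator tests.
#'
#' @param pos_meanlog,pos_sdlog Log-mean and log-sd of the positive
#'   population (defaults `log(20)`, 0.35).
#' @param neg_meanlog,neg_sdlog Log-mean and log-sd of the background
#'   population (defaults `log(1)`, 0.35).
#' @param nuclear_scale_meanlog,nuclear_scale_sdlog Lognormal factor
#'   linking whole-cell signal to the nuclear channel for nuclear markers.
#' @param marker_params Optional tibble (`marker`, `pos_meanlog`,
#'   `pos_sdlog`, `neg_meanlog`, `neg_sdlog`) overriding the global
#'   populations per marker.
#' @return A list of class `intensity_model`.
#' @export
intensity_model <- function(pos_meanlog = log(20), pos_sdlog = 0.35,
                            neg_meanlog = log(1), neg_sdlog = 0.35,
                            nuclear_scale_meanlog = log(0.7),
                            nuclear_scale_sdlog = 0.15,
                            marker_params = NULL) {
  if (pos_meanlog <= neg_meanlog) {
    stop("positive population log-mean must exceed the negative log-mean",
         call. = FALSE)
  }
  structure(list(
    pos_meanlog = pos_meanlog, pos_sdlog = pos_sdlog,
    neg_meanlog = neg_meanlog, neg_sdlog = neg_sdlog,
    nuclear_scale_meanlog = nuclear_scale_meanlog,
    nuclear_scale_sdlog = nuclear_scale_sdlog,
    marker_params = marker_params
  ), class = "intensity_model")
}

#' Noise-free intensity model
#'
#' Degenerate model with zero log-sd everywhere: positives are constant
#' `exp(pos_meanlog)`, negatives constant `exp(neg_meanlog)`. Used to
#' check that classification recovers planted labels exactly when marker
#' populations do not overlap at all.
#'
#' @inheritParams intensity_model
#' @return An `intensity_model`.
#' @export
noise_free_model <- function(pos_meanlog = log(20), neg_meanlog = log(1)) {
  intensity_model(pos_meanlog = pos_meanlog, pos_sdlog = 0,
                  neg_meanlog = neg_meanlog, neg_sdlog = 0,
                  nuclear_scale_sdlog = 0)
}

# per-marker population parameters as a matrix lookup
model_params_for <- function(model, markers) {
  out <- tibble::tibble(
    marker = markers,
    pos_meanlog = model$pos_meanlog, pos_sdlog = model$pos_sdlog,
    neg_meanlog = model$neg_meanlog, neg_sdlog = model$neg_sdlog
  )
  if (!is.null(model$marker_params)) {
    ov <- model$marker_params
    m <- match(out$marker, ov$marker)
    for (col in c("pos_meanlog", "pos_sdlog", "neg_meanlog", "neg_sdlog")) {
      if (col %in% names(ov)) {
        out[[col]] <- ifelse(is.na(m), out[[col]], ov[[col]][m])
      }
    }
  }
  out
}

#' Fixed positivity thresholds implied by an intensity model
#'
#' The arcsinh-scale threshold at the geometric midpoint of the two
#' population medians — the planted decision boundary the mixture-model
#' estimator is expected to recover.
#'
#' @param model An `intensity_model`.
#' @param markers Marker names to produce thresholds for.
#' @param cofactor arcsinh cofactor used downstream.
#' @return Named numeric vector of thresholds on the arcsinh scale.
#' @export
model_thresholds <- function(model, markers, cofactor = 5) {
  pr <- model_params_for(model, markers)
  mid <- exp((pr$pos_meanlog + pr$neg_meanlog) / 2)
  stats::setNames(asinh(mid / cofactor), markers)
}

#' Draw per-cell marker positivity flags
#'
#' A cell is flagged positive for a marker when the marker is in its true
#' type's signature, or by chance at the per-(type, marker) rate in
#' `rates` (functional positivity). DNA channels are always positive;
#' segmentation channels never.
#'
#' @param cells Tibble with a `type` column (one row per cell).
#' @param signatures Named list: type -> character vector of signature
#'   markers.
#' @param panel A `marker_panel`.
#' @param rates Optional tibble (`type`, `marker`, `rate`) of extra
#'   positivity rates.
#' @param seed Optional RNG seed.
#' @return Logical matrix, cells x panel markers.
#' @export
positivity_flags <- function(cells, signatures, panel, rates = NULL, seed = NULL) {
  missing_sig <- setdiff(unique(cells$type), names(signatures))
  if (length(missing_sig) > 0) {
    stop("cell type(s) without an intensity signature: ",
         paste(missing_sig, collapse = ", "), call. = FALSE)
  }
  local_rng(seed, {
    n <- nrow(cells)
    flags <- matrix(FALSE, nrow = n, ncol = nrow(panel),
                    dimnames = list(NULL, panel$name))
    for (t in unique(cells$type)) {
      rows <- which(cells$type == t)
      sig <- intersect(signatures[[t]], panel$name)
      flags[rows, sig] <- TRUE
    }
    if (!is.null(rates) && nrow(rates) > 0) {
      for (k in seq_len(nrow(rates))) {
        rows <- which(cells$type == rates$type[k])
        m <- rates$marker[k]
        if (length(rows) > 0 && m %in% panel$name && rates$rate[k] > 0) {
          hit <- stats::runif(length(rows)) < rates$rate[k]
          flags[rows[hit], m] <- TRUE
        }
      }
    }
    flags[, panel$name[panel$role == "dna"]] <- TRUE
    flags[, panel$name[panel$role == "segmentation"]] <- FALSE
    flags
  })
}

#' Draw raw marker intensities for flagged cells
#'
#' Each (cell, marker) intensity is a lognormal draw from the positive or
#' negative population according to `flags`. Nuclear-compartment markers
#' additionally get a `nuc_<marker>` channel; the whole-cell value is the
#' nuclear value times a lognormal dilution factor.
#'
#' @param cells Tibble with `cell_id`, `sample_id`, `roi_id`, `group`,
#'   `x`, `y` columns (one row per cell).
#' @param flags Logical cells x markers matrix from [positivity_flags()].
#' @param model An `intensity_model`.
#' @param panel A `marker_panel`.
#' @param seed Optional RNG seed.
#' @return A raw `cell_table`.
#' @export
draw_intensities <- function(cells, flags, model, panel, seed = NULL) {
  stopifnot(nrow(flags) == nrow(cells), all(colnames(flags) == panel$name))
  pr <- model_params_for(model, panel$name)
  local_rng(seed, {
    n <- nrow(cells)
    df <- tibble::as_tibble(cells)[, c("cell_id", "sample_id", "roi_id",
                                       "group", "x", "y")]
    for (k in seq_len(nrow(panel))) {
      m <- panel$name[k]
      f <- flags[, m]
      meanlog <- ifelse(f, pr$pos_meanlog[k], pr$neg_meanlog[k])
      sdlog <- ifelse(f, pr$pos_sdlog[k], pr$neg_sdlog[k])
      v <- stats::rlnorm(n, meanlog, sdlog)
      if (panel$compartment[k] == "nuclear") {
        df[[paste0("nuc_", m)]] <- v
        df[[m]] <- v * stats::rlnorm(n, model$nuclear_scale_meanlog,
                                     model$nuclear_scale_sdlog)
      } else {
        df[[m]] <- v
      }
    }
    cell_table(df, panel, transform_state = "raw")
  })
}
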