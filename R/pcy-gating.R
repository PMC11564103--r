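#' Gate cells on marker intensities
#'
#' Turns raw per-channel intensities into boolean marker gates, fitting
#' one plate-level threshold per marker (intensity histograms are pooled
#' across the whole drug plate, so DMSO and drug wells share thresholds).
#' If the requested gate columns are already boolean the table is
#' returned unchanged.
#'
#' @param cells Cell-level table.  For each marker in `markers`, either a
#'   boolean column of that name or an intensity column
#'   `intensity_<marker>` must be present.
#' @param markers Marker gate columns to produce.
#' @param method Thresholding method: `"gmm"` fits a two-component
#'   Gaussian mixture on log10 intensity and places the threshold where
#'   the posterior flips between components; `"fixed"` uses
#'   `thresholds[marker]`; `"quantile"` uses the `prob` quantile of the
#'   plate's intensities as a robust background cut.
#' @param thresholds Named numeric vector of fixed thresholds
#'   (`method = "fixed"`), on the raw intensity scale.
#' @param prob Quantile for `method = "quantile"`.
#' @return `cells` with boolean gate columns; fitted thresholds are
#'   attached as attribute `"thresholds"` (plate x marker tibble).
#' @export
gate_cells <- function(cells,
                       markers = c("nestin", "s100b", "cd45"),
                       method = c("gmm", "fixed", "quantile"),
                       thresholds = NULL,
                       prob = 0.95) {
  method <- match.arg(method)
  cells <- tibble::as_tibble(cells)
  have_gates <- markers[markers %in% names(cells)]
  if (length(have_gates) == length(markers) &&
      all(vapply(cells[markers], is.logical, logical(1)))) {
    return(cells)  # pre-gated input passes through untouched
  }
  fitted <- list()
  for (m in markers) {
    col <- paste0("intensity_", m)
    if (!col %in% names(cells)) {
      abort(sprintf("no gate or intensity column for marker '%s'", m))
    }
    for (plate in unique(cells$plate_id)) {
      in_plate <- cells$plate_id == plate
      x <- cells[[col]][in_plate]
      if (method == "gmm" && sum(in_plate) < 500) {
        abort("automatic thresholding needs >= 500 cells per plate")
      }
      if (sd(x) == 0) {
        abort(sprintf("degenerate intensity distribution in channel '%s'", m))
      }
      thr <- switch(method,
        gmm = .gmm_threshold(x),
        fixed = {
          if (is.null(thresholds) || is.na(thresholds[m])) {
            abort(sprintf("no fixed threshold supplied for marker '%s'", m))
          }
          unname(thresholds[m])
        },
        quantile = unname(quantile(x, prob))
      )
      cells[[m]][in_plate] <- x > thr
      fitted[[length(fitted) + 1L]] <-
        tibble::tibble(plate_id = plate, marker = m, threshold = thr)
    }
  }
  attr(cells, "thresholds") <- dplyr::bind_rows(fitted)
  cells
}

# Two-component Gaussian mixture on log10 intensity; threshold at the
# posterior crossover between the low and high component.
.gmm_threshold <- function(x) {
  lx <- log10(pmax(x, .Machine$double.eps))
  fit <- Mclust(lx, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) fit <- Mclust(lx, G = 2, modelNames = "E", verbose = FALSE)
  mu <- fit$parameters$mean
  lo <- which.min(mu); hi <- which.max(mu)
  sdv <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sdv) == 1) sdv <- rep(sdv, 2)
  pro <- fit$parameters$pro
  post_diff <- function(v) {
    pro[hi] * stats::dnorm(v, mu[hi], sdv[hi]) -
      pro[lo] * stats::dnorm(v, mu[lo], sdv[lo])
  }
  root <- tryCatch(
    stats::uniroot(post_diff, lower = mu[lo], upper = mu[hi])$root,
    error = function(e) mean(mu)
  )
  10^root
}
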