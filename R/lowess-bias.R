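#' Fit a distance-dependent inter-sample bias curve by LOWESS
#'
#' For every stored position present in either matrix the log-ratio
#' `M = log2((target + pseudocount) / (reference + pseudocount))` is
#' computed, and a LOWESS curve of M against log10(genomic distance) is
#' fitted over all intra-chromosomal positions pooled genome-wide. The
#' fitted curve, evaluated on the grid of realized distances, captures the
#' systematic distance-dependent bias of the target library relative to the
#' reference; [apply_bias_correction()] divides it out. Diagonal entries
#' (distance 0) are excluded from the fit.
#'
#' @param target,reference [contact_matrix()] objects on identical layouts.
#' @param smoothing_fraction LOWESS smoother span in (0, 1\] (default 0.3).
#' @param pseudocount added to both counts before the log ratio (default 1).
#' @return an object of class `bias_curve`: data.frame-backed list with
#'   `distance_grid` (bp, strictly increasing), `log2_bias`, and
#'   `smoothing_fraction`.
#' @export
fit_lowess_bias <- function(target, reference, smoothing_fraction = 0.3,
                            pseudocount = 1.0) {
  if (!layouts_identical(target$layout, reference$layout)) {
    stop_input("fit_lowess_bias requires identical layouts")
  }
  if (!is.finite(smoothing_fraction) || smoothing_fraction <= 0 ||
      smoothing_fraction > 1) {
    stop_input("smoothing_fraction must be in (0, 1]")
  }
  m <- merged_entries(target, reference)
  bin_size <- target$layout$bin_size
  d <- (m$bin2 - m$bin1) * bin_size
  keep <- d > 0
  if (!any(keep & (m$count.x > 0) & (m$count.y > 0))) {
    stop_input("no overlapping nonzero off-diagonal positions to fit")
  }
  d <- d[keep]
  M <- log2((m$count.x[keep] + pseudocount) / (m$count.y[keep] + pseudocount))
  fit <- stats::lowess(log10(d), M, f = smoothing_fraction)
  # lowess sorts by x; collapse ties onto the unique distance grid
  g <- tapply(fit$y, fit$x, mean)
  grid_d <- 10^as.numeric(names(g))
  structure(list(distance_grid = round(grid_d),
                 log2_bias = as.numeric(g),
                 smoothing_fraction = smoothing_fraction),
            class = "bias_curve")
}

#' @export
print.bias_curve <- function(x, ...) {
  cat(sprintf(paste0("bias_curve: %d grid points, distance %g-%g bp, ",
                     "log2 bias range [%.3g, %.3g]\n"),
              length(x$distance_grid), min(x$distance_grid),
              max(x$distance_grid), min(x$log2_bias), max(x$log2_bias)))
  invisible(x)
}

# interpolate the curve at distances d: linear in log10(d) between grid
# points, constant beyond the grid ends; d == 0 takes the left end value.
interp_bias <- function(curve, d) {
  gx <- log10(curve$distance_grid)
  gy <- curve$log2_bias
  if (length(gx) == 1L) return(rep(gy, length(d)))
  x <- ifelse(d <= 0, gx[1L], log10(d))
  stats::approx(gx, gy, xout = x, rule = 2)$y
}

#' Divide a fitted distance bias out of a contact matrix
#'
#' Each count is divided by `2^b(d)` where `b` is the bias curve linearly
#' interpolated at the entry's genomic distance (constant extrapolation
#' beyond the grid). `total_valid_pairs` is left unchanged.
#'
#' @param target a [contact_matrix()].
#' @param curve a `bias_curve` from [fit_lowess_bias()].
#' @return the corrected [contact_matrix()].
#' @export
apply_bias_correction <- function(target, curve) {
  stopifnot(inherits(curve, "bias_curve"))
  ent <- target$entries
  if (nrow(ent) > 0L) {
    d <- (ent$bin2 - ent$bin1) * target$layout$bin_size
    ent$count <- ent$count / 2^interp_bias(curve, d)
  }
  contact_matrix(target$layout, ent,
                 total_valid_pairs = target$total_valid_pairs)
}
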