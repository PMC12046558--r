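#' Gaussian kernel density estimate of a distance distribution
#'
#' Smooths a sample of ligand-carbene distances into a probability density
#' with a Gaussian kernel. The default bandwidth is Silverman's rule,
#' h = 0.9 min(sd, IQR/1.34) n^(-1/5); the evaluation grid spans
#' \[min - 3h, max + 3h\] at `n_grid` points, so the trapezoid integral of
#' the density is 1 to within about 1%. Local maxima are reported as peaks:
#' the global maximum always, secondary maxima only above `peak_min_frac`
#' of its height.
#'
#' @param samples numeric vector of distances (Angstrom), >= 10 finite
#'   positive values.
#' @param bandwidth `"silverman"` or a fixed numeric bandwidth (Angstrom).
#' @param n_grid number of grid points (>= 512 recommended; default 512).
#' @param peak_min_frac minimum height of a secondary peak, as a fraction of
#'   the main peak height (default 0.2).
#' @return an object of class `KDEResult`: list with `grid`, `density`,
#'   `bandwidth`, `n_samples` and `peaks` (data frame `location`, `height`,
#'   sorted by height, decreasing).
#' @export
kde <- function(samples, bandwidth = "silverman", n_grid = 512L,
                peak_min_frac = 0.2) {
  samples <- as.numeric(samples)
  if (length(samples) < 10L) {
    stop("too few samples for a density estimate (need >= 10)", call. = FALSE)
  }
  if (!all(is.finite(samples)) || any(samples <= 0)) {
    stop("samples must be finite positive distances", call. = FALSE)
  }
  if (identical(bandwidth, "silverman")) {
    spread <- min(stats::sd(samples), stats::IQR(samples) / 1.34)
    h <- 0.9 * spread * length(samples)^(-1 / 5)
  } else {
    h <- as.numeric(bandwidth)
    if (!is.finite(h) || h <= 0) stop("invalid fixed bandwidth", call. = FALSE)
  }
  if (h < 0.01) {
    warning("near-zero sample variance; using bandwidth floor 0.01 A",
            call. = FALSE)
    h <- 0.01
  }
  dens <- stats::density(samples, bw = h, kernel = "gaussian",
                         from = min(samples) - 3 * h,
                         to = max(samples) + 3 * h, n = n_grid)
  peaks <- .find_peaks(dens$x, dens$y, peak_min_frac)
  structure(
    list(grid = dens$x, density = dens$y, bandwidth = h,
         n_samples = length(samples), peaks = peaks),
    class = "KDEResult"
  )
}

# local maxima of a sampled curve; global max always kept, secondary maxima
# only above min_frac of the global height
.find_peaks <- function(x, y, min_frac) {
  n <- length(y)
  d <- diff(y)
  s <- sign(d)
  # a local max is a + -> - sign change of the first difference
  idx <- which(s[-length(s)] > 0 & s[-1L] < 0) + 1L
  if (y[1L] > y[2L]) idx <- c(1L, idx)
  if (y[n] > y[n - 1L]) idx <- c(idx, n)
  if (length(idx) == 0L) idx <- which.max(y)
  height <- y[idx]
  keep <- height > min_frac * max(y) | height == max(y)
  idx <- idx[keep]
  height <- height[keep]
  ord <- order(height, decreasing = TRUE)
  data.frame(location = x[idx[ord]], height = height[ord])
}

#' @export
print.KDEResult <- function(x, ...) {
  cat(sprintf("<KDEResult: n=%d, bw=%.3f A, %d peak(s); mode at %.2f A>\n",
              x$n_samples, x$bandwidth, nrow(x$peaks), x$peaks$location[1L]))
  invisible(x)
}

#' Facial-selectivity prediction from a descriptor series
#'
#' The primary statistic is the paired-frame blocking probability
#' `p_re_blocked`: the fraction of frames (with both distances defined) in
#' which d(Re) < d(Si), ties counting one half. A face is called only when
#' the probability is decisive: `p_re_blocked` above `decision_threshold`
#' predicts approach at the less hindered Si face, below
#' `1 - decision_threshold` the Re face, anything between predicts no face.
#' Per-face KDEs supply the mode positions and a multimodality flag (two or
#' more peaks with a secondary-to-primary height ratio above 0.2), the
#' structural signature of a conformationally flexible, weakly selective
#' catalyst.
#'
#' @param series a `DescriptorSeries` (or any data frame with `d_re`,
#'   `d_si` columns).
#' @param decision_threshold probability cut for calling a face
#'   (default 0.8).
#' @param bandwidth passed to [kde()].
#' @return an object of class `SelectivityReport`: list with
#'   `p_re_blocked`, `predicted_face` (`"Si"`, `"Re"` or `"none"`),
#'   `mode_re`, `mode_si`, `kde_re`, `kde_si`, `multimodality`
#'   (named logical, one per face), `n_frames_used`, `n_frames_missing`,
#'   `decision_threshold`.
#' @export
facial_bias <- function(series, decision_threshold = 0.8,
                        bandwidth = "silverman") {
  if (!all(c("d_re", "d_si") %in% names(series))) {
    stop("series must contain d_re and d_si columns", call. = FALSE)
  }
  if (decision_threshold <= 0.5 || decision_threshold > 1) {
    stop("decision_threshold must be in (0.5, 1]", call. = FALSE)
  }
  paired <- is.finite(series$d_re) & is.finite(series$d_si)
  n <- sum(paired)
  if (n < 10L) {
    stop(sprintf("insufficient paired frames (%d; need >= 10)", n),
         call. = FALSE)
  }
  dre <- series$d_re[paired]
  dsi <- series$d_si[paired]
  p <- (sum(dre < dsi) + 0.5 * sum(dre == dsi)) / n
  predicted <- if (p > decision_threshold) "Si" else
    if (p < 1 - decision_threshold) "Re" else "none"
  kde_re <- kde(series$d_re[is.finite(series$d_re)], bandwidth = bandwidth)
  kde_si <- kde(series$d_si[is.finite(series$d_si)], bandwidth = bandwidth)
  multim <- c(Re = nrow(kde_re$peaks) >= 2L, Si = nrow(kde_si$peaks) >= 2L)
  structure(
    list(p_re_blocked = p, predicted_face = predicted,
         mode_re = kde_re$peaks$location[1L],
         mode_si = kde_si$peaks$location[1L],
         kde_re = kde_re, kde_si = kde_si,
         multimodality = multim,
         n_frames_used = n, n_frames_missing = nrow(series) - n,
         decision_threshold = decision_threshold),
    class = "SelectivityReport"
  )
}

#' @export
print.SelectivityReport <- function(x, ...) {
  cat("<SelectivityReport>\n")
  cat(sprintf("  p(Re blocked)   : %.3f over %d paired frames (%d missing)\n",
              x$p_re_blocked, x$n_frames_used, x$n_frames_missing))
  cat(sprintf("  predicted face  : %s (threshold %.2f)\n",
              x$predicted_face, x$decision_threshold))
  cat(sprintf("  KDE modes       : d(Re) %.2f A, d(Si) %.2f A\n",
              x$mode_re, x$mode_si))
  cat(sprintf("  multimodal      : Re %s, Si %s\n",
              x$multimodality[["Re"]], x$multimodality[["Si"]]))
  invisible(x)
}

#' Compare a face prediction with an experimental ee sign
#'
#' Uses the sign convention of enantioselectivity reporting for these
#' systems: a positive experimental ee means addition at the carbene Si
#' face is favored, a negative ee means the Re face. The comparison is
#' `"indeterminate"` when the prediction declined to call a face.
#'
#' @param report a `SelectivityReport`.
#' @param experimental_ee_percent signed ee in percent, in \[-100, 100\].
#' @param ee_sign_convention only `"positive_means_si"` is defined.
#' @return list with `agrees` (`TRUE`, `FALSE` or `"indeterminate"`) and
#'   `detail` (human-readable summary).
#' @export
compare_to_experiment <- function(report, experimental_ee_percent,
                                  ee_sign_convention = "positive_means_si") {
  ee_sign_convention <- match.arg(ee_sign_convention)
  ee <- as.numeric(experimental_ee_percent)
  if (!is.finite(ee) || abs(ee) > 100) {
    stop("experimental ee must be a signed percentage in [-100, 100]",
         call. = FALSE)
  }
  if (report$predicted_face == "none") {
    return(list(agrees = "indeterminate",
                detail = sprintf(
                  "no face called (p_re_blocked = %.3f); experimental ee %+g%%",
                  report$p_re_blocked, ee)))
  }
  agrees <- (report$predicted_face == "Si" && ee > 0) ||
    (report$predicted_face == "Re" && ee < 0)
  list(agrees = agrees,
       detail = sprintf("predicted %s-face approach vs experimental ee %+g%% (%s)",
                        report$predicted_face, ee,
                        if (agrees) "consistent" else "inconsistent"))
}
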