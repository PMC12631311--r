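#' Chromatogram container
#'
#' @param volume Elution volume in mL (strictly increasing).
#' @param absorbance Detector absorbance (mAU, finite).
#' @param flow_ml_min Flow rate (mL/min), metadata only.
#' @return data.frame of class `"chromatogram"`.
#' @export
chromatogram <- function(volume, absorbance, flow_ml_min = NA_real_) {
  if (length(volume) != length(absorbance)) stop("length mismatch")
  if (length(volume) > 1L && any(diff(volume) <= 0))
    stop("elution volumes must be strictly increasing")
  if (any(!is.finite(absorbance))) stop("absorbance must be finite")
  out <- data.frame(volume = as.numeric(volume),
                    absorbance = as.numeric(absorbance))
  attr(out, "flow_ml_min") <- flow_ml_min
  class(out) <- c("chromatogram", "data.frame")
  out
}

#' Fit a size-exclusion calibration curve
#'
#' Least-squares line of log10(MW in kDa) against elution volume (mL)
#' through the standards, the classic log-linear column calibration.
#' Larger species elute earlier, so the slope is negative for a sane
#' standard set.
#'
#' @param standards data.frame with columns `mw_kda` and `ve_ml`
#'   (optionally `name`).
#' @return list of class `"sec_calibration"`: `slope`, `intercept`,
#'   `residuals` (in log10 kDa), `range_ml` (volume span of the
#'   standards), `standards`.
#' @export
fit_calibration <- function(standards) {
  if (nrow(standards) < 2L) stop("need at least 2 calibration standards")
  if (anyDuplicated(standards$ve_ml)) stop("duplicate standard elution volumes")
  fit <- stats::lm(log10(mw_kda) ~ ve_ml, data = standards)
  co <- stats::coef(fit)
  out <- list(slope = unname(co[2L]), intercept = unname(co[1L]),
              residuals = unname(stats::residuals(fit)),
              range_ml = range(standards$ve_ml), standards = standards)
  class(out) <- "sec_calibration"
  out
}

#' Apparent molecular weight from an elution volume
#'
#' `MW = 10^(slope * V + intercept)`; predictions outside the
#' standards' volume span are flagged as extrapolations.
#'
#' @param volume Elution volume(s) in mL.
#' @param cal A [fit_calibration()] object.
#' @return data.frame: `volume`, `mw_kda`, `extrapolated`.
#' @export
apparent_mw <- function(volume, cal) {
  stopifnot(inherits(cal, "sec_calibration"))
  mw <- 10^(cal$slope * volume + cal$intercept)
  data.frame(volume = volume, mw_kda = mw,
             extrapolated = volume < cal$range_ml[1L] |
                            volume > cal$range_ml[2L])
}

#' Invert a calibration: elution volume for a molecular weight
#'
#' @param mw_kda Molecular weight(s), kDa.
#' @param cal A [fit_calibration()] object.
#' @return Elution volume(s) in mL.
#' @export
elution_volume <- function(mw_kda, cal) {
  stopifnot(inherits(cal, "sec_calibration"))
  (log10(mw_kda) - cal$intercept) / cal$slope
}

#' Detect peaks and shoulders in a chromatogram
#'
#' Peaks are local maxima of the Savitzky-Golay-smoothed signal above
#' a height threshold. Shoulders are local minima of the second
#' derivative (curvature pockets) on a peak's flank that exceed a
#' curvature prominence threshold without being local maxima
#' themselves. Detection is invariant to uniform absorbance scaling.
#'
#' @param chrom A [chromatogram()].
#' @param window Odd smoothing window in samples (default 11).
#' @param min_height Minimum peak height as a fraction of the signal
#'   maximum (default 0.05).
#' @param shoulder_prominence Minimum absolute second-derivative dip,
#'   as a fraction of the strongest curvature (default 0.05).
#' @param min_separation_ml Minimum distance between reported features
#'   (default 0.3 mL).
#' @return data.frame: `volume`, `height`, `kind` ("peak"/"shoulder"),
#'   ordered by volume.
#' @export
detect_peaks <- function(chrom, window = 11L, min_height = 0.05,
                         shoulder_prominence = 0.05,
                         min_separation_ml = 0.3) {
  v <- chrom$volume
  y <- chrom$absorbance
  if (length(v) < 5L) stop("chromatogram too short for peak detection")
  if (window %% 2L == 0L) window <- window + 1L
  window <- min(window, length(v) - (1 - length(v) %% 2L))
  ys <- signal::sgolayfilt(y, p = 3L, n = window)
  n <- length(ys)
  ymax <- max(ys)
  # local maxima of the smoothed signal
  is_max <- c(FALSE, ys[2:(n - 1L)] > ys[1:(n - 2L)] &
                     ys[2:(n - 1L)] >= ys[3:n], FALSE)
  peak_idx <- which(is_max & ys >= min_height * ymax)
  # second derivative via Savitzky-Golay differentiation
  h <- mean(diff(v))
  d2 <- signal::sgolayfilt(y, p = 3L, n = window, m = 2L) / h^2
  is_d2min <- c(FALSE, d2[2:(n - 1L)] < d2[1:(n - 2L)] &
                       d2[2:(n - 1L)] <= d2[3:n], FALSE)
  # curvature-dip prominence: depth of the d2 minimum below the lower
  # of its two flanking d2 maxima (a shoulder is a pocket of locally
  # reduced curvature on a peak flank, whatever the sign of d2 there)
  d2range <- diff(range(d2))
  d2_prom <- function(i) {
    left <- if (i > 1L) max(d2[1:(i - 1L)]) else d2[i]
    right <- if (i < n) max(d2[(i + 1L):n]) else d2[i]
    min(left, right) - d2[i]
  }
  cand <- which(is_d2min & ys >= min_height * ymax)
  cand <- cand[vapply(cand, d2_prom, numeric(1L)) >=
                 shoulder_prominence * d2range]
  # drop candidates that coincide with detected peaks
  near_peak <- function(i) any(abs(v[i] - v[peak_idx]) < min_separation_ml)
  shoulder_idx <- cand[!vapply(cand, near_peak, logical(1L))]
  # enforce separation among shoulders (keep deepest curvature first)
  shoulder_idx <- shoulder_idx[order(d2[shoulder_idx])]
  kept <- integer(0)
  for (i in shoulder_idx) {
    if (all(abs(v[i] - v[kept]) >= min_separation_ml)) kept <- c(kept, i)
  }
  out <- rbind(
    if (length(peak_idx) > 0L)
      data.frame(volume = v[peak_idx], height = ys[peak_idx],
                 kind = "peak", stringsAsFactors = FALSE),
    if (length(kept) > 0L)
      data.frame(volume = v[kept], height = ys[kept],
                 kind = "shoulder", stringsAsFactors = FALSE)
  )
  if (is.null(out))
    return(data.frame(volume = numeric(0), height = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE))
  out <- out[order(out$volume), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Oligomeric order from an apparent molecular weight
#'
#' Ratio of apparent to monomer weight and its nearest integer. The
#' raw ratio is returned so callers can flag ambiguous assignments
#' (e.g. a fast dimer-tetramer equilibrium averaging near 3).
#'
#' @param mw_app Apparent molecular weight (kDa).
#' @param monomer_mw Monomer weight (kDa).
#' @return list: `ratio`, `order` (integer).
#' @export
oligomer_order <- function(mw_app, monomer_mw) {
  if (!isTRUE(mw_app > 0) || !isTRUE(monomer_mw > 0))
    stop("weights must be positive")
  r <- mw_app / monomer_mw
  list(ratio = r, order = as.integer(round(r)))
}

#' Read a chromatogram from a two-column TSV/CSV file
#' @param path File with columns volume_mL, mAU.
#' @return A [chromatogram()].
#' @export
read_chromatogram <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep)
  chromatogram(d[[1L]], d[[2L]])
}

#' Read a calibration-standards table
#' @param path TSV with columns name, MW_kDa, Ve_mL.
#' @return data.frame with columns `name`, `mw_kda`, `ve_ml`.
#' @export
read_standards <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  data.frame(name = d$name, mw_kda = d$mw_kda, ve_ml = d$ve_ml,
             stringsAsFactors = FALSE)
}
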