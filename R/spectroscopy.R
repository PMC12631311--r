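#' Circular-dichroism spectrum container
#'
#' Far-UV CD spectrum on a strictly increasing wavelength grid, either
#' in raw millidegrees or in mean residue ellipticity (MRE), with the
#' acquisition parameters needed for conversion.
#'
#' @param wavelength Wavelength grid in nm (strictly increasing).
#' @param value Ellipticity values.
#' @param unit "mdeg" or "MRE".
#' @param path_cm Cuvette path length L in cm.
#' @param conc_mg_ml Sample concentration C in mg/mL.
#' @param mw_kda Mean residue (or molar) weight Mw in kDa.
#' @return data.frame of class `"cd_spectrum"` with columns
#'   `wavelength`, `value` and metadata attributes.
#' @export
cd_spectrum <- function(wavelength, value, unit = c("mdeg", "MRE"),
                        path_cm = NA_real_, conc_mg_ml = NA_real_,
                        mw_kda = NA_real_) {
  unit <- match.arg(unit)
  if (length(wavelength) != length(value)) stop("grid/value length mismatch")
  if (length(wavelength) > 1L && any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  out <- data.frame(wavelength = as.numeric(wavelength),
                    value = as.numeric(value))
  attr(out, "unit") <- unit
  attr(out, "path_cm") <- path_cm
  attr(out, "conc_mg_ml") <- conc_mg_ml
  attr(out, "mw_kda") <- mw_kda
  class(out) <- c("cd_spectrum", "data.frame")
  out
}

#' Convert a CD spectrum from millidegrees to mean residue ellipticity
#'
#' Pointwise `MRE = mdeg * Mw / (10 * L * C)` with L the path length in
#' cm, C the concentration in mg/mL and Mw the weight in kDa.
#'
#' @param spectrum A [cd_spectrum()] in mdeg.
#' @param path_cm,conc_mg_ml,mw_kda Override the spectrum's stored
#'   acquisition parameters.
#' @return A [cd_spectrum()] in MRE.
#' @export
to_mre <- function(spectrum, path_cm = attr(spectrum, "path_cm"),
                   conc_mg_ml = attr(spectrum, "conc_mg_ml"),
                   mw_kda = attr(spectrum, "mw_kda")) {
  if (attr(spectrum, "unit") != "mdeg") stop("spectrum is not in mdeg")
  if (!isTRUE(path_cm > 0) || !isTRUE(conc_mg_ml > 0) || !isTRUE(mw_kda > 0))
    stop("path length, concentration and Mw must all be positive")
  cd_spectrum(spectrum$wavelength,
              spectrum$value * mw_kda / (10 * path_cm * conc_mg_ml),
              unit = "MRE", path_cm = path_cm, conc_mg_ml = conc_mg_ml,
              mw_kda = mw_kda)
}

#' Baseline-correct and average replicate CD spectra
#'
#' Subtracts the baseline pointwise from each acquisition, then takes
#' the pointwise mean.
#'
#' @param spectra list of [cd_spectrum()] objects on one grid and unit.
#' @param baseline Optional [cd_spectrum()] on the same grid.
#' @return A [cd_spectrum()].
#' @export
average_and_correct <- function(spectra, baseline = NULL) {
  stopifnot(length(spectra) >= 1L)
  grid <- spectra[[1L]]$wavelength
  unit <- attr(spectra[[1L]], "unit")
  for (s in spectra) {
    if (!isTRUE(all.equal(s$wavelength, grid)) ||
        !identical(attr(s, "unit"), unit))
      stop("all spectra must share one wavelength grid and unit")
  }
  vals <- vapply(spectra, function(s) s$value, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  if (!is.null(baseline)) {
    if (!isTRUE(all.equal(baseline$wavelength, grid)))
      stop("baseline grid mismatch")
    vals <- vals - baseline$value
  }
  cd_spectrum(grid, rowMeans(vals), unit = unit,
              path_cm = attr(spectra[[1L]], "path_cm"),
              conc_mg_ml = attr(spectra[[1L]], "conc_mg_ml"),
              mw_kda = attr(spectra[[1L]], "mw_kda"))
}

#' Savitzky-Golay smoothing of a CD spectrum
#'
#' Local least-squares polynomial smoothing on a uniform grid; the
#' default (order 3, window 9) reproduces any cubic exactly.
#'
#' @param spectrum A [cd_spectrum()] on a uniform grid.
#' @param order Polynomial order (default 3).
#' @param window Odd window size in samples (default 9).
#' @return Smoothed [cd_spectrum()].
#' @export
smooth_spectrum <- function(spectrum, order = 3L, window = 9L) {
  if (window %% 2L != 1L || window <= order)
    stop("window must be odd and larger than the polynomial order")
  dg <- diff(spectrum$wavelength)
  if (max(dg) - min(dg) > 1e-6 * mean(dg)) stop("grid must be uniform")
  sm <- signal::sgolayfilt(spectrum$value, p = order, n = window)
  out <- spectrum
  out$value <- sm
  out
}

#' Basis set of secondary-structure component spectra
#'
#' @param wavelength Shared wavelength grid (nm).
#' @param components Named list or matrix (columns = classes) of basis
#'   spectra on that grid.
#' @param grouping Named character vector mapping every component name
#'   to one of the three reported classes ("helix", "strand", "coil").
#' @param name Basis-set label.
#' @return list of class `"cd_basis"`.
#' @export
cd_basis <- function(wavelength, components, grouping, name = "basis") {
  comp <- as.matrix(as.data.frame(components))
  if (nrow(comp) != length(wavelength)) stop("component/grid length mismatch")
  if (is.null(colnames(comp))) stop("components must be named")
  missing_map <- setdiff(colnames(comp), names(grouping))
  if (length(missing_map) > 0L)
    stop("grouping map misses class(es): ", paste(missing_map, collapse = ", "))
  out <- list(wavelength = as.numeric(wavelength), components = comp,
              grouping = grouping, name = name)
  class(out) <- "cd_basis"
  out
}

# Interpolate basis components onto a spectrum grid (linear).
interpolate_basis <- function(basis, grid) {
  if (min(grid) > max(basis$wavelength) || max(grid) < min(basis$wavelength))
    stop("spectrum and basis wavelength ranges do not overlap")
  comp <- apply(basis$components, 2L, function(col)
    stats::approx(basis$wavelength, col, xout = grid, rule = 2L)$y)
  matrix(comp, nrow = length(grid),
         dimnames = list(NULL, colnames(basis$components)))
}

# Nonnegative least squares with a sum-to-one constraint, via a
# heavily weighted augmented row solved with Lawson-Hanson NNLS.
simplex_nnls <- function(A, b) {
  w <- 1e6 * max(abs(A), 1)
  fit <- pracma::lsqnonneg(rbind(A, w), c(b, w))
  x <- fit$x
  s <- sum(x)
  if (s > 0) x <- x / s
  x
}

#' Deconvolve a CD spectrum into secondary-structure fractions
#'
#' Finds nonnegative class fractions summing to one, and a single
#' positive scale factor applied to the experimental spectrum,
#' minimizing the residual between the scaled spectrum and the basis
#' combination (alternating closed-form scale and constrained
#' nonnegative least squares). The achieved root-mean-square deviation
#' is reported in kMRE (MRE / 1000).
#'
#' @param spectrum A [cd_spectrum()] in MRE.
#' @param basis A [cd_basis()].
#' @param max_iter,tol Alternation controls.
#' @return list: `fractions` (named, sums to 1), `scale`, `rmsd_kmre`,
#'   `fitted` (basis combination on the spectrum grid).
#' @export
deconvolve_cd <- function(spectrum, basis, max_iter = 200L, tol = 1e-12) {
  B <- interpolate_basis(basis, spectrum$wavelength)
  y <- spectrum$value
  s <- 1
  f <- rep(1 / ncol(B), ncol(B))
  last <- Inf
  for (it in seq_len(max_iter)) {
    f <- simplex_nnls(B, s * y)
    pred <- as.numeric(B %*% f)
    if (sum(y * y) > 0) {
      s_new <- sum(y * pred) / sum(y * y)
      if (s_new > 0) s <- s_new
    }
    obj <- mean((s * y - pred)^2)
    if (abs(last - obj) <= tol * max(obj, 1e-30)) break
    last <- obj
  }
  pred <- as.numeric(B %*% f)
  rmsd <- sqrt(mean((s * y - pred)^2)) / 1000
  list(fractions = stats::setNames(as.numeric(f), colnames(B)),
       scale = s, rmsd_kmre = rmsd, fitted = pred)
}

#' Select the best basis set for a spectrum
#'
#' Deconvolves against each candidate and keeps the one with the
#' lowest post-scaling RMSD; ties break by candidate order (noted via
#' a message).
#'
#' @param spectrum A [cd_spectrum()].
#' @param candidates list of [cd_basis()] objects.
#' @return list: `best` (the winning basis), `fit` (its deconvolution),
#'   `table` (data.frame: name, rmsd_kmre per candidate).
#' @export
select_basis <- function(spectrum, candidates) {
  stopifnot(length(candidates) >= 1L)
  fits <- lapply(candidates, function(b) deconvolve_cd(spectrum, b))
  rmsds <- vapply(fits, function(f) f$rmsd_kmre, numeric(1L))
  best <- which.min(rmsds)
  if (sum(abs(rmsds - rmsds[best]) < 1e-12) > 1L)
    message("basis-set RMSD tie; keeping the first candidate in order")
  list(best = candidates[[best]], fit = fits[[best]],
       table = data.frame(
         name = vapply(candidates, function(b) b$name, character(1L)),
         rmsd_kmre = rmsds, stringsAsFactors = FALSE))
}

#' Group deconvolved fractions into the three reported classes
#'
#' @param fractions Named fractions from [deconvolve_cd()].
#' @param basis The [cd_basis()] holding the grouping map.
#' @return Named numeric vector (helix, strand, coil) summing to the
#'   input total.
#' @export
group_classes <- function(fractions, basis) {
  unmapped <- setdiff(names(fractions), names(basis$grouping))
  if (length(unmapped) > 0L)
    stop("no grouping for class(es): ", paste(unmapped, collapse = ", "))
  groups <- c("helix", "strand", "coil")
  out <- vapply(groups, function(g)
    sum(fractions[names(fractions)[basis$grouping[names(fractions)] == g]]),
    numeric(1L))
  stats::setNames(out, groups)
}

#' Read a two-column spectrum file with a YAML sidecar
#'
#' The data file is TSV/CSV with columns wavelength_nm and value; an
#' optional `<file>.yaml` sidecar supplies `unit`, `path_cm`,
#' `conc_mg_ml`, `mw_kda`.
#'
#' @param path Data file path.
#' @return A [cd_spectrum()].
#' @export
read_cd_spectrum <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep)
  meta <- list()
  side <- paste0(path, ".yaml")
  if (file.exists(side)) meta <- yaml::read_yaml(side)
  cd_spectrum(d[[1L]], d[[2L]],
              unit = meta$unit %||% "mdeg",
              path_cm = meta$path_cm %||% NA_real_,
              conc_mg_ml = meta$conc_mg_ml %||% NA_real_,
              mw_kda = meta$mw_kda %||% NA_real_)
}

#' Load a basis set from a directory of component tables
#'
#' Expects `components.tsv` (wavelength_nm column plus one column per
#' class) and `grouping.yaml` (class -> helix/strand/coil map).
#'
#' @param dir Directory path.
#' @param name Label (default: directory basename).
#' @return A [cd_basis()].
#' @export
read_cd_basis <- function(dir, name = basename(dir)) {
  d <- utils::read.table(file.path(dir, "components.tsv"),
                         header = TRUE, sep = "\t")
  gmap <- unlist(yaml::read_yaml(file.path(dir, "grouping.yaml")))
  cd_basis(d[[1L]], d[, -1L, drop = FALSE], gmap, name = name)
}
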