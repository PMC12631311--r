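# Block-averaged free-energy surfaces over two collective variables.
#
# The trajectory tail (after discarding an equilibration span) is cut
# into equal time windows; each window yields a normalized bivariate
# histogram H(i, j). The surface is the Boltzmann inversion of the
# window-averaged histogram,
#   F_i = -kB T [ ln(Hbar_i) - ln(max(Hbar_i)) ],
# so the minimum of F is 0 kJ/mol, with the between-window standard
# error of the mean propagated through the logarithm:
#   err_i = kB T * sem(H(i, .)) / Hbar_i.

.kb_kj <- 0.0083145  # Boltzmann constant, kJ/(mol K)

#' Block-averaged bivariate histograms of two collective variables
#'
#' @param cv1,cv2 [cv_series()] objects aligned on identical frame
#'   times (cv1 is the first histogram axis).
#' @param discard_ns Equilibration span to drop from the start (ns).
#' @param window_ns Block window length (ns).
#' @param bins Number of bins per axis (default 50), or a list
#'   `list(breaks1, breaks2)` of explicit bin edges.
#' @param pad Fractional range padding used when deriving edges from
#'   the observed CV ranges (default 0.05).
#' @return list of class `"block_histograms"`: `H` (array nb1 x nb2 x
#'   N, each window summing to 1), `breaks1`, `breaks2`, `mid1`,
#'   `mid2`, `window_ns`, `discard_ns`, `n_windows`.
#' @export
block_histograms <- function(cv1, cv2, discard_ns = 50, window_ns = 10,
                             bins = 50L, pad = 0.05) {
  if (nrow(cv1) != nrow(cv2) || any(abs(cv1$time - cv2$time) > 1e-9))
    stop("cv1 and cv2 must be aligned on the same frames")
  rel <- cv1$time   # discard is measured on the series' own time axis
  keep <- rel > discard_ns
  if (!any(keep)) stop("no frames remain after the discard span")
  x <- cv1$value[keep]
  y <- cv2$value[keep]
  trel <- rel[keep] - discard_ns
  span <- max(trel)
  n_win <- as.integer(floor(span / window_ns + 1e-9))
  if (n_win < 2L) stop("need at least 2 complete windows")
  if (span - n_win * window_ns > 1e-9)
    warning(sprintf("trailing %.3g ns (< one window) dropped", span - n_win * window_ns))
  win <- ceiling(trel / window_ns - 1e-9)
  win[win < 1L] <- 1L
  inside <- win <= n_win
  x <- x[inside]; y <- y[inside]; win <- win[inside]

  if (is.list(bins)) {
    br1 <- bins[[1L]]; br2 <- bins[[2L]]
  } else {
    r1 <- range(x); r2 <- range(y)
    e1 <- diff(r1) * pad + 1e-12; e2 <- diff(r2) * pad + 1e-12
    br1 <- seq(r1[1L] - e1, r1[2L] + e1, length.out = bins + 1L)
    br2 <- seq(r2[1L] - e2, r2[2L] + e2, length.out = bins + 1L)
  }
  nb1 <- length(br1) - 1L; nb2 <- length(br2) - 1L
  H <- array(0, c(nb1, nb2, n_win))
  i1 <- findInterval(x, br1, rightmost.closed = TRUE, all.inside = TRUE)
  i2 <- findInterval(y, br2, rightmost.closed = TRUE, all.inside = TRUE)
  for (j in seq_len(n_win)) {
    sel <- win == j
    if (!any(sel)) stop("window ", j, " contains no frames")
    tab <- table(factor(i1[sel], levels = seq_len(nb1)),
                 factor(i2[sel], levels = seq_len(nb2)))
    H[, , j] <- as.numeric(tab) / sum(tab)
  }
  out <- list(H = H, breaks1 = br1, breaks2 = br2,
              mid1 = (br1[-1L] + br1[-length(br1)]) / 2,
              mid2 = (br2[-1L] + br2[-length(br2)]) / 2,
              cv1_name = attr(cv1, "cv_name"), cv2_name = attr(cv2, "cv_name"),
              window_ns = window_ns, discard_ns = discard_ns,
              n_windows = n_win)
  class(out) <- "block_histograms"
  out
}

#' Window-averaged histogram
#'
#' Elementwise mean of the per-window normalized histograms.
#'
#' @param stack A [block_histograms()] object.
#' @return Matrix (nb1 x nb2) summing to 1.
#' @export
average_histogram <- function(stack) {
  stopifnot(inherits(stack, "block_histograms"), stack$n_windows >= 2L)
  apply(stack$H, c(1L, 2L), mean)
}

#' Boltzmann inversion of a probability histogram
#'
#' `F = -kB T [ln(H) - ln(max(H))]` in kJ/mol; the modal bin has
#' F = 0 and unvisited (zero-probability) bins are masked as NA.
#'
#' @param h Normalized histogram (matrix or vector).
#' @param temperature Temperature in K (default 298.15).
#' @return Object shaped like `h`: free energy in kJ/mol, NA where
#'   `h` is 0.
#' @export
boltzmann_invert <- function(h, temperature = 298.15) {
  stopifnot(temperature > 0)
  if (all(h == 0)) stop("all-zero histogram cannot be inverted")
  hmax <- max(h)
  f <- -.kb_kj * temperature * (log(h) - log(hmax))
  f[h == 0] <- NA_real_
  f
}

#' Free-energy surface with propagated block error
#'
#' @param stack A [block_histograms()] object.
#' @param temperature Temperature in K.
#' @return list of class `"free_energy_surface"`: `F` and `error`
#'   (nb1 x nb2 matrices, kJ/mol, NA where unvisited), `mid1`, `mid2`,
#'   `temperature`, `n_windows`.
#' @export
free_energy_surface <- function(stack, temperature = 298.15) {
  hbar <- average_histogram(stack)
  f <- boltzmann_invert(hbar, temperature)
  err <- fes_error(stack, temperature)
  out <- list(F = f, error = err, mid1 = stack$mid1, mid2 = stack$mid2,
              cv1_name = stack$cv1_name, cv2_name = stack$cv2_name,
              temperature = temperature, n_windows = stack$n_windows)
  class(out) <- "free_energy_surface"
  out
}

#' Per-bin error of the free-energy surface
#'
#' Delta-method propagation of the between-window standard error of
#' the mean histogram through the logarithm:
#' `err_i = kB T sem(H(i, .)) / Hbar_i`. The alternative estimator
#' (invert each window, then take the spread of the per-window
#' surfaces) is available via `method = "invert_first"`.
#'
#' @param stack A [block_histograms()] object.
#' @param temperature Temperature in K.
#' @param method "delta" (default) or "invert_first".
#' @return Matrix of errors (kJ/mol), NA where unvisited.
#' @export
fes_error <- function(stack, temperature = 298.15,
                      method = c("delta", "invert_first")) {
  method <- match.arg(method)
  n <- stack$n_windows
  hbar <- average_histogram(stack)
  if (method == "delta") {
    sdm <- apply(stack$H, c(1L, 2L), stats::sd) / sqrt(n)
    err <- .kb_kj * temperature * sdm / hbar
    err[hbar == 0] <- NA_real_
  } else {
    fw <- array(NA_real_, dim(stack$H))
    for (j in seq_len(n)) {
      hj <- stack$H[, , j]
      fj <- suppressWarnings(-.kb_kj * temperature * log(hj))
      fj[hj == 0] <- NA_real_
      fw[, , j] <- fj
    }
    err <- apply(fw, c(1L, 2L), function(v) {
      v <- v[is.finite(v)]
      if (length(v) < 2L) return(NA_real_)
      stats::sd(v) / sqrt(length(v))
    })
    err[hbar == 0] <- NA_real_
  }
  attr(err, "method") <- method
  err
}

#' One-dimensional free-energy profile by marginalization
#'
#' Marginalizes each window's probability onto one CV axis, averages
#' over windows, Boltzmann-inverts, and propagates the between-window
#' error. Because marginalization and window-averaging are both
#' linear, the profile equals the inversion of the marginal of the
#' averaged histogram.
#'
#' @param stack A [block_histograms()] object.
#' @param axis 1 (cv1) or 2 (cv2).
#' @param temperature Temperature in K.
#' @return data.frame: `center`, `prob`, `F` (kJ/mol), `error`
#'   (kJ/mol), NA rows where unvisited; attribute `temperature`.
#' @export
project_1d <- function(stack, axis = 1L, temperature = 298.15) {
  stopifnot(axis %in% c(1L, 2L))
  marg_axis <- if (axis == 1L) 1L else 2L
  n <- stack$n_windows
  M <- apply(stack$H, c(marg_axis, 3L), sum)  # bins x windows
  pbar <- rowMeans(M)
  f <- boltzmann_invert(pbar, temperature)
  sem <- apply(M, 1L, stats::sd) / sqrt(n)
  err <- .kb_kj * temperature * sem / pbar
  err[pbar == 0] <- NA_real_
  out <- data.frame(center = if (axis == 1L) stack$mid1 else stack$mid2,
                    prob = pbar, F = f, error = err)
  attr(out, "temperature") <- temperature
  attr(out, "n_windows") <- n
  out
}

#' Free-energy difference between two basins of a 1D profile
#'
#' Sums the window-averaged probability over each basin's CV range and
#' reports `dF = F(basin2) - F(basin1) = -kB T ln(p2 / p1)` together
#' with a conservative error band: the per-basin errors
#' `kB T sem(p_k) / pbar_k` are added (not combined in quadrature,
#' since basin occupancies are anticorrelated) and scaled by the
#' two-sided 97.5% Student-t quantile at N - 1 window degrees of
#' freedom, giving a 95%-level recovery band.
#'
#' @param stack A [block_histograms()] object.
#' @param axis 1 or 2: which CV the basins are defined on.
#' @param basin1,basin2 Length-2 numeric ranges on that CV.
#' @param temperature Temperature in K.
#' @return list: `delta_f` (kJ/mol), `band` (kJ/mol), `p1`, `p2`,
#'   `err1`, `err2`, `n_windows`.
#' @export
basin_delta_f <- function(stack, axis, basin1, basin2,
                          temperature = 298.15) {
  mids <- if (axis == 1L) stack$mid1 else stack$mid2
  M <- apply(stack$H, c(if (axis == 1L) 1L else 2L, 3L), sum)
  in1 <- mids >= basin1[1L] & mids <= basin1[2L]
  in2 <- mids >= basin2[1L] & mids <= basin2[2L]
  if (!any(in1) || !any(in2)) stop("empty basin range")
  p1w <- colSums(M[in1, , drop = FALSE])
  p2w <- colSums(M[in2, , drop = FALSE])
  n <- stack$n_windows
  p1 <- mean(p1w); p2 <- mean(p2w)
  if (p1 <= 0 || p2 <= 0) stop("a basin has zero occupancy")
  kt <- .kb_kj * temperature
  err1 <- kt * stats::sd(p1w) / sqrt(n) / p1
  err2 <- kt * stats::sd(p2w) / sqrt(n) / p2
  list(delta_f = -kt * (log(p2) - log(p1)),
       band = stats::qt(0.975, n - 1L) * (err1 + err2),
       p1 = p1, p2 = p2, err1 = err1, err2 = err2, n_windows = n)
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf("free_energy_surface: %d x %d bins, T = %.2f K, N = %d windows\n",
              nrow(x$F), ncol(x$F), x$temperature, x$n_windows))
  cat(sprintf("  F range (visited): 0 .. %.3f kJ/mol; %d unvisited bins\n",
              max(x$F, na.rm = TRUE), sum(is.na(x$F))))
  invisible(x)
}

#' Heat-map plot of a free-energy surface
#'
#' Unvisited bins render blank.
#'
#' @param x A [free_energy_surface()] object.
#' @param ... Passed to [graphics::image()].
#' @export
plot.free_energy_surface <- function(x, ...) {
  graphics::image(x$mid1, x$mid2, x$F, xlab = x$cv1_name %||% "cv1",
                  ylab = x$cv2_name %||% "cv2",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
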