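#' Collective-variable series
#'
#' Per-frame values of a named scalar collective variable, aligned with
#' trajectory frame times.
#'
#' @param name CV name (e.g. "beta_rmsd", "distance").
#' @param unit Unit string ("" for dimensionless, "A" for Angstrom).
#' @param time Frame times in ns (strictly increasing).
#' @param value Numeric per-frame values.
#' @return data.frame of class `"cv_series"` with columns `time` and
#'   `value`, and attributes `cv_name`, `cv_unit`.
#' @export
cv_series <- function(name, unit, time, value) {
  if (length(time) != length(value)) stop("time and value lengths differ")
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("cv_series times must be strictly increasing")
  out <- data.frame(time = as.numeric(time), value = as.numeric(value))
  attr(out, "cv_name") <- name
  attr(out, "cv_unit") <- unit
  class(out) <- c("cv_series", "data.frame")
  out
}

#' @export
print.cv_series <- function(x, ...) {
  cat(sprintf("cv_series '%s' [%s]: %d frames, t = %.4g..%.4g ns\n",
              attr(x, "cv_name"), attr(x, "cv_unit"), nrow(x),
              x$time[1L], x$time[nrow(x)]))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}
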