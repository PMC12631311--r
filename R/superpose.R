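#' Kabsch superposition of two coordinate sets
#'
#' Finds the rigid transform (rotation + translation) minimizing the
#' mass-unweighted RMSD between paired atoms, by singular value
#' decomposition of the cross-covariance matrix with a proper-rotation
#' (determinant) correction.
#'
#' @param mobile numeric matrix (n x 3) to be moved onto `reference`.
#' @param reference numeric matrix (n x 3).
#' @param fit logical/integer selection of rows used for the fit
#'   (default: all rows). RMSD is reported over the fit selection.
#' @return list with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `xyz %*% t(rotation) + translation`), `rmsd` (Angstrom)
#'   and `transform`, a function applying the fit to any n x 3 matrix.
#' @export
#' @examples
#' a <- matrix(rnorm(12), 4, 3)
#' fit <- kabsch_superpose(a, a)
#' stopifnot(fit$rmsd < 1e-12)
kabsch_superpose <- function(mobile, reference, fit = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!is.null(fit)) {
    mf <- mobile[fit, , drop = FALSE]
    rf <- reference[fit, , drop = FALSE]
  } else {
    mf <- mobile
    rf <- reference
  }
  if (nrow(mf) != nrow(rf)) stop("selections must pair equal atom counts")
  if (nrow(mf) < 3L) stop("superposition needs at least 3 paired atoms")
  cm <- colMeans(mf)
  cr <- colMeans(rf)
  A <- sweep(mf, 2L, cm)
  B <- sweep(rf, 2L, cr)
  # collinearity check: rank of the fit selection point cloud
  sv_a <- svd(A)$d
  if (sv_a[2L] < 1e-8 * max(sv_a[1L], 1))
    stop("degenerate (collinear) fit selection")
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  tr <- cr - as.numeric(R %*% cm)
  moved <- sweep(A %*% t(R), 2L, cr, "+")
  rmsd <- sqrt(mean(rowSums((moved - rf)^2)))
  transform <- function(xyz) sweep(as.matrix(xyz) %*% t(R), 2L, tr, "+")
  list(rotation = R, translation = tr, rmsd = rmsd, transform = transform)
}

# RMSD between two coordinate sets after optimal superposition on `fit`
# rows, measured over `measure` rows (defaults: all rows for both).
fit_rmsd <- function(mobile, reference, fit = NULL, measure = NULL) {
  k <- kabsch_superpose(mobile, reference, fit = fit)
  if (is.null(measure)) measure <- seq_len(nrow(as.matrix(mobile)))
  moved <- k$transform(as.matrix(mobile)[measure, , drop = FALSE])
  ref <- as.matrix(reference)[measure, , drop = FALSE]
  sqrt(mean(rowSums((moved - ref)^2)))
}

#' Per-frame RMSD of a trajectory against a reference structure
#'
#' Removes rigid-body motion by fitting each frame onto the reference
#' over the fit selection (typically alpha-carbons of the protein core,
#' excluding any purification tag), then measures RMSD over the measure
#' selection.
#'
#' @param traj A [trajectory3d()] object.
#' @param reference A [structure3d] object with a matching atom table.
#' @param fit_sel,measure_sel integer atom indices (see [atom_select()]);
#'   `measure_sel` defaults to `fit_sel`.
#' @return A [cv_series()] named "rmsd" (Angstrom).
#' @export
rmsd_series <- function(traj, reference,
                        fit_sel = atom_select(traj, name = "CA"),
                        measure_sel = fit_sel) {
  if (max(fit_sel, measure_sel) > nrow(reference$atoms) ||
      max(fit_sel, measure_sel) > nrow(traj$atoms))
    stop("selection indices outside the atom tables")
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(i) {
    fit_rmsd(traj$coords[, , i], reference$xyz, fit = fit_sel,
             measure = measure_sel)
  }, numeric(1L))
  cv_series("rmsd", "A", traj$time, vals)
}
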