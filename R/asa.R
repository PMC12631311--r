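# van der Waals radii (Angstrom, Bondi) used for surface calculations.
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, SE = 1.90)

# Theoretical maximum accessible surface areas per residue (Angstrom^2),
# Tien et al. 2013 "theoretical" column; used for relative ASA.
.max_asa <- c(
  ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167, GLU = 223,
  GLN = 225, GLY = 104, HIS = 224, ILE = 197, LEU = 201, LYS = 236,
  MET = 224, PHE = 240, PRO = 159, SER = 155, THR = 172, TRP = 285,
  TYR = 263, VAL = 174
)

# Deterministic quasi-uniform points on the unit sphere (golden-spiral
# lattice), so ASA values are reproducible for a given point count.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over the atomic van der Waals spheres using the
#' classic point-lattice occlusion test. Returns per-atom areas, summed
#' per-residue areas, and residue areas relative to a published table
#' of theoretical per-residue maxima.
#'
#' @param structure A [structure3d] object.
#' @param probe_radius Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sphere test points per atom (default 960). The
#'   discretization error decreases as the point count grows.
#' @return list with `atom` (numeric vector, Angstrom^2), `residue`
#'   (data.frame: resno, resid, asa, rel_asa) and `total`.
#' @export
shrake_rupley_asa <- function(structure, probe_radius = 1.4, n_points = 960L) {
  a <- structure$atoms
  xyz <- structure$xyz
  ele <- toupper(a$element)
  unknown <- setdiff(unique(ele), names(.vdw_radii))
  if (length(unknown) > 0L)
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  radii <- .vdw_radii[ele] + probe_radius
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  asa <- numeric(n)
  # neighbor prefilter on pairwise distances
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    ri <- radii[i]
    nb <- which(d2[i, ] < (ri + radii)^2 & seq_len(n) != i)
    test <- sweep(pts * ri, 2L, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (test[, 1L] - xyz[j, 1L])^2 + (test[, 2L] - xyz[j, 2L])^2 +
             (test[, 3L] - xyz[j, 3L])^2
      exposed <- exposed & dj2 > radii[j]^2
      if (!any(exposed)) break
    }
    asa[i] <- 4 * pi * ri^2 * sum(exposed) / n_points
  }
  key <- paste(a$chain, a$resno)
  uk <- !duplicated(key)
  res <- data.frame(resno = a$resno[uk], resid = a$resid[uk],
                    chain = a$chain[uk], stringsAsFactors = FALSE)
  res$asa <- as.numeric(tapply(asa, factor(key, levels = key[uk]), sum))
  mx <- .max_asa[res$resid]
  res$rel_asa <- ifelse(is.na(mx), NA_real_, res$asa / mx)
  list(atom = asa, residue = res, total = sum(asa))
}
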