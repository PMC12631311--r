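#' Configuration for the beta-RMSD collective variable
#'
#' The beta-RMSD scores, for every ordered pair of non-overlapping
#' 3-residue backbone segments inside a region, how closely the pair
#' resembles an ideal beta-sheet segment pair, via the rational
#' switching function `S(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)` applied
#' to the best-fit RMSD against the ideal template, and sums over
#' pairs. "total" mode is the sum of the parallel and antiparallel
#' contents.
#'
#' @param region Author-numbered residue span (contiguous, >= 6
#'   residues), default the VPS9 beta1 region 1532-1542.
#' @param mode "total", "antiparallel" or "parallel".
#' @param r0_nm Switching-function reference RMSD in nm (default 0.1).
#' @param nn,mm Switching exponents (default 8 and 12, `nn < mm`).
#' @return list of class `"beta_rmsd_config"`.
#' @export
beta_rmsd_config <- function(region = 1532:1542,
                             mode = c("total", "antiparallel", "parallel"),
                             r0_nm = 0.1, nn = 8L, mm = 12L) {
  mode <- match.arg(mode)
  region <- sort(unique(as.integer(region)))
  if (length(region) < 6L) stop("beta-RMSD region must span at least 6 residues")
  if (any(diff(region) != 1L)) stop("beta-RMSD region must be contiguous")
  if (r0_nm <= 0) stop("r0 must be positive")
  if (nn >= mm) stop("switching exponents require n < m")
  out <- list(region = region, mode = mode, r0_nm = r0_nm, nn = nn, mm = mm)
  class(out) <- "beta_rmsd_config"
  out
}

# Rational switching function with the l'Hopital limit n/m at r = r0.
beta_switch <- function(r, r0, nn, mm) {
  x <- r / r0
  ifelse(abs(x - 1) < 1e-9, nn / mm, (1 - x^nn) / (1 - x^mm))
}

# Extract an (n_res x 5 atoms) coordinate block (N, CA, CB, C, O per
# residue, CB synthesized for glycine) for the given residues of one
# frame. Returns a (5 * n_res) x 3 matrix in residue-major order.
backbone_block <- function(atoms, xyz, residues) {
  out <- matrix(NA_real_, 5L * length(residues), 3L)
  for (k in seq_along(residues)) {
    rows <- which(atoms$resno == residues[k])
    if (length(rows) == 0L) stop("residue ", residues[k], " absent")
    nm <- atoms$name[rows]
    for (j in seq_along(c("N", "CA", "CB", "C", "O"))) {
      at <- c("N", "CA", "CB", "C", "O")[j]
      hit <- rows[nm == at]
      if (length(hit) >= 1L) {
        out[(k - 1L) * 5L + j, ] <- xyz[hit[1L], ]
      } else if (at == "CB") {
        gn <- rows[nm == "N"]; gca <- rows[nm == "CA"]; gc <- rows[nm == "C"]
        if (length(gn) < 1L || length(gca) < 1L || length(gc) < 1L)
          stop("cannot synthesize CB for residue ", residues[k])
        out[(k - 1L) * 5L + j, ] <-
          synthesize_cb(xyz[gn[1L], ], xyz[gca[1L], ], xyz[gc[1L], ])
      } else {
        stop("residue ", residues[k], " is missing backbone atom ", at)
      }
    }
  }
  out
}

# Beta-RMSD of a single frame for one register mode.
beta_rmsd_frame <- function(block, n_res, mode, r0_A, nn, mm) {
  template <- beta_template(mode)
  n_seg <- n_res - 2L
  total <- 0
  for (k in seq_len(n_seg)) {
    lmin <- k + 3L
    if (lmin > n_seg) break
    rows_k <- ((k - 1L) * 5L + 1L):((k + 2L) * 5L)
    for (l in lmin:n_seg) {
      rows_l <- ((l - 1L) * 5L + 1L):((l + 2L) * 5L)
      pair <- block[c(rows_k, rows_l), ]
      r <- kabsch_superpose(pair, template)$rmsd
      total <- total + beta_switch(r, r0_A, nn, mm)
    }
  }
  total
}

#' Beta-RMSD content of a residue region along a trajectory
#'
#' @param traj A [trajectory3d()] object whose residues include the
#'   configured region with backbone N, CA, C, O (CB synthesized for
#'   glycine when absent).
#' @param cfg A [beta_rmsd_config()].
#' @return A [cv_series()] named "beta_rmsd" (dimensionless).
#' @export
beta_rmsd <- function(traj, cfg = beta_rmsd_config()) {
  stopifnot(inherits(cfg, "beta_rmsd_config"))
  n_res <- length(cfg$region)
  r0_A <- cfg$r0_nm * 10   # coordinates are in Angstrom
  modes <- if (cfg$mode == "total") c("antiparallel", "parallel") else cfg$mode
  nf <- n_frames(traj)
  vals <- numeric(nf)
  for (i in seq_len(nf)) {
    block <- backbone_block(traj$atoms, traj$coords[, , i], cfg$region)
    vals[i] <- sum(vapply(modes, function(m)
      beta_rmsd_frame(block, n_res, m, r0_A, cfg$nn, cfg$mm), numeric(1L)))
  }
  cv_series("beta_rmsd", "", traj$time, vals)
}

#' Configuration for the probe-loop distance collective variable
#'
#' @param probe Author number of the probe residue (default 1611).
#' @param loop Author-numbered loop span (default 1545-1550); must not
#'   contain the probe.
#' @return list of class `"distance_config"`.
#' @export
distance_config <- function(probe = 1611L, loop = 1545:1550) {
  probe <- as.integer(probe)
  loop <- sort(unique(as.integer(loop)))
  if (probe %in% loop) stop("probe residue must lie outside the loop region")
  out <- list(probe = probe, loop = loop)
  class(out) <- "distance_config"
  out
}

#' Distance between a probe C-alpha and a loop C-alpha centroid
#'
#' Per frame, the Euclidean distance from the probe residue's C-alpha
#' to the unweighted centroid of the loop residues' C-alpha atoms.
#'
#' @param traj A [trajectory3d()] object.
#' @param cfg A [distance_config()].
#' @return A [cv_series()] named "distance" (Angstrom).
#' @export
probe_loop_distance <- function(traj, cfg = distance_config()) {
  stopifnot(inherits(cfg, "distance_config"))
  a <- traj$atoms
  ip <- which(a$resno == cfg$probe & a$name == "CA")
  if (length(ip) != 1L) stop("probe residue C-alpha not found (or ambiguous)")
  il <- vapply(cfg$loop, function(r) {
    hit <- which(a$resno == r & a$name == "CA")
    if (length(hit) != 1L) stop("loop residue ", r, " C-alpha not found")
    hit
  }, integer(1L))
  nf <- n_frames(traj)
  vals <- vapply(seq_len(nf), function(i) {
    xyz <- traj$coords[, , i]
    ctr <- colMeans(xyz[il, , drop = FALSE])
    sqrt(sum((xyz[ip, ] - ctr)^2))
  }, numeric(1L))
  cv_series("distance", "A", traj$time, vals)
}
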