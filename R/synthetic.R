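# Seeded synthetic-data generators. Every generator is a pure function
# of (spec, seed): the RNG state is isolated and restored, so the same
# seed reproduces output bit-for-bit without disturbing the caller's
# random stream.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification of the two-state (folded/unfolded) synthetic system
#'
#' Emulates a dynamic equilibrium between a folded beta-hairpin and an
#' unstructured coil in a short region, with a probe residue whose
#' distance to a neighboring loop co-varies with the state: in-contact
#' around 12 A when folded, around 17.5 A when unfolded. Defaults
#' mirror the replica analysis scales: a 200 ns span sampled every
#' 0.4 ns, of which the first 50 ns are discarded and the remainder
#' cut into 10 ns blocks (15 windows).
#'
#' @param region Hairpin region residues (default 1532:1542).
#' @param loop Loop residues (default 1545:1550).
#' @param probe Probe residue number (default 1611).
#' @param p_folded Stationary folded occupancy (default 0.6).
#' @param flip Total Markov switching rate a + b per frame (default
#'   0.8; lag-1 state autocorrelation is 1 - flip).
#' @param d_folded,d_unfolded Mean probe-loop distances (A).
#' @param d_sd_folded,d_sd_unfolded In-state distance spreads (A).
#' @param noise_sigma Isotropic coordinate noise sigma (A).
#' @param n_frames Number of frames (default 500).
#' @param dt_ns Sampling interval (default 0.4 ns; frame i has time
#'   `i * dt_ns`, so the span is `n_frames * dt_ns`).
#' @return list of class `"two_state_spec"`.
#' @export
two_state_spec <- function(region = 1532:1542, loop = 1545:1550,
                           probe = 1611L, p_folded = 0.6, flip = 0.8,
                           d_folded = 12, d_unfolded = 17.5,
                           d_sd_folded = 0.8, d_sd_unfolded = 1.0,
                           noise_sigma = 0.15, n_frames = 500L,
                           dt_ns = 0.4) {
  stopifnot(p_folded > 0, p_folded <= 1, flip > 0, flip <= 1,
            noise_sigma >= 0, n_frames >= 2L, dt_ns > 0)
  out <- list(region = sort(as.integer(region)), loop = sort(as.integer(loop)),
              probe = as.integer(probe), p_folded = p_folded, flip = flip,
              d_folded = d_folded, d_unfolded = d_unfolded,
              d_sd_folded = d_sd_folded, d_sd_unfolded = d_sd_unfolded,
              noise_sigma = noise_sigma, n_frames = as.integer(n_frames),
              dt_ns = dt_ns)
  class(out) <- "two_state_spec"
  out
}

# Markov state path with stationary folded occupancy p and total
# switching rate `flip`: P(F->U) = flip * (1 - p), P(U->F) = flip * p.
markov_states <- function(n, p_folded, flip) {
  a <- flip * (1 - p_folded)   # leave folded
  b <- flip * p_folded         # leave unfolded
  s <- integer(n)
  s[1L] <- if (stats::runif(1L) < p_folded) 1L else 0L
  u <- stats::runif(n)
  for (i in 2:n) {
    s[i] <- if (s[i - 1L] == 1L) {
      if (u[i] < a) 0L else 1L
    } else {
      if (u[i] < b) 1L else 0L
    }
  }
  s
}

# Reference folded conformation for the hairpin region + loop: the
# ideal antiparallel template placed at two 3-residue strands, with
# the remaining residues bridged/extended along smooth arcs. Returns
# a list of per-residue 5 x 3 atom blocks (N, CA, CB, C, O) keyed by
# residue number, plus the strand residue numbers used.
folded_reference <- function(region, chain_res) {
  tpl <- beta_template("antiparallel")
  n_reg <- length(region)
  sA <- region[2:4]                       # strand A residues
  sB <- region[(n_reg - 3L):(n_reg - 1L)] # strand B residues
  blocks <- list()
  for (k in 1:3) blocks[[as.character(sA[k])]] <- tpl[((k - 1L) * 5L + 1L):(k * 5L), ]
  for (k in 1:3) blocks[[as.character(sB[k])]] <- tpl[((k + 2L) * 5L + 1L):((k + 3L) * 5L), ]
  ca <- function(res) blocks[[as.character(res)]][2L, ]
  stepA <- ca(sA[3L]) - ca(sA[2L])        # extension steps along strands
  stepB <- ca(sB[3L]) - ca(sB[2L])
  # extend strand A backward to the chain start
  back <- rev(chain_res[chain_res < sA[1L]])
  for (i in seq_along(back))
    blocks[[as.character(back[i])]] <-
      sweep(blocks[[as.character(sA[1L])]], 2L, i * stepA, "-")
  # turn residues between the strands: linear bridge with a bulge
  mid <- chain_res[chain_res > sA[3L] & chain_res < sB[1L]]
  pA <- ca(sA[3L]); pB <- ca(sB[1L])
  bulge <- 4 * unitv(vcross(stepA, pB - pA))
  for (i in seq_along(mid)) {
    f <- i / (length(mid) + 1L)
    ctr <- pA + f * (pB - pA) + sin(pi * f) * bulge
    blocks[[as.character(mid[i])]] <-
      sweep(blocks[[as.character(sA[3L])]], 2L, ctr - pA, "+")
  }
  # extend strand B forward through the chain end (region tail + loop)
  fwd <- chain_res[chain_res > sB[3L]]
  for (i in seq_along(fwd))
    blocks[[as.character(fwd[i])]] <-
      sweep(blocks[[as.character(sB[3L])]], 2L, i * stepB, "+")
  list(blocks = blocks, strandA = sA, strandB = sB)
}

# Coil conformation: backbone torsions drawn from a broad coil
# distribution (mix of polyproline-II-like and extended draws).
coil_conformation <- function(residues) {
  n <- length(residues)
  phi <- stats::runif(n, -150, -60)
  psi <- ifelse(stats::runif(n) < 0.7,
                stats::runif(n, 100, 175),
                stats::runif(n, -60, 0))
  build_backbone(n, phi = phi, psi = psi, resno = residues)
}

#' Generate a two-state synthetic trajectory with known state labels
#'
#' Frames alternate, via a two-state Markov chain, between (a) a
#' beta-hairpin conformation of the region built from the ideal
#' antiparallel template and (b) a freshly drawn coil conformation,
#' each with isotropic Gaussian coordinate noise. The probe residue's
#' C-alpha is placed so its distance to the loop C-alpha centroid is
#' `d_folded` or `d_unfolded` (plus in-state spread) according to the
#' state.
#'
#' @param spec A [two_state_spec()].
#' @param seed Integer seed; the output is a pure function of
#'   (spec, seed).
#' @return list: `trajectory` (a [trajectory3d()]), `states`
#'   (integer vector, 1 = folded), `spec`.
#' @export
gen_two_state_trajectory <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "two_state_spec"))
  with_seed(seed, {
    chain_res <- seq(min(spec$region), max(spec$loop))
    chain_res <- chain_res[chain_res < spec$probe]
    fref <- folded_reference(spec$region, chain_res)
    states <- markov_states(spec$n_frames, spec$p_folded, spec$flip)
    atom_names <- c("N", "CA", "CB", "C", "O")
    all_res <- c(chain_res, spec$probe)
    atoms <- data.frame(
      name = rep(atom_names, length(all_res)),
      element = rep(substr(atom_names, 1L, 1L), length(all_res)),
      resno = rep(all_res, each = 5L),
      resid = "ALA", chain = "A", stringsAsFactors = FALSE)
    nat <- nrow(atoms)
    loop_rows <- function(xyz_chain) {
      idx <- which(rep(chain_res, each = 5L) %in% spec$loop &
                   rep(atom_names, length(chain_res)) == "CA")
      colMeans(xyz_chain[idx, , drop = FALSE])
    }
    res_tpl <- fref$blocks[[as.character(fref$strandA[1L])]]
    res_tpl <- sweep(res_tpl, 2L, res_tpl[2L, ])  # residue template at origin
    coords <- array(NA_real_, c(nat, 3L, spec$n_frames))
    for (i in seq_len(spec$n_frames)) {
      if (states[i] == 1L) {
        xyz_chain <- do.call(rbind, lapply(as.character(chain_res),
                                           function(r) fref$blocks[[r]]))
        d_mean <- spec$d_folded; d_sd <- spec$d_sd_folded
      } else {
        xyz_chain <- coil_conformation(chain_res)$xyz
        d_mean <- spec$d_unfolded; d_sd <- spec$d_sd_unfolded
      }
      ctr <- loop_rows(xyz_chain)
      dir <- unitv(stats::rnorm(3L))
      d <- max(stats::rnorm(1L, d_mean, d_sd), 1)
      probe_xyz <- sweep(res_tpl, 2L, ctr + d * dir, "+")
      xyz <- rbind(xyz_chain, probe_xyz)
      if (spec$noise_sigma > 0) {
        # perturb the chain isotropically; keep the probe-loop distance
        # exact by translating the probe with the loop centroid shift
        noise <- matrix(stats::rnorm(length(xyz_chain), 0, spec$noise_sigma),
                        nrow(xyz_chain), 3L)
        xyz_chain2 <- xyz_chain + noise
        shift <- loop_rows(xyz_chain2) - ctr
        xyz <- rbind(xyz_chain2, sweep(probe_xyz, 2L, shift, "+"))
      }
      coords[, , i] <- xyz
    }
    traj <- trajectory3d(atoms, coords, time = seq_len(spec$n_frames) * spec$dt_ns)
    list(trajectory = traj, states = states, spec = spec)
  })
}

#' Generate a two-state synthetic collective-variable series
#'
#' The collective-variable-level counterpart of
#' [gen_two_state_trajectory()]: the same Markov state path, but
#' emitting the (beta-RMSD, distance) pair directly from in-state
#' distributions instead of building coordinates. Used for
#' parameter-recovery studies over many seeds, where only the CV
#' statistics matter.
#'
#' @param spec A [two_state_spec()].
#' @param seed Integer seed.
#' @param beta_folded,beta_unfolded Mean in-state beta-RMSD values.
#' @param beta_sd_folded,beta_sd_unfolded In-state spreads (values are
#'   truncated at 0).
#' @return list: `beta` and `dist` ([cv_series()] objects), `states`.
#' @export
gen_two_state_cv <- function(spec, seed = 1L, beta_folded = 1.0,
                             beta_unfolded = 0.05, beta_sd_folded = 0.15,
                             beta_sd_unfolded = 0.03) {
  stopifnot(inherits(spec, "two_state_spec"))
  with_seed(seed, {
    states <- markov_states(spec$n_frames, spec$p_folded, spec$flip)
    folded <- states == 1L
    n <- spec$n_frames
    beta <- ifelse(folded,
                   stats::rnorm(n, beta_folded, beta_sd_folded),
                   stats::rnorm(n, beta_unfolded, beta_sd_unfolded))
    beta <- pmax(beta, 0)
    d <- ifelse(folded,
                stats::rnorm(n, spec$d_folded, spec$d_sd_folded),
                stats::rnorm(n, spec$d_unfolded, spec$d_sd_unfolded))
    tm <- seq_len(n) * spec$dt_ns
    list(beta = cv_series("beta_rmsd", "", tm, beta),
         dist = cv_series("distance", "A", tm, d),
         states = states)
  })
}

#' Generate a synthetic CD spectrum from known fractions
#'
#' Linear combination of basis spectra plus iid Gaussian noise.
#'
#' @param fractions Named nonnegative fractions summing to 1, matching
#'   the basis component names.
#' @param basis A [cd_basis()].
#' @param noise_sd Gaussian noise sigma (same unit as the basis).
#' @param seed Integer seed.
#' @return A [cd_spectrum()] in MRE.
#' @export
gen_cd_spectrum <- function(fractions, basis, noise_sd = 0, seed = 1L) {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be nonnegative and sum to 1")
  if (!all(names(fractions) %in% colnames(basis$components)))
    stop("fraction names must match basis components")
  f <- fractions[colnames(basis$components)]
  f[is.na(f)] <- 0
  y <- as.numeric(basis$components %*% f)
  with_seed(seed, {
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  })
  cd_spectrum(basis$wavelength, y, unit = "MRE")
}

#' Generate a synthetic chromatogram from known species
#'
#' Sum of Gaussian elution peaks centered at the calibration-predicted
#' volumes of the species, heights proportional to amounts, plus
#' Gaussian baseline noise.
#'
#' @param species data.frame with columns `mw_kda`, `amount`.
#' @param cal A [fit_calibration()] object.
#' @param peak_sd_ml Gaussian peak width (mL).
#' @param noise_sd Baseline noise (mAU).
#' @param seed Integer seed.
#' @param volumes Sampling grid (mL), default `seq(8, 20, 0.02)`.
#' @return A [chromatogram()] with attribute `true_volumes`.
#' @export
gen_chromatogram <- function(species, cal, peak_sd_ml = 0.25,
                             noise_sd = 0, seed = 1L,
                             volumes = seq(8, 20, by = 0.02)) {
  if (nrow(species) < 1L || any(species$mw_kda <= 0) || any(species$amount <= 0))
    stop("species must have positive weights and amounts")
  centers <- elution_volume(species$mw_kda, cal)
  y <- rep(0, length(volumes))
  for (i in seq_len(nrow(species)))
    y <- y + species$amount[i] *
      exp(-(volumes - centers[i])^2 / (2 * peak_sd_ml^2))
  with_seed(seed, {
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  })
  out <- chromatogram(volumes, y)
  attr(out, "true_volumes") <- centers
  out
}

#' Generate a minimal two-residue interaction fixture
#'
#' Builds a structure realizing exactly one requested contact geometry
#' (or none), for exercising the interaction detectors against known
#' ground truth. Residues are numbered 1 and 10 so the sequence-
#' separation rule never interferes, and only the atoms needed for
#' the requested contact (plus backbone stubs) are included, with the
#' two backbones kept far apart.
#'
#' @param kind "hydrogen_bond", "salt_bridge", "hydrophobic" or
#'   "none".
#' @param distance Defining distance in A (donor-acceptor, centroid-
#'   centroid, or carbon-carbon according to `kind`).
#' @param angle Donor angle in degrees (hydrogen bonds; default 160).
#' @return A [structure3d] object.
#' @export
gen_interaction_fixture <- function(kind = c("hydrogen_bond", "salt_bridge",
                                             "hydrophobic", "none"),
                                    distance = 3.0, angle = 160) {
  kind <- match.arg(kind)
  if (distance <= 0) stop("distance must be positive")
  mk <- function(resno, resid, names) {
    data.frame(name = names, element = substr(gsub("[0-9]", "", names), 1L, 1L),
               resno = resno, resid = resid, chain = "A",
               stringsAsFactors = FALSE)
  }
  far <- c(0, 0, 12)  # backbone offset keeping stubs out of range
  if (kind == "none") {
    a1 <- mk(1L, "ALA", c("N", "CA", "C", "O"))
    x1 <- rbind(c(0, 0, 0), c(1.46, 0, 0), c(2.0, 1.3, 0), c(1.5, 2.4, 0))
    a2 <- mk(10L, "ALA", c("N", "CA", "C", "O"))
    x2 <- sweep(x1, 2L, c(30, 0, 0), "+")
    return(structure3d(rbind(a1, a2), rbind(x1, x2)))
  }
  if (kind == "hydrogen_bond") {
    if (distance < 1.2) stop("unrealizable hydrogen-bond distance")
    th <- angle * pi / 180
    N <- c(0, 0, 0); H <- c(1, 0, 0)
    u <- c(-cos(th), sin(th), 0)   # H->acceptor direction, angle N-H-A
    s <- cos(th) + sqrt(max(cos(th)^2 - 1 + distance^2, 0))
    A <- H + s * u
    don_names <- c("N", "H", "CA", "C", "O")
    don_xyz <- rbind(N, H, N + c(-0.8, -1.2, 0), N + c(-2.2, -1.4, 0) + far,
                     N + c(-2.7, -2.5, 0) + far)
    acc_names <- c("O", "C", "N", "CA")
    Cc <- A + 1.23 * u
    acc_xyz <- rbind(A, Cc, Cc + c(0, 0, 2) + far, Cc + c(1.2, 0.8, 2) + far)
    atoms <- rbind(mk(10L, "ALA", don_names), mk(1L, "ALA", acc_names))
    return(structure3d(atoms, rbind(don_xyz, acc_xyz)))
  }
  if (kind == "salt_bridge") {
    NZ <- c(0, 0, 0)
    ctr <- c(distance, 0, 0)
    OD1 <- ctr + c(0, 1.1, 0); OD2 <- ctr - c(0, 1.1, 0)
    lys_names <- c("NZ", "CE", "N", "CA", "C", "O")
    lys_xyz <- rbind(NZ, NZ + c(-1.5, 0, 0), NZ + far + c(-4, 0, 0),
                     NZ + far + c(-2.6, 0.6, 0), NZ + far + c(-1.4, -0.3, 0),
                     NZ + far + c(-1.5, -1.5, 0))
    asp_names <- c("OD1", "OD2", "CG", "N", "CA", "C", "O")
    asp_xyz <- rbind(OD1, OD2, ctr + c(0.8, 0, 0), ctr + far + c(4, 0, 0),
                     ctr + far + c(2.6, 0.6, 0), ctr + far + c(1.4, -0.3, 0),
                     ctr + far + c(1.5, -1.5, 0))
    atoms <- rbind(mk(10L, "LYS", lys_names), mk(1L, "ASP", asp_names))
    return(structure3d(atoms, rbind(lys_xyz, asp_xyz)))
  }
  # hydrophobic
  C1 <- c(0, 0, 0); C2 <- c(distance, 0, 0)
  l1_names <- c("CD1", "N", "CA", "C", "O")
  l1_xyz <- rbind(C1, C1 + far + c(-3, 0, 0), C1 + far + c(-1.8, 0.8, 0),
                  C1 + far + c(-0.6, -0.2, 0), C1 + far + c(-0.6, -1.4, 0))
  l2_names <- c("CD1", "N", "CA", "C", "O")
  l2_xyz <- rbind(C2, C2 + far + c(3, 0, 0), C2 + far + c(1.8, 0.8, 0),
                  C2 + far + c(0.6, -0.2, 0), C2 + far + c(0.6, -1.4, 0))
  atoms <- rbind(mk(10L, "LEU", l1_names), mk(1L, "LEU", l2_names))
  structure3d(atoms, rbind(l1_xyz, l2_xyz))
}
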