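# Kabsch-Sander secondary-structure assignment.
#
# Hydrogen bonds are detected with the classic electrostatic model
# E = q1*q2*f*(1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) (kcal/mol), bonded
# when E < -0.5 kcal/mol. Missing backbone amide hydrogens are placed
# 1.0 A from N, anti-parallel to the preceding carbonyl C=O bond (the
# convention of the original dictionary program, which trajectory
# backends reproduce).

.ks_q1q2f <- 0.42 * 0.20 * 332   # kcal*A/mol
.ks_cutoff <- -0.5               # kcal/mol
.ks_ca_prefilter <- 9.0          # A, CA-CA distance prefilter

ks_hbond_energy <- function(n, h, c, o) {
  r_on <- vnorm(o - n); r_ch <- vnorm(c - h)
  r_oh <- vnorm(o - h); r_cn <- vnorm(c - n)
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5) return(-9.9)  # clash convention
  .ks_q1q2f * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

# Collect per-residue backbone coordinates (N, CA, C, O, H) for one
# chain, placing H geometrically when absent. Returns a list of
# matrices keyed by atom, rows = residues in author order.
collect_backbone <- function(atoms, xyz, residues) {
  n_res <- length(residues)
  get1 <- function(resno, name) {
    hit <- which(atoms$resno == resno & atoms$name == name)
    if (length(hit) < 1L) return(rep(NA_real_, 3L))
    xyz[hit[1L], ]
  }
  N <- t(vapply(residues, get1, numeric(3L), name = "N"))
  CA <- t(vapply(residues, get1, numeric(3L), name = "CA"))
  C <- t(vapply(residues, get1, numeric(3L), name = "C"))
  O <- t(vapply(residues, get1, numeric(3L), name = "O"))
  H <- t(vapply(residues, get1, numeric(3L), name = "H"))
  if (anyNA(N) || anyNA(CA) || anyNA(C) || anyNA(O))
    stop("missing backbone atoms in secondary-structure assignment")
  resid <- vapply(residues, function(r)
    atoms$resid[which(atoms$resno == r)[1L]], character(1L))
  for (i in seq_len(n_res)) {
    if (anyNA(H[i, ]) && i > 1L && resid[i] != "PRO")
      H[i, ] <- N[i, ] + 1.0 * unitv(C[i - 1L, ] - O[i - 1L, ])
  }
  list(N = N, CA = CA, C = C, O = O, H = H, resid = resid)
}

#' Assign secondary structure to a single frame
#'
#' Kabsch-Sander hydrogen-bond patterns collapsed to the four classes
#' reported for per-residue probabilities: helix (8-class H, G, I),
#' strand (E, B), turn (T, S) and coil. Chains shorter than 3 residues
#' are all coil.
#'
#' @param frame A [structure3d] object with backbone N, CA, C, O
#'   atoms (amide H placed geometrically when absent).
#' @return data.frame with columns `resno`, `resid`, `class` (factor
#'   with levels helix/strand/turn/coil) and `class8` (DSSP-style
#'   letter, "-" for coil).
#' @export
assign_secondary_structure <- function(frame) {
  atoms <- frame$atoms
  residues <- unique(atoms$resno)
  n <- length(residues)
  out <- data.frame(resno = residues,
                    resid = vapply(residues, function(r)
                      atoms$resid[which(atoms$resno == r)[1L]], character(1L)),
                    stringsAsFactors = FALSE)
  if (n < 3L) {
    out$class <- factor(rep("coil", n), levels = c("helix", "strand", "turn", "coil"))
    out$class8 <- rep("-", n)
    return(out)
  }
  bb <- collect_backbone(atoms, frame$xyz, residues)

  # hb[i, j]: NH of residue i donates to CO of residue j
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    if (anyNA(bb$H[i, ])) next           # no donor (Pro / chain start)
    for (j in seq_len(n)) {
      if (abs(i - j) < 2L) next
      if (vnorm(bb$CA[i, ] - bb$CA[j, ]) > .ks_ca_prefilter) next
      e <- ks_hbond_energy(bb$N[i, ], bb$H[i, ], bb$C[j, ], bb$O[j, ])
      hb[i, j] <- e < .ks_cutoff
    }
  }
  co_nh <- function(a, b) {  # CO of a accepts from NH of b
    if (a < 1L || b < 1L || a > n || b > n) return(FALSE)
    hb[b, a]
  }

  turn3 <- vapply(seq_len(n), function(i) co_nh(i, i + 3L), logical(1L))
  turn4 <- vapply(seq_len(n), function(i) co_nh(i, i + 4L), logical(1L))
  turn5 <- vapply(seq_len(n), function(i) co_nh(i, i + 5L), logical(1L))

  flagH <- flagG <- flagI <- flagE <- flagT <- flagS <- rep(FALSE, n)
  for (i in 2:n) {
    if (turn4[i - 1L] && turn4[i]) flagH[i:min(n, i + 3L)] <- TRUE
    if (turn3[i - 1L] && turn3[i]) flagG[i:min(n, i + 2L)] <- TRUE
    if (turn5[i - 1L] && turn5[i]) flagI[i:min(n, i + 4L)] <- TRUE
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i + 3L) next
      par <- (co_nh(j, i - 1L) && co_nh(i + 1L, j)) ||
             (co_nh(i, j - 1L) && co_nh(j + 1L, i))
      anti <- (co_nh(j, i) && co_nh(i, j)) ||
              (co_nh(j + 1L, i - 1L) && co_nh(i + 1L, j - 1L))
      if (par || anti) flagE[c(i, j)] <- TRUE
    }
  }
  for (i in seq_len(n)) {
    for (k in 3:5) {
      tn <- switch(as.character(k), "3" = turn3, "4" = turn4, "5" = turn5)
      if (tn[i] && i + k <= n) flagT[(i + 1L):(i + k - 1L)] <- TRUE
    }
  }
  if (n >= 5L) {
    for (i in 3:(n - 2L)) {
      a <- bb$CA[i, ] - bb$CA[i - 2L, ]
      b <- bb$CA[i + 2L, ] - bb$CA[i, ]
      if (vec_angle(a, b) > 70) flagS[i] <- TRUE
    }
  }

  class8 <- rep("-", n)
  class8[flagS] <- "S"
  class8[flagT] <- "T"
  class8[flagI] <- "I"
  class8[flagG] <- "G"
  class8[flagE] <- "E"
  class8[flagH] <- "H"

  map4 <- c(H = "helix", G = "helix", I = "helix",
            E = "strand", B = "strand", T = "turn", S = "turn", "-" = "coil")
  out$class <- factor(unname(map4[class8]),
                      levels = c("helix", "strand", "turn", "coil"))
  out$class8 <- class8
  out
}

#' Per-frame secondary-structure labels for a trajectory
#'
#' @param traj A [trajectory3d()] object.
#' @return Character matrix (frames x residues) of 4-class labels, with
#'   residue numbers as column names.
#' @export
ss_trajectory <- function(traj) {
  residues <- unique(traj$atoms$resno)
  nf <- n_frames(traj)
  out <- matrix(NA_character_, nf, length(residues),
                dimnames = list(NULL, residues))
  for (i in seq_len(nf))
    out[i, ] <- as.character(assign_secondary_structure(get_frame(traj, i))$class)
  out
}

#' Per-residue secondary-structure probabilities over replicas
#'
#' Concatenates frames across replica trajectories and divides the
#' number of occurrences of each class by the total frame count, per
#' residue. Also returns each replica's overall class fractions with
#' their across-replica mean and standard deviation.
#'
#' @param trajs A [trajectory3d()] object, a list of them, or a list of
#'   per-frame label matrices as returned by [ss_trajectory()].
#' @return list with `table` (data.frame: resno, helix, strand, turn,
#'   coil; rows sum to 1) and `replica` (data.frame: class, mean, sd,
#'   and one column per replica, as fractions in [0, 1]).
#' @export
ss_probability <- function(trajs) {
  if (inherits(trajs, "trajectory3d") || is.matrix(trajs)) trajs <- list(trajs)
  labs <- lapply(trajs, function(x) if (is.matrix(x)) x else ss_trajectory(x))
  cols <- colnames(labs[[1L]])
  if (!all(vapply(labs, function(m) identical(colnames(m), cols), logical(1L))))
    stop("replicas must share one residue set")
  classes <- c("helix", "strand", "turn", "coil")
  pooled <- do.call(rbind, labs)
  tab <- t(apply(pooled, 2L, function(col)
    vapply(classes, function(k) mean(col == k), numeric(1L))))
  table <- data.frame(resno = as.integer(cols), tab, row.names = NULL)
  names(table)[-1L] <- classes
  rep_frac <- vapply(labs, function(m)
    vapply(classes, function(k) mean(m == k), numeric(1L)),
    numeric(length(classes)))
  rep_frac <- matrix(rep_frac, nrow = length(classes),
                     dimnames = list(classes, paste0("replica", seq_along(labs))))
  replica <- data.frame(class = classes,
                        mean = rowMeans(rep_frac),
                        sd = apply(rep_frac, 1L, stats::sd),
                        rep_frac, row.names = NULL)
  list(table = table, replica = replica)
}
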