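# Geometric noncovalent-interaction detection between a probe residue
# and the rest of the protein, following the criteria of the standard
# protein-interaction profiler: hydrogen bond when donor-acceptor
# distance <= 4.1 A with donor angle >= 100 degrees; salt bridge when
# charged-group centroids of opposite sign lie within 5.5 A;
# hydrophobic contact when two apolar carbons lie within 4.0 A.

.hbond_dist_max <- 4.1     # A, donor-acceptor
.hbond_angle_min <- 100    # degrees at the donor
.saltbridge_dist_max <- 5.5
.hydrophobic_dist_max <- 4.0

# Side-chain donor atoms (name -> antecedent heavy atom) per residue;
# the backbone amide N (antecedent CA) is a donor for every residue
# except proline.
.sc_donors <- list(
  SER = c(OG = "CB"), THR = c(OG1 = "CB"), TYR = c(OH = "CZ"),
  ASN = c(ND2 = "CG"), GLN = c(NE2 = "CD"), LYS = c(NZ = "CE"),
  ARG = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"), TRP = c(NE1 = "CD1"),
  HIS = c(ND1 = "CG", NE2 = "CD2")
)
# Side-chain acceptor atoms per residue; the backbone carbonyl O is an
# acceptor for every residue.
.sc_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = c("OD1"),
  GLN = c("OE1"), SER = c("OG"), THR = c("OG1"), TYR = c("OH"),
  HIS = c("ND1", "NE2")
)
# Charged groups at standard protonation (Asp/Glu deprotonated,
# Lys/Arg protonated, His neutral).
.charged_groups <- list(
  LYS = list(sign = +1, atoms = c("NZ")),
  ARG = list(sign = +1, atoms = c("NE", "NH1", "NH2")),
  ASP = list(sign = -1, atoms = c("OD1", "OD2")),
  GLU = list(sign = -1, atoms = c("OE1", "OE2"))
)
# Apolar carbons (bonded only to C/H) per residue type.
.apolar_carbons <- list(
  ALA = c("CB"), VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"), ILE = c("CB", "CG1", "CG2", "CD1"),
  MET = c("CB"), PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  PRO = c("CB", "CG"), LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"),
  GLU = c("CB", "CG"), GLN = c("CB", "CG"), ASP = c("CB"), ASN = c("CB"),
  THR = c("CG2"), HIS = c("CB"), CYS = c("CB"), GLY = character(0),
  SER = c("CB")
)

.known_residues <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLU", "GLN",
                     "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                     "PRO", "SER", "THR", "TRP", "TYR", "VAL")

interaction_types <- c("hydrogen_bond", "salt_bridge", "hydrophobic")
.unsupported_types <- c("metal_complex", "pi_stacking", "pi_cation", "halogen_bond")

# Gather candidate interaction atoms of one residue in one frame.
residue_chem <- function(atoms, xyz, resno) {
  rows <- which(atoms$resno == resno)
  resid <- atoms$resid[rows[1L]]
  if (!resid %in% .known_residues)
    stop("unknown residue type: ", resid)
  nm <- atoms$name[rows]
  pick <- function(names) rows[match(names, nm, nomatch = 0L)]
  don <- list()
  if (resid != "PRO" && "N" %in% nm && "CA" %in% nm)
    don <- c(don, list(c(d = pick("N"), x = pick("CA"))))
  for (dn in names(.sc_donors[[resid]] %||% character(0))) {
    ante <- .sc_donors[[resid]][[dn]]
    if (dn %in% nm && ante %in% nm)
      don <- c(don, list(c(d = pick(dn), x = pick(ante))))
  }
  acc <- integer(0)
  if ("O" %in% nm) acc <- c(acc, pick("O"))
  acc <- c(acc, pick(intersect(.sc_acceptors[[resid]] %||% character(0), nm)))
  hyd <- pick(intersect(.apolar_carbons[[resid]] %||% character(0), nm))
  chg <- NULL
  cg <- .charged_groups[[resid]]
  if (!is.null(cg) && all(cg$atoms %in% nm))
    chg <- list(sign = cg$sign,
                centroid = colMeans(xyz[pick(cg$atoms), , drop = FALSE]))
  hyds <- rows[nm == "H" | grepl("^H", nm)]
  list(resid = resid, rows = rows, donors = don, acceptors = acc,
       hydrophobic = hyd, charged = chg, hydrogens = hyds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Donor angle: use the explicit hydrogen when one is bonded to the
# donor (angle D-H...A), otherwise the heavy-atom proxy angle X-D-A.
donor_angle <- function(xyz, d, x, a, hydrogens) {
  hs <- if (length(hydrogens) == 0L) integer(0) else
    hydrogens[sqrt(rowSums((xyz[hydrogens, , drop = FALSE] -
          matrix(xyz[d, ], length(hydrogens), 3L, byrow = TRUE))^2)) < 1.3]
  if (length(hs) > 0L) {
    max(vapply(hs, function(h)
      vec_angle(xyz[d, ] - xyz[h, ], xyz[a, ] - xyz[h, ]), numeric(1L)))
  } else {
    vec_angle(xyz[x, ] - xyz[d, ], xyz[a, ] - xyz[d, ])
  }
}

#' Detect noncovalent contacts of a probe residue in one frame
#'
#' Applies geometric criteria for hydrogen bonds, salt bridges and
#' hydrophobic contacts between the probe residue and every other
#' residue at least 2 positions away in sequence. Duplicate contacts
#' of one type to the same partner collapse to a single record.
#'
#' @param frame A [structure3d] object.
#' @param probe Author residue number of the probe (e.g. 1611).
#' @param types Interaction types to detect. Metal complexes,
#'   pi-stacking, pi-cation and halogen bonds are recognized names but
#'   have no detector and raise an error if requested.
#' @return data.frame with columns `type`, `partner` (resno),
#'   `partner_resid`, `distance` (A); zero rows when nothing is found.
#' @export
detect_contacts <- function(frame, probe, types = interaction_types) {
  bad <- intersect(types, .unsupported_types)
  if (length(bad) > 0L)
    stop("interaction type(s) not supported: ", paste(bad, collapse = ", "))
  types <- match.arg(types, interaction_types, several.ok = TRUE)
  atoms <- frame$atoms
  xyz <- frame$xyz
  if (!probe %in% atoms$resno) stop("probe residue not present")
  pc <- residue_chem(atoms, xyz, probe)
  partners <- setdiff(unique(atoms$resno), probe)
  partners <- partners[abs(partners - probe) >= 2L]
  rec <- list()
  for (p in partners) {
    tc <- residue_chem(atoms, xyz, p)
    # hydrogen bonds, both directions
    if ("hydrogen_bond" %in% types) {
      best <- Inf
      for (dir in 1:2) {
        don <- if (dir == 1L) pc else tc
        acc <- if (dir == 1L) tc else pc
        for (dpair in don$donors) {
          for (a in acc$acceptors) {
            dda <- vnorm(xyz[dpair[["d"]], ] - xyz[a, ])
            if (dda <= .hbond_dist_max &&
                donor_angle(xyz, dpair[["d"]], dpair[["x"]], a,
                            don$hydrogens) >= .hbond_angle_min)
              best <- min(best, dda)
          }
        }
      }
      if (is.finite(best))
        rec[[length(rec) + 1L]] <- data.frame(
          type = "hydrogen_bond", partner = p, partner_resid = tc$resid,
          distance = best, stringsAsFactors = FALSE)
    }
    if ("salt_bridge" %in% types && !is.null(pc$charged) &&
        !is.null(tc$charged) && pc$charged$sign * tc$charged$sign < 0) {
      d <- vnorm(pc$charged$centroid - tc$charged$centroid)
      if (d <= .saltbridge_dist_max)
        rec[[length(rec) + 1L]] <- data.frame(
          type = "salt_bridge", partner = p, partner_resid = tc$resid,
          distance = d, stringsAsFactors = FALSE)
    }
    if ("hydrophobic" %in% types && length(pc$hydrophobic) > 0L &&
        length(tc$hydrophobic) > 0L) {
      dmin <- Inf
      for (i in pc$hydrophobic)
        for (j in tc$hydrophobic)
          dmin <- min(dmin, vnorm(xyz[i, ] - xyz[j, ]))
      if (dmin <= .hydrophobic_dist_max)
        rec[[length(rec) + 1L]] <- data.frame(
          type = "hydrophobic", partner = p, partner_resid = tc$resid,
          distance = dmin, stringsAsFactors = FALSE)
    }
  }
  if (length(rec) == 0L)
    return(data.frame(type = character(0), partner = integer(0),
                      partner_resid = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rec)
  # a charge-assisted hydrogen bond inside a detected salt bridge is
  # reported as the salt bridge only
  sb <- out$partner[out$type == "salt_bridge"]
  drop <- out$type == "hydrogen_bond" & out$partner %in% sb
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interaction occupancy probabilities along a trajectory
#'
#' For each (type, partner) pair, the fraction of frames in which at
#' least one such contact is present.
#'
#' @param traj A [trajectory3d()] object.
#' @param probe Probe residue author number.
#' @param types Interaction types to detect (see [detect_contacts()]).
#' @return data.frame with columns `type`, `partner`, `partner_resid`,
#'   `probability`, sorted by descending probability.
#' @export
interaction_probability <- function(traj, probe, types = interaction_types) {
  nf <- n_frames(traj)
  if (nf < 1L) stop("empty trajectory")
  tally <- new.env(parent = emptyenv())
  meta <- new.env(parent = emptyenv())
  for (i in seq_len(nf)) {
    con <- detect_contacts(get_frame(traj, i), probe, types)
    if (nrow(con) == 0L) next
    keys <- unique(paste(con$type, con$partner, sep = "|"))
    for (k in keys) {
      tally[[k]] <- (tally[[k]] %||% 0L) + 1L
      if (is.null(meta[[k]]))
        meta[[k]] <- con$partner_resid[paste(con$type, con$partner, sep = "|") == k][1L]
    }
  }
  keys <- ls(tally)
  if (length(keys) == 0L)
    return(data.frame(type = character(0), partner = integer(0),
                      partner_resid = character(0), probability = numeric(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(
    type = vapply(parts, `[`, character(1L), 1L),
    partner = as.integer(vapply(parts, `[`, character(1L), 2L)),
    partner_resid = vapply(keys, function(k) meta[[k]], character(1L)),
    probability = vapply(keys, function(k) tally[[k]], numeric(1L)) / nf,
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$probability, out$partner), , drop = FALSE]
}

#' Filter interaction records by occupancy
#'
#' Keeps records whose probability is strictly greater than the
#' threshold (the reported fingerprints use 30%), ordered by
#' descending probability.
#'
#' @param records data.frame from [interaction_probability()].
#' @param threshold Occupancy threshold in [0, 1] (default 0.30).
#' @return Filtered, reordered data.frame.
#' @export
filter_interactions <- function(records, threshold = 0.30) {
  stopifnot(threshold >= 0, threshold <= 1)
  out <- records[records$probability > threshold, , drop = FALSE]
  out <- out[order(-out$probability, out$partner), , drop = FALSE]
  rownames(out) <- NULL
  out
}
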