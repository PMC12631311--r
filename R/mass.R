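# Average (isotope-abundance-weighted) residue masses in Da, i.e. the
# mass of each amino acid minus one water, and the mass of water.
.residue_mass <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.water_mass <- 18.01528

#' Average molecular mass of a protein sequence
#'
#' Sum of average amino-acid residue masses plus one water, reported in
#' kDa. Used e.g. to obtain the monomer weight that anchors
#' size-exclusion oligomer assignment (see [oligomer_order()]).
#'
#' @param sequence One-letter amino-acid string (case-insensitive;
#'   whitespace ignored).
#' @return Mass in kDa.
#' @export
#' @examples
#' sequence_mass("G")  # free glycine, 0.07507 kDa
sequence_mass <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- gsub("[[:space:]]", "", toupper(sequence))
  if (nchar(s) == 0L) stop("empty sequence")
  aa <- strsplit(s, "")[[1L]]
  bad <- setdiff(aa, names(.residue_mass))
  if (length(bad) > 0L)
    stop("invalid amino-acid letter(s): ", paste(unique(bad), collapse = ", "))
  (sum(.residue_mass[aa]) + .water_mass) / 1000
}

#' Read a single-record FASTA sequence
#'
#' @param path FASTA file with one record.
#' @return Named character scalar (name = FASTA header).
#' @export
read_fasta_sequence <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) != 1L || hdr != 1L) stop("expected a single-record FASTA file")
  stats::setNames(paste(lines[-1L], collapse = ""), sub("^>\\s*", "", lines[1L]))
}

#' Apply point substitutions to a numbered sequence
#'
#' @param sequence One-letter string.
#' @param substitutions Character vector like `"C1551S"`.
#' @param offset Author number of the first residue in `sequence`
#'   (e.g. 1513 for the VPS9 construct).
#' @return Substituted sequence string.
#' @export
apply_substitutions <- function(sequence, substitutions, offset = 1L) {
  aa <- strsplit(toupper(sequence), "")[[1L]]
  for (s in substitutions) {
    m <- regmatches(s, regexec("^([A-Z])([0-9]+)([A-Z])$", toupper(s)))[[1L]]
    if (length(m) != 4L) stop("malformed substitution: ", s)
    pos <- as.integer(m[3L]) ; from <- m[2L] ; to <- m[4L]
    i <- pos - offset + 1L
    if (i < 1L || i > length(aa)) stop("substitution outside sequence: ", s)
    if (aa[i] != from)
      stop(sprintf("substitution %s: position %d holds %s, not %s",
                   s, pos, aa[i], from))
    aa[i] <- to
  }
  paste(aa, collapse = "")
}
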