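# Shared fixture builders for the test suite. Everything is generated
# in code; nothing is read from disk except packaged extdata.

make_helix <- function(n = 12, resno = seq_len(n))
  build_backbone(n, phi = -57, psi = -47, resno = resno)

make_extended <- function(n = 11, resno = seq_len(n))
  build_backbone(n, phi = 180, psi = 180, resno = resno)

# A structure whose region is exactly the ideal antiparallel template
# (6 residues, one template-matching segment pair).
template_structure <- function(resno = 1532:1537, mode = "antiparallel") {
  tpl <- beta_template(mode)
  atoms <- data.frame(name = rep(c("N", "CA", "CB", "C", "O"), 6),
                      element = rep(c("N", "C", "C", "C", "O"), 6),
                      resno = rep(resno, each = 5L),
                      resid = "ALA", chain = "A", stringsAsFactors = FALSE)
  structure3d(atoms, tpl)
}

synthetic_basis <- function()
  read_cd_basis(system.file("extdata", "basis_synthetic", package = "mutadyn"))

synthetic_standards <- function()
  read_standards(system.file("extdata", "standards_synthetic.tsv",
                             package = "mutadyn"))

# Independent RMSD oracle: Horn's closed-form quaternion method
# (eigen-decomposition of the 4x4 key matrix), sharing no code with
# the SVD-based implementation under test.
quaternion_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(A, B)
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[1, 3] + M[3, 1]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lmax <- max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lmax) / nrow(A)
  sqrt(max(msd, 0))
}
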