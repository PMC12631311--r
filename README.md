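# mutadyn

Structural characterization of point mutations from trajectories,
spectra and chromatograms — built around the alsin VPS9 R1611W case.

The VPS9 domain of human alsin (residues 1513–1657, author numbering)
carries the protein's nucleotide-exchange activity, and the pathogenic
R1611W substitution is linked to infantile-onset hereditary spastic
paralysis. Understanding what one substitution does to such a domain
takes several independent readouts analyzed consistently. `mutadyn`
implements that analysis stack for R users in structural
bioinformatics:

* **Structure/trajectory model** — multi-model PDB I/O, Kabsch
  superposition and RMSD series, Shrake–Rupley accessible surface
  area, sequence masses (author residue numbering preserved
  end-to-end).
* **Collective variables** — the beta-RMSD content of a residue
  window, scoring segment pairs against ideal beta-sheet templates
  through the switching function
  `S(r) = (1 − (r/r0)^n) / (1 − (r/r0)^m)`, and the probe–loop
  C-alpha distance *d*.
* **Free-energy surfaces** — block-averaged bivariate histograms
  `H̄_i = (1/N) Σ_j H(i,j)` Boltzmann-inverted as
  `F_i = −k_B T [ln H̄_i − ln max(H̄_i)]` (minimum pinned at
  0 kJ/mol), with between-window errors propagated through the log,
  1D projections, and basin free-energy differences with a
  conservative confidence band.
* **Secondary structure** — Kabsch–Sander hydrogen-bond assignment
  (`E = q1·q2·f·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)`, bond below
  −0.5 kcal/mol) collapsed to helix/strand/turn/coil, with
  per-residue probabilities over concatenated replicas.
* **Interaction fingerprints** — geometric hydrogen-bond, salt-bridge
  and hydrophobic detection for a probe residue, occupancy over
  frames, and the strictly-greater-than 30% selection in the standard
  (Type, Residue, Probability %) layout.
* **CD spectroscopy** — millidegree → MRE conversion
  `[Θ] = mdeg·Mw/(10·L·C)`, baseline correction and averaging,
  Savitzky–Golay smoothing (order 3, window 9), constrained basis-set
  deconvolution with spectrum scaling, basis selection by RMSD, and
  3-class grouping.
* **SEC** — log-linear column calibration, apparent molecular
  weights with extrapolation flags, peak/shoulder detection, and
  oligomer-order assignment.
* **Synthetic data** — seeded generators with known ground truth for
  every stage (two-state folded/unfolded trajectories, CD mixtures,
  Gaussian-peak chromatograms, single-contact structures).
* **Pipeline** — `run_pipeline()` executes configured stages for
  labeled conditions (e.g. WT vs mutant) with TSV tables, checksummed
  manifest and JSON summary; a thin CLI wrapper lives in
  `inst/scripts/mutadyn`.

## Worked example

```r
library(mutadyn)

## two-state synthetic system: 200 ns span sampled every 0.4 ns,
## folded occupancy 0.6, probe-loop distance 12 A (folded) / 17.5 A
spec <- two_state_spec()
cv <- gen_two_state_cv(spec, seed = 42)

## block-averaged free-energy analysis: discard 50 ns, 10 ns windows
stack <- block_histograms(cv$beta, cv$dist, discard_ns = 50, window_ns = 10)
stack$n_windows
#> [1] 15

## basin gap along the distance axis vs the designed value
bd <- basin_delta_f(stack, axis = 2, c(-Inf, 14.75), c(14.75, Inf))
sprintf("delta F = %.2f +/- %.2f kJ/mol (designed: %.2f)",
        bd$delta_f, bd$band, -0.0083145 * 298.15 * log(0.4 / 0.6))
#> "delta F = 0.54 +/- 0.68 kJ/mol (designed: 1.01)"

## CD: noisy synthetic mixture, smoothed then deconvolved
basis <- read_cd_basis(system.file("extdata", "basis_synthetic",
                                   package = "mutadyn"))
sp <- gen_cd_spectrum(c(helix = 0.4, strand = 0.1, coil = 0.5), basis,
                      noise_sd = 0.02 * max(abs(basis$components)), seed = 1)
round(group_classes(deconvolve_cd(smooth_spectrum(sp), basis)$fractions, basis), 3)
#>  helix strand   coil
#>  0.347  0.153  0.500

## SEC: a 13.4 mL feature on the synthetic calibration
cal <- fit_calibration(read_standards(system.file(
  "extdata", "standards_synthetic.tsv", package = "mutadyn")))
mw <- apparent_mw(13.4, cal)$mw_kda
oo <- oligomer_order(mw, monomer_mw = 16.6)
sprintf("13.4 mL -> %.1f kDa, ratio %.2f -> order %d", mw, oo$ratio, oo$order)
#> "13.4 mL -> 64.0 kDa, ratio 3.85 -> order 4"
```

Reading the numbers: the estimated basin gap (0.54 kJ/mol at this
seed) agrees with the designed −k_B·T·ln(0.4/0.6) = 1.01 kJ/mol
within its 95%-level error band (±0.68); the CD fractions land within
a few hundredths of the generating mixture; and a 13.4 mL elution
feature maps to ~64 kDa, i.e. a tetramer of the 16.6 kDa monomer.

The packaged construct FASTA
(`inst/extdata/vps9_construct_synthetic.fasta`) and the CD basis and
SEC standards under `inst/extdata/` are synthetic, clearly labelled
stand-ins so that examples and tests run without external downloads.

## Vignette

`vignettes/mutadyn-methods.Rmd` documents the models and their
assumptions, every tunable parameter with units and defaults, what
the synthetic generators emulate (and what passing tests on them do
and do not show about real data), the numerical choices, and known
limitations.
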