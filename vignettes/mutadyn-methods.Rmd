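---
title: "Methods behind mutadyn: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind mutadyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutadyn)
```

# The scientific problem

The alsin VPS9 domain (residues 1513–1657 of human alsin, numbered
throughout by the full-length sequence) carries the guanine nucleotide
exchange activity of the protein, and the pathogenic R1611W
substitution is associated with infantile-onset hereditary spastic
paralysis. Characterizing how that single substitution reshapes the
domain requires several independent measurements to be brought
together: replica-exchange trajectories summarized by collective
variables and free-energy surfaces, per-residue secondary-structure
probabilities, the noncovalent contacts that residue 1611 makes with
the rest of the domain, far-UV circular dichroism (CD) deconvolved
into secondary-structure content, and size-exclusion chromatography
(SEC) read out as oligomeric state. `mutadyn` implements that analysis
stack as reusable, tested components, together with synthetic-data
generators that give every stage a known ground truth.

# Collective variables

## Beta-RMSD

The beta-RMSD of a residue window measures how much of the window is
arranged as a beta sheet. Every ordered pair of 3-residue backbone
segments inside the window that shares no residue (segment starts at
least 3 apart) is superposed, as a 30-atom unit (N, CA, CB, C, O per
residue), onto an ideal two-strand template, and the best-fit RMSD $r$
is passed through the rational switching function

$$S(r) = \frac{1 - (r/r_0)^n}{1 - (r/r_0)^m},$$

with $S = n/m$ at $r = r_0$ by continuity. The CV is the sum of $S$
over segment pairs; "total" mode adds the parallel and antiparallel
register sums. Defaults are $r_0 = 0.1$ nm, $n = 8$, $m = 12$. Because
coordinates are carried in ångström internally, $r_0$ is converted at
the module boundary; the ratio $r/r_0$ is unit-free.

The two ideal templates are package constants. They were constructed
from ideal beta-strand torsions ($\phi = -139^\circ$,
$\psi = 135^\circ$, ideal bond geometry) with the second segment
placed by solving for canonical 2.91 Å N–H⋯O=C hydrogen bonds in the
antiparallel and parallel registers; the construction script is frozen
and the resulting 30-atom coordinate sets are embedded as matrices.
Glycine C-beta atoms are synthesized at the ideal tetrahedral position
from N, CA and C so that glycine-containing windows score like any
other.

Two properties of the CV are worth knowing when reading values:

* A window built *exactly* from the antiparallel template scores 1
  for its matching pair; neighboring overlapping pairs add partial
  scores, so an 11-residue folded hairpin window scores about 1.5,
  not 1.
* $S$ decays only as $(r/r_0)^{-4}$ at large $r$, so an extended
  chain does not score exactly zero: each of its segment pairs sits
  around $r \approx 5$ Å and contributes a few times $10^{-3}$. The
  calibration checks therefore use the minimal 6-residue window (a
  single segment pair); wider windows accumulate a small baseline
  that grows roughly quadratically with window length. This baseline
  is orders of magnitude below the folded-state signal and does not
  affect state discrimination.

The default analysis window is residues 1532–1542 (the beta1 element
between helices alpha-1 and alpha-2). Published descriptions of this
element vary by one residue at either end; the region is a plain
argument, so any span of at least six contiguous residues can be
scored.

## Probe–loop distance

The second CV is the Euclidean distance between the C-alpha of the
probe residue (default 1611) and the unweighted centroid of the
C-alpha atoms of a loop (default 1545–1550). Both CVs are invariant
under rigid motion of a frame, which the test suite checks by
property.

# Free-energy surfaces by block averaging

Frames with $t \le t_\mathrm{discard}$ (default 50 ns) are dropped as
equilibration; the remainder is cut into windows of
$t_\mathrm{window}$ (default 10 ns). With the default synthetic
sampling (0.4 ns per frame over a 200 ns span) this yields exactly
$N = 15$ windows of 25 frames. Each window $j$ gives a normalized
bivariate histogram $H(i, j)$ on shared bin edges (default 50 × 50
bins over the observed CV ranges padded by 5%; the bin count is a
resolution/noise compromise and is configurable). The surface is the
Boltzmann inversion of the window average
$\bar H_i = \tfrac1N \sum_j H(i,j)$:

$$F_i = -k_B T\,[\ln \bar H_i - \ln \max(\bar H_i)],$$

with $k_B = 0.0083145$ kJ mol$^{-1}$ K$^{-1}$, so the modal bin has
$F = 0$ and every visited bin has $F \ge 0$. Bins never visited are
masked (`NA`) rather than assigned an arbitrary cap, and plots leave
them blank.

The per-bin error is the between-window standard error of the mean
propagated through the logarithm (delta method):

$$\mathrm{err}_i = k_B T\,\frac{\mathrm{sem}_j\,H(i,j)}{\bar H_i}.$$

An alternative estimator — invert each window separately, then take
the spread of the per-window surfaces — is available as
`fes_error(..., method = "invert_first")` and is labeled in its
output; the delta method is the default because it remains defined in
bins that individual windows leave empty. One-dimensional profiles
marginalize each window onto one CV axis before averaging and
inverting; since marginalization and averaging are both linear, this
equals inverting the marginal of $\bar H$ (checked to floating
tolerance in the tests).

## Basin free-energy differences and their band

`basin_delta_f()` sums $\bar H$ over each basin's CV range and
reports $\Delta F = -k_B T \ln(p_2/p_1)$. Its error band is
deliberately conservative: the two per-basin errors
$k_B T\,\mathrm{sem}(p_k)/\bar p_k$ are *added* (basin occupancies
are anticorrelated, so combining them in quadrature would
underestimate), then scaled by the two-sided 97.5% Student-t quantile
with $N - 1$ degrees of freedom. For a two-basin system this band is
a 95%-level confidence interval: in a 1000-seed simulation of the
default two-state generator the true gap fell inside the band in
about 95% of runs, which is what the parameter-recovery test asserts
on its fixed seed set.

# Secondary structure

Assignment follows the classic hydrogen-bond dictionary: the
electrostatic bond energy

$$E = q_1 q_2 f \left(\frac{1}{r_{ON}} + \frac{1}{r_{CH}} -
\frac{1}{r_{OH}} - \frac{1}{r_{CN}}\right)$$

with $q_1 q_2 f = 0.42 \cdot 0.20 \cdot 332$ kcal Å/mol, bonded when
$E < -0.5$ kcal/mol. When trajectories carry no amide hydrogens the H
is placed 1.0 Å from N, anti-parallel to the preceding carbonyl C=O
bond — the convention of the original dictionary program and of the
trajectory backends built on it, which is why this package's
assignments can be checked against an established implementation on
identical inputs. Helices come from consecutive $i \to i+n$ turns
($n = 3, 4, 5$), strands from parallel/antiparallel bridge patterns,
turns from isolated turn patterns plus the C-alpha bend criterion
(angle > 70°), everything else is coil. The 8-class output is
collapsed to the four reported classes as {H, G, I} → helix,
{E, B} → strand, {T, S} → turn, rest → coil; the collapse map is an
argument-free constant here because the reported quantities use
exactly these four classes, and the full 8-class letters remain
available in the assignment output. Chains shorter than three
residues are all coil by construction.

Per-residue probabilities divide class occurrences by the total frame
count over concatenated replicas (row-stochastic by construction, and
invariant to replica order); overall composition is reported per
replica with across-replica mean and standard deviation.

# Interaction fingerprints

Contacts between the probe residue and every residue at least two
positions away in sequence are detected per frame with geometric
criteria modeled on the standard protein-interaction profiler:

* hydrogen bond — donor–acceptor distance ≤ 4.1 Å and donor angle
  ≥ 100° (measured at the hydrogen when one is present within
  bonding distance of the donor, otherwise at the donor heavy atom
  against its antecedent);
* salt bridge — centroids of oppositely charged groups within 5.5 Å,
  with standard-state protonation (Asp/Glu anionic, Lys/Arg
  cationic, His neutral), since coordinate frames carry no titration
  information;
* hydrophobic — two apolar carbons (bonded only to C/H, from
  per-residue name tables) within 4.0 Å.

A charge-assisted hydrogen bond inside a detected salt bridge is
reported as the salt bridge only, and duplicate contacts of one type
to one partner collapse to a single record per frame. Metal
complexes, pi-stacking, pi-cation and halogen bonds are recognized
type names whose detectors intentionally raise a not-supported error.
Occupancy is the fraction of frames with at least one contact of a
given (type, partner); the reported fingerprint keeps records with
occupancy *strictly greater* than 30% (literal reading of the
selection rule), ordered by descending occupancy, in a three-column
layout (Type, Residue, Probability %).

# Circular dichroism

Raw ellipticity in millidegrees converts to mean residue ellipticity
as $[\Theta] = \mathrm{mdeg} \cdot M_w / (10\,L\,C)$ with the path
length $L$ in cm, concentration $C$ in mg/mL and weight $M_w$ in kDa.
Replicate acquisitions are baseline-subtracted pointwise and
averaged, then smoothed with a Savitzky–Golay filter (order 3, window
9 samples — exact on cubics, which the tests assert to $10^{-10}$;
endpoint rows of the projection matrix handle the boundaries).

Deconvolution finds nonnegative class fractions summing to one, and a
single positive scale factor applied to the experimental spectrum,
minimizing the residual against the basis combination. The fraction
step is a Lawson–Hanson nonnegative least squares with the
sum-to-one constraint imposed through a heavily weighted augmented
row; the scale step is closed-form; the two alternate to
convergence. In the noiseless case the augmented system has an exact
solution, so recovery is exact to machine precision. The achieved
RMSD is reported in kMRE (MRE/1000) to match conventional magnitudes.
Basis sets are plain-text component tables with a grouping map onto
the three reported classes (helix, strand, coil); the packaged basis
is synthetic (smooth Gaussian-shaped far-UV components labeled as
such) so that tests need no external data, and published basis-set
files load through the same two-file interface. `select_basis()`
ranks candidate bases by post-scaling RMSD, breaking ties by order
with a message.

# Size-exclusion chromatography

Calibration is the classic log-linear model: least squares of
$\log_{10}(\mathrm{MW})$ on elution volume through the standards. The
slope must come out negative for a sane standard set (larger species
elute earlier), predictions outside the standards' volume span are
flagged as extrapolations, and a partition-coefficient variant is
deliberately out of scope until void/total volumes are part of the
inputs. Apparent weights divide by the monomer mass to give an
oligomer ratio and its nearest integer; the raw ratio is returned
because values near half-integers (for example a fast dimer–tetramer
equilibrium averaging near 3) should be flagged by the caller rather
than silently rounded.

Peaks are local maxima of the Savitzky–Golay-smoothed trace above a
height fraction of the maximum (default 5%). Shoulders are local
minima of the second derivative on a peak flank — pockets of locally
reduced curvature, whatever the sign of the curvature there — kept
when the dip below the flanking curvature maxima exceeds a prominence
fraction (default 5% of the curvature range) and separated from
detected peaks by at least 0.3 mL. On a synthetic mixture of two
0.4 mL-wide Gaussians 0.7 mL apart with 40% relative height, the
detector reports one peak and one shoulder, each within 0.1 mL of
construction; a lone Gaussian yields exactly one peak. Detection is
invariant to uniform absorbance scaling.

# Synthetic data: what it emulates, and what it does not

The two-state generator emulates the folded/unfolded equilibrium of
the beta1 region: a first-order Markov chain (stationary folded
occupancy 0.6, total switching rate 0.8 per frame, so the lag-1 state
autocorrelation is 0.2) alternates frames between a hairpin
conformation built from the ideal antiparallel template and freshly
drawn coil conformations (torsions from a broad coil distribution, so
the unfolded state has in-state variance), plus isotropic Gaussian
coordinate noise (default 0.15 Å). The probe C-alpha sits at
12 ± 0.8 Å from the loop centroid when folded and 17.5 ± 1.0 Å when
unfolded, reproducing the in-contact/released signature of the
domain's basins. Defaults mirror the replica-analysis scales: 500
frames at 0.4 ns over a 200 ns span, discard 50 ns, 10 ns windows,
N = 15. A CV-level twin (`gen_two_state_cv()`) emits the
(beta-RMSD, distance) pair directly from the same state chain for
many-seed recovery studies where coordinates are irrelevant.

The CD generator produces noisy linear combinations of basis spectra;
the chromatogram generator places Gaussian elution peaks at
calibration-predicted volumes (default width 0.4 mL, typical of an
analytical gel-filtration column) with optional baseline noise; the
interaction generator builds minimal two-residue structures realizing
exactly one requested contact geometry. All generators are pure
functions of (spec, seed) and restore the caller's RNG state.

What passing tests on these generators shows — and what it does not:
the generators have no physics. The Markov chain has no kinetics
beyond one autocorrelation scale; coil draws ignore excluded volume;
the hairpin is rigid up to isotropic noise; CD noise is iid Gaussian
rather than wavelength-correlated; chromatogram peaks are symmetric.
Recovery of designed ground truth therefore validates the *analysis
chain* (binning, averaging, inversion, error propagation,
deconvolution, calibration logic), not the ability of any of these
methods to conquer real conformational sampling or instrument
systematics.

# Numerical and interface choices

* Coordinates are ångström and times nanoseconds everywhere inside
  the package; conversions happen only at I/O boundaries.
* Residue numbers are author numbers (1513–1657 for this construct)
  end-to-end; no internal renumbering leaks into results.
* Superposition uses SVD with a determinant correction (proper
  rotations only); selections with fewer than three points or
  collinear geometry are rejected. The suite cross-checks RMSD
  against a closed-form quaternion solution and a brute-force
  rotation search.
* Accessible surface areas use the point-lattice occlusion method on
  a deterministic golden-spiral lattice (default 960 points, probe
  1.4 Å, Bondi radii), so results are bit-reproducible; relative
  areas divide by a published table of theoretical per-residue
  maxima. The discretization error decreases with the point count,
  which a test asserts by monotonicity.
* Sequence masses use average residue masses plus one water; the
  packaged construct FASTA is a clearly labelled synthetic stand-in
  (anchor residues from the cloning primers and reported contacts,
  random interior), shipped so that examples run end-to-end; results
  derived from it carry "synthetic" in their names.
* The window-count rule for block averaging takes exactly
  $\lfloor \mathrm{span}/t_\mathrm{window} \rfloor$ complete windows
  and warns when a trailing remainder is dropped; fewer than two
  complete windows is an error.
* The pipeline (`run_pipeline()`) validates its configuration before
  any stage runs, writes per-stage TSVs plus a manifest with MD5
  checksums and a JSON summary, juxtaposes labeled conditions where
  two are supplied, and on stage failure stops with the stage name
  while leaving partial outputs next to a FAILED marker. Reruns with
  the same config and seed are byte-identical.

# Known limitations

* No trajectory formats beyond (multi-model) PDB; compact binary
  formats would need an external reader.
* The interaction chemistry tables cover the 20 standard residues at
  fixed protonation; no cofactors, ions or modified residues.
* The beta-RMSD baseline from switching-function tails (above) makes
  absolute values of wide windows slightly offset; comparisons
  between states, which is what the CV is used for, are unaffected.
* Free-energy analysis is single-temperature; no cross-temperature
  reweighting.
* CD deconvolution assumes the basis spans the spectrum; it reports
  the residual RMSD but no goodness-of-fit test.
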