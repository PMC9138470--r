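---
title: "Quantifying conformational entropy of antibody loops with cdrentropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conformational entropy of antibody loops with cdrentropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The antigen-binding loops of single-domain antibodies — the CDRs, and
CDR3 in particular — can range from rigid, scaffold-anchored hairpins to
highly mobile loops that interconvert between many conformations.
Comparing that heterogeneity across antibodies requires (i) unbiasing
ensembles that were produced with enhanced-sampling MD, and (ii)
summarising the unbiased ensemble with statistics that are robust to the
arbitrary choices of the analysis (cluster cutoffs, histogram bins).
`cdrentropy` implements that pipeline end to end and validates every
stage on synthetic ensembles with known ground truth.

## Model and procedure

**Reweighting.** Parallel-bias metadynamics leaves each frame with a
time-independent bias potential $V_{PB,i}$ (kJ/mol). The unbiased weight
of frame $i$ at temperature $T$ is

$$w_i = \frac{e^{V_{PB,i}/k_B T}}{\sum_j e^{V_{PB,j}/k_B T}},$$

with $k_B = 0.0083144621$ kJ/(mol K) fixed at the GROMACS value so
results are bit-stable. All downstream observables are weighted ensemble
averages. The exponent is evaluated after subtracting its maximum
(log-sum-exp), which makes the computation exactly invariant under a
constant shift of the bias — the physically meaningful property, since
the zero of a metadynamics bias is arbitrary — and immune to overflow at
realistic bias magnitudes (hundreds of kJ/mol).

**Clustering.** Conformations are compared by C$\alpha$ RMSD after
per-pair optimal (Kabsch) superposition on the same atoms used for the
RMSD ("fit on self", the behaviour of the standard GROMOS clustering
tool). The GROMOS/Daura algorithm repeatedly takes the structure with
the most neighbours within the cutoff as a cluster center and removes it
with its neighbours. Neighbour counting uses plain frame counts, as in
the original algorithm; statistical weights enter only the reported
populations. An average-linkage agglomerative alternative
(`stats::hclust`) cross-checks that conclusions do not hinge on the
algorithm.

**Entropies.** Conformational heterogeneity is summarised as the
information entropy $S = -\sum_i p_i \log p_i$ over normalised cluster
populations, and per residue as the entropy of the weighted 2D
histogram of backbone $(\phi, \psi)$ angles. Natural logarithms are used
throughout; entropy *rankings* between ensembles are base-invariant, so
nothing scientific hangs on this choice.

**Uncertainty.** The cluster entropy carries a weighted bootstrap:
samples of frames are drawn with replacement with probability equal to
the weights, each sample is re-clustered from scratch with uniform
within-sample weights, and the 2.5/97.5 percentiles of the per-sample
entropies form the band. Duplicated frames are handled exactly through
multiplicities (clustering a matrix with frame $i$ repeated $c_i$ times
is algebraically identical to neighbour-counting with counts $c_i$), so
re-clustering costs only a submatrix slice. A `mode = "map"` shortcut
assigns resampled frames to the whole-ensemble clusters instead; it is
an approximation and is labelled as such.

**Contacts and landscapes.** Two residues are in contact when any pair
of their heavy atoms is strictly below 0.45 nm. Per-frame counts of
intra-loop and loop–scaffold contacts, normalised to $[0,1]$, serve as
collective variables; the weighted 2D histogram over them gives the
free-energy surface $F = -k_B T \log(p/p_{max})$ anchored at 0 in the
most populated bin. Weighted contact frequencies per residue pair give
the contact probability map, and the weighted population of any
rectangle in CV space measures minor-state occupancies.

**Convergence.** After discarding the first 10% of frames, the retained
ensemble is clustered once and each cluster's weighted population is
compared between the two halves. Only clusters whose overall population
reaches the floor (0.001, i.e. 10 of 10,000 frames) are judged.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| clustering cutoff | 0.15 | nm | separates loop conformers at C$\alpha$ resolution; scans via `cluster_count_curve()` show how conclusions depend on it |
| hierarchical scan | 0.01–0.4 | nm | range over which the cutoff scan is meaningful |
| contact cutoff | 0.45 | nm | conventional heavy-atom contact distance; strict inequality, ties are non-contacts |
| `min_seq_sep` | 2 | residues | $i,i\pm1$ heavy-atom contacts are always present and carry no conformational signal; configurable because some analyses keep them |
| dihedral bins | 100 per dimension | – | a 100×100 grid on $(-\pi,\pi]^2$; "100 bins" could also be read as a 10×10 total grid, so the bin count is exposed as a parameter |
| bootstrap | 20 × 10,000 | samples × frames | enough samples for a stable 95% percentile band without dominating runtime |
| temperature | 300 | K | the simulation temperature; enters weights and free energies |
| discard fraction | 0.10 | – | equilibration burn-in before split-half comparison |
| population floor | 0.001 | – | populations below ~10 frames per 10,000 cannot be judged converged either way |

## The synthetic-data generator

`generate_multibasin_ensemble()` builds what the analysis needs and
nothing more: a small number of basin templates (idealised N–CA–C–O
backbones from fixed bond lengths/angles and chosen $\phi/\psi$
torsions), mutually separated by at least `min_separation` in C$\alpha$
RMSD, plus i.i.d. Gaussian coordinate noise of scale $\sigma$. In
`bias_mode = "reweight"` the basins are sampled uniformly and each frame
carries $V = k_B T \log(\text{target population}) + \text{const}$, so
reweighting must recover the targets — the exact inverse of the
reweighting formula, which is what makes it a ground truth rather than
a tautology: the *clustering and population machinery*, not the
formula, is what gets tested.

Resolvability requires `min_separation > 4σ√3`; the default separation
is 0.5 nm for 16-residue chains and 0.35 nm for the short 10-residue
chains of the entropy ladder (shorter random coils cannot reach 0.5 nm
pairwise RMSD, while 0.35 nm is still far above the 0.15 nm cutoff plus
the ~$σ\sqrt{6}$ ≈ 0.05 nm intra-basin spread). Dihedral ground truth
comes from von Mises mixtures (a Best–Fisher rejection sampler is
included, as no circular-statistics package is a dependency), with a
reference entropy computed by a deliberately naive cell-by-cell
histogram implementation that shares no code with the fast path.

What the generator does **not** emulate: force-field energetics, solvent,
side chains, sequence-dependent loop propensities, kinetic correlation
between frames (frames are i.i.d.), and bias potentials that are *wrong*
(the attached bias is exactly consistent with the targets). Passing
tests therefore demonstrate that the machinery is correct and
well-calibrated on resolvable, stationary, uncorrelated ensembles — not
that any particular MD ensemble is converged or its bias accurate.
Convergence of real data must be argued from the split-half and
bootstrap diagnostics on that data.

## Numerical choices

- Coordinates are stored in nm (the PLUMED/GROMACS convention); PDB
  Å values are converted on read/write. All cutoffs are in nm.
- Superposition uses the SVD form of the Kabsch solution with the
  determinant correction, so the rotation is always proper
  (det $= +1$); collinear selections are rejected rather than silently
  resolved.
- Pairwise RMSD matrices and contact counting are implemented in C++
  (RcppArmadillo) — the only two hot loops; everything else is plain R.
- GROMOS tie-breaks: equal neighbour counts go to the lowest frame
  index; cluster ids are assigned by descending weighted population,
  ties broken by center index. Partitions are therefore deterministic.
- Histogram binning clamps values at the $(-\pi, \pi]$ boundary into the
  edge bins, so a frame at exactly $-\pi$ (numerical noise) cannot
  vanish.
- $0 \log 0 := 0$ in all entropies; empty free-energy bins are masked
  (NA), never reported as $F = 0$.
- Degenerate inputs degrade loudly: single-frame RMSF returns zeros
  with a warning, an all-zero contact class yields a zero CV with a
  warning, missing backbone atoms mark dihedrals as NA with a warning.
- Every stochastic routine takes an explicit seed, restores the caller's
  RNG state, and records the seed in its output.

## Design decisions that were genuinely open

- **Split-half verdict.** A per-cluster tolerance is needed, but the
  entropy bootstrap yields a band on a scalar. The verdict therefore
  uses $|\Delta p| \le \max(3 \times \text{binomial SE from the halves'
  effective sample sizes}, \text{bootstrap population-band half-width})$,
  the latter only when population bootstrapping is requested. This keeps
  the diagnostic self-contained and sample-size aware.
- **CV normalisation.** "Relative proportion" of contacts is normalised
  by the ensemble-maximum count per contact class, giving per-frame
  values in $[0,1]$; normalising by the number of admissible pairs is
  available via `normalization = "max_pairs"`.
- **Weighted contact maps.** Contact probabilities are weighted by
  default, consistent with every other observable; unweighted
  frequencies are the uniform-weights special case.
- **Region ranges are taken literally.** CDR boundary conventions vary
  between numbering schemes, and published range tables do not always
  match the printed loop sequences exactly; the loader deliberately does
  not reconcile ranges against sequences.
- **Cluster ids are 1-based**, following R convention, with cluster 1
  the largest by weighted population.

## Problem sizes

The validation suite runs at sizes chosen to make sampling error small
relative to the tested tolerances while keeping the suite quick:
5,000-frame ensembles (16 residues) for population/entropy recovery,
20 seeds × 3 ensembles × 600 frames for the entropy-ladder ranking,
100,000 frames for the 0.1% minor-state population and for the
dihedral-entropy oracle comparison, and 200 random matrices of up to 8
frames for exact GROMOS-oracle agreement. Expected statistical
tolerances follow from binomial/delta-method standard errors at those
sizes and are stated next to each test.

## Known limitations

- Pairwise-fitted RMSD is not a metric (no triangle inequality), which
  is fine for GROMOS and average linkage but would not support
  metric-tree accelerations.
- The RMSD matrix is dense: memory scales as $O(n^2)$ frames
  (~200 MB at 5,000 frames); for much longer trajectories, stride the
  frames before analysis.
- Split-half diagnostics treat frames as concatenated in time; per-walker
  structure of multi-walker simulations is not recoverable from the
  concatenated input and is not modelled.
- The native trajectory format is multi-model PDB; binary formats
  (XTC/DCD) should be converted upstream.
- Only backbone $\phi/\psi$ entropies are implemented; side-chain
  $\chi$ angles are out of scope.
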