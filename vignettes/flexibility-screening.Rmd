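---
title: "Differential flexibility analysis and screening triage with pocketflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential flexibility analysis and screening triage with pocketflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketflex)
```

## The problem and the model

A protein that exists both free in solution and tethered to a membrane
can present the same sequence yet different dynamics: tethering damps
the thermal breathing of surface residues.  If a cleft near the
protein–protein interaction epitope opens appreciably only in the free
form, a small molecule can bind there selectively — inhibiting the
soluble form's signalling while leaving the membrane form (and its
immune functions) untouched.  RANKL is the motivating case: soluble
RANKL drives osteoporotic bone resorption, membrane RANKL sustains
T-cell and dendritic-cell biology, and the two are cleaved from the
same precursor.

`pocketflex` quantifies that contrast from conformational ensembles
with three statistics:

1. **Exceedance probability.**  For a monitored residue pair with
   per-frame distance $d(f)$ and reference distance $d_{\mathrm{ref}}$
   (the starting, crystal-derived conformation), the exceedance at
   threshold $t$ is
   $$P_t = \frac{1}{F}\,\#\{f : d(f) - d_{\mathrm{ref}} > t\}.$$
   It is one-sided by construction: only opening beyond the reference
   indicates ligand inducibility.  The comparison is strict, so a frame
   exactly at the threshold does not count.

2. **SDRP.**  The sum of the four monitored pair distances per frame.
   A wider, more variable SDRP indicates a larger, more inducible site.
   SDRP values are histogrammed in bins of width 2 Å anchored at
   integer multiples of the width, so bins carry labels such as
   [76, 78).  The most populated ("modal") bin defines the common
   conformation; frames in it, ranked by closeness of their SDRP to the
   bin midpoint, are the representative conformers handed to docking.

3. **Pocket geometry.**  Site size is deliberately summarised by just
   two distances — a length pair and a width pair — measured on a
   representative frame.  No cavity detection is attempted; two numbers
   measured identically in both forms are what the selectivity argument
   needs.

Downstream, docking results enter as plain long-format score tables
(compound, target, scorer, score; lower = better) and pass through an
ordered cascade of three rule types: *differential binder* (score
strictly below the cutoff against the positive target and **not** below
it against the negative target), *threshold*, and *rank-top*.  The
default funnel applies the differential rule at −6, a secondary
threshold at −3.5, and represents induced-fit re-docking as a rank-top
stage over a third score column.  Stage order matters — the engine is
deliberately ordering-agnostic and the audit trail records, for every
compound, where and why it was removed, so alternative orderings can
be compared transparently.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `threshold` | 1.8 (2.0 preset) | Å | exceedance cutoff on the deviation from the reference distance |
| `bin_width` | 2 | Å | SDRP histogram bin width |
| `distance_mode` | `sidechain_centroid` | — | residue position definition (`ca`, `min_heavy` available) |
| differential cutoff | −6 | score | primary-scorer selection |
| secondary cutoff | −3.5 | score | secondary-scorer selection |
| `k_final` | none | — | induced-fit survivors retained |

Two thresholds circulate for the exceedance criterion, 1.8 Å and
2.0 Å; both are shipped as documented presets and the parameter is
always explicit, since the difference is immaterial to the qualitative
contrast but visible in the absolute probabilities.  The default
distance mode is the side-chain heavy-atom centroid (Cα for glycine)
because the monitored residues (Tyr, His, Asp, Lys, Gln, Arg) interact
through their side chains; `ca` and `min_heavy` are provided for
sensitivity checks.  The reference conformation defaults to frame 1,
the crystal-derived starting structure; a trajectory-mean reference is
available via `reference_frame = "mean"`.

Residue numbers can be stated in rat, mouse or human convention;
`map_residue_numbering()` applies the fixed offsets
(rat = mouse + 2 = human + 1).  Published pair labels mix conventions
(e.g. length/width pairs quoted in rat numbering against text in mouse
numbering); the offset map, not guesswork, is the supported way to
reconcile them.

## What the synthetic generator emulates — and what it does not

Real ensembles come from ~100 ns molecular-dynamics simulations.  The
generator does not imitate the physics; it reproduces the *statistical
structure* the analysis consumes.  Each monitored pair distance follows
a discrete Ornstein–Uhlenbeck process
$$d(t{+}1) = d_0 + \varphi\,(d(t) - d_0) +
  \sqrt{1-\varphi^2}\,\sigma_{\mathrm{eff}}\,\varepsilon_t,
  \qquad \varphi = e^{-1/\tau},$$
the minimal stationary Gaussian model with a tunable correlation time.
The tethered variant damps the fluctuation
($\sigma_{\mathrm{eff}} = \sigma \cdot \texttt{tether\_factor}$) and
shifts the mean down by `d0_shift` per pair — the summary-level effect
of membrane restraint.  The process starts at $d_0$, so frame 1 is the
reference conformation exactly, and the stationary law gives a
closed-form oracle for the exceedance,
$P(d - d_0 > t) = 1 - \Phi(t/\sigma_{\mathrm{eff}})$.

Generator defaults are fixed study conditions, chosen once:

* `d0 = 19.3` Å per pair, so the free SDRP concentrates near 77 Å
  (modal bin [76, 78)); `d0_shift = 1.5` Å puts the tethered SDRP near
  71 Å (modal bin [70, 72)) — the separation characteristic of the
  free/tethered contrast.
* `sigma = 1.2` Å, a realistic side-chain breathing amplitude giving
  exceedance probabilities of a few percent at the 1.8–2 Å thresholds.
* `tau = 5` frames: ensemble snapshots are saved at intervals
  comparable to the distance relaxation time, so consecutive frames are
  only weakly correlated, as in a sparsely sampled trajectory.
* `tether_factor = 0.4`, `n_frames = 5000`.

The pseudo-structure places each pair on its own axis with three-atom
residues (N, CA, CB offset along z), so all three distance modes
resolve and all three reproduce the planted distance exactly.  Note the
generator's four pairs are *disjoint*: real monitored pairs can share a
residue, but a shared residue cannot follow two independent breathing
processes, so independence was chosen over literal pair labels.
Consequences for interpretation: passing tests demonstrate that the
metrics, binning, selection and cascade logic are correct on data whose
truth is known — they say nothing about force fields, convergence of
real MD, anharmonic or multi-well breathing, or correlations between
pairs, none of which the generator models.

The planted screen likewise samples score tables so that selective
compounds satisfy every funnel rule with a margin of at least 0.5 score
units, pan binders clear both docking cutoffs (and are therefore
removed by the differential rule), and decoys fail at least one rule
with margin.  Recovery of the planted set is thus a correctness check
on the cascade, not a statement about docking accuracy.

## Numerical choices

* **Bins and ties.**  Histogram edges at integer multiples of the bin
  width; modal-bin ties break toward the lower edge; representative
  ties break toward the lower frame index; rank-top ties break by
  compound id.  Every tie-break is deterministic.
* **Cutoffs.**  Strict `<` everywhere, so a score exactly at −3.5
  fails.  Missing scores are "did not dock": fatal on a positive
  requirement, counted as non-binding on the negative side of the
  differential rule.  Both paths are visible in the audit trail.
* **Tolerances.**  Distances are validated to 1e-9 Å against a
  brute-force per-frame oracle; PDB round trips are exact to the
  file format's 0.001 Å precision.
* **4PL fitting.**  `fit_logistic4()` fits
  $y = b + (a-b)/(1 + (x/\mathrm{IC}_{50})^h)$ by Levenberg–Marquardt
  on log10-dose with deterministic initialisation (bottom = min,
  top = max, hill = 1, IC50 at the interpolated half-range crossing),
  hill bounded to [0.1, 10], and up to five jittered restarts from a
  fixed internal seed, so identical inputs always give identical fits.
  Flat responses are refused rather than fitted.  The fit is invariant
  to dose-unit rescaling (IC50 rescales, the other parameters do not).
* **Degenerate inputs.**  Coincident pair members, empty chain
  selections, models with unequal atom counts (reported with the
  offending model index), insertion codes, non-finite scores and
  duplicate score keys are all rejected with specific errors rather
  than propagated.
* **Randomness.**  One integer seed feeds every stochastic component
  through per-stream derived states (one stream per pair, per score
  class, per noise column), so adding a stream never perturbs existing
  ones, and generation leaves the session's global RNG untouched.

## Problem sizes

The shipped tests and the reproduction script use 20,000-frame
ensembles for moment- and exceedance-recovery checks (sampling error
about 0.5% on a 5% exceedance at $\tau = 5$), 5,000 frames for the
qualitative free/tethered contrast, 50-frame ensembles for exact-oracle
comparisons, and 500-compound screens with 20 planted binders.  These
sizes make every statistical check sharp relative to its tolerance
while keeping a full run in seconds.

## Known limitations

* Gaussian, single-well breathing only; no multi-modal opening.
* Pairs are treated independently; no cross-pair covariance.
* PDB only (no mmCIF, DCD/XTC); no insertion codes or multi-altloc
  handling beyond keeping the first conformer.
* The cascade consumes scores; it cannot detect upstream docking
  pathologies, and score polarity must be "lower is better".
* The 4PL fitter reports point estimates and residuals, not
  confidence intervals.
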