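---
title: "Methods: bias quantification and recognition-site analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bias quantification and recognition-site analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ChemokineBias)
```

This vignette documents the statistical and geometric models the package
implements, the default parameters and why they were chosen, what the
synthetic-data generator does and does not emulate, and the limitations a
user should keep in mind. Code chunks are illustrative and not evaluated.

## 1. Dose–response model

Every trace is modelled as a four-parameter logistic (4PL) on
log10-molar concentration $x$:

$$r(x) = b + \frac{E_{max} - b}{1 + 10^{\,h\,(\log_{10}EC_{50} - x)}}$$

with baseline $b$, maximal response $E_{max}$, midpoint $\log_{10}EC_{50}$
and Hill slope $h$.

**Assumptions.** Responses are monotone in dose, noise is additive,
homoscedastic and Gaussian on the response scale, and replicates
(experiments) are independent. These match plate-based luminescence readouts
after normalization reasonably well, but heavy-tailed or proportional noise
is not modelled.

**Defaults and rationale.**

* `model = "hill_fixed_1"` — the Hill slope is fixed at 1 by default. With
  15-point single-replicate traces a free slope trades bias for a large
  variance inflation of $\log_{10}EC_{50}$; receptor-proximal readouts are
  usually adequately described by $h = 1$. `hill_free` is available and
  bounded to $[0.1, 10]$.
* Fitting uses `minpack.lm::nlsLM` (Levenberg–Marquardt) with box
  constraints: $\log_{10}EC_{50}$ is confined to the concentration grid
  ± 2 log units, so the optimizer cannot wander to unidentifiable plateaus.
  Starting values are taken from the data (min, max, grid midpoint).
* Traces whose response range is below `flat_tol` (1e-6 of the response
  unit) are flagged *degenerate* rather than fitted: a flat trace carries no
  EC50 information and must not silently enter a bias factor.
* `pooling = "per_experiment"` fits each replicate separately (after a
  combined fit that supplies starting values). Per-experiment fits are what
  make per-experiment bias factors — the replication unit of all downstream
  statistics — possible.

**Normalization conventions** (`normalizePanel`): `reference_max_100`
(responses as % of the reference ligand's maximal observed response, per
pathway), `fold_over_lowest_dose` (each trace relative to its own
lowest-dose point) and `untreated_100` (relative to a no-ligand control).
The first is the default because the bias factor is defined relative to a
reference ligand measured in the same system.

## 2. Bias factor

For pathway pair (P1, P2) — by default Gi dissociation and β-arrestin
recruitment —

$$\beta = \left[\log_{10}\frac{E_{max}}{EC_{50}}\Big|_{lig,P1}
 - \log_{10}\frac{E_{max}}{EC_{50}}\Big|_{lig,P2}\right]
 - \left[\;\text{same for the reference}\;\right]$$

computed as $\log_{10} E_{max} - \log_{10}EC_{50}$ from the fitted
parameters. Properties enforced and tested: $\beta = 0$ for the reference
against itself; antisymmetry under pathway swap and under ligand/reference
role exchange; invariance to common $E_{max}$ rescaling within a pathway
and to a common shift of $\log_{10}EC_{50}$ (unit changes).

Per-experiment β values are formed from matched experiment identifiers of
ligand and reference; a missing match is an error, never an imputation.
Classification (`gi_biased` / `arrestin_biased` / `balanced`) uses a
one-sample two-tailed t test of the per-experiment β values against zero at
`alpha = 0.05`. This deliberately reports "balanced" when replication is
too noisy to exclude zero — a sign claim without significance would
overstate the evidence.

**Many-vs-one comparison** (`compareVsReference`): one-way ANOVA across
ligand groups followed by Dunnett's test against the reference
(`multcomp::glht`), the standard procedure when several ligands are each
compared with one control. `compareTwo` provides the pairwise pooled-variance
Student's t test (Welch optional).

## 3. Synthetic-data generator

`generatePanel("ccl15_truncations")` encodes six N-terminal truncation
variants with full, nearly constant Gi efficacy/potency and monotonically
decreasing arrestin efficacy, including a pronounced drop between the
second and third variants. `simulatePanel` evaluates the 4PL on a
log10-molar grid (default −13…−6 in 0.5 steps — wide enough to define both
plateaus around EC50 ≈ 1 nM) and adds i.i.d. Gaussian noise (`noise_sd = 5`
response units, about 5% of the reference maximum, a typical plate-assay
scale) for `n_experiments = 8` replicates from a single seeded RNG stream.

**What it emulates:** replicate-to-replicate scatter, pathway-specific
efficacy/potency profiles, normalization pipelines, matched-replicate
bookkeeping.

**What it does not emulate:** plate/edge effects, proportional or
heteroscedastic error, day effects or any replicate correlation,
constitutive activity, biphasic curves, ligand depletion, and inter-assay
amplification differences beyond what the profile parameters encode. True
parameter values are therefore recoverable exactly in the noiseless limit —
which the tests exploit — but effect sizes should not be read as empirical
predictions.

The structural counterpart, `makeToyInterface`, builds small atom sets whose
SASA/BSA ground truth is computed by an *independent* latitude–longitude
quadrature oracle (`sasaOracle`), so the production engine is validated
against a different discretization, not against itself.

## 4. Structural methods

**I/O and annotation.** PDB/mmCIF parsing is delegated to `bio3d`;
alternate locations default to highest occupancy (ties to altloc "A").
Ballesteros–Weinstein numbering is attached from a residue→label map; the
shipped CCR1 map is anchored at T86^2.56, W90^2.60, Y113^3.32, Y255^6.51,
D280^7.32, E287^7.39 and Y291^7.43, with helix spans assigned by class-A
homology. Anchor identities are verified against the model — a mismatch is
an error, never a silent misnumbering. Non-anchor labels are approximate and
replaceable via `readBWMap`.

**CRS partition** (`defineSites`). CRS1: resolved receptor N-terminus
through residue 26, minus the CRS1.5 region (23–25 around C24). CRS2:
receptor residues with any heavy atom within `crs2_cutoff = 4.5` Å of the
chemokine segment preceding its first core cysteine — a geometric rather
than list-based definition, because the pocket lining depends on the ligand
pose. CRS3: chemokine 30s loop (50–57) and β1–β2 strands against ECL2/ECL3
and the extracellular tips of TM5/TM6. Receptor sets are made pairwise
disjoint with priority CRS1 > CRS1.5 > CRS3 > CRS2.

**SASA/BSA.** Shrake–Rupley with a deterministic golden-spiral point set
(default `n_points = 960`; at least 92 enforced — 960 puts the
single-sphere discretization error far below the 0.5% tolerance while
keeping interface-sized systems interactive), probe radius 1.4 Å (water),
Bondi-type van der Waals radii, hydrogens ignored (cryo-EM coordinates
rarely include them). Buried area follows the halved-ΔSASA convention,
$BSA = (SASA_A + SASA_B - SASA_{AB})/2$, with the unhalved ΔSASA also
reported.

**Hydrogen bonds.** Donor/acceptor chemistry tables over N/O/S heavy atoms;
distance ≤ 3.5 Å; the D–H⋯A angle criterion (≥ 120°) applies only when
hydrogens are present. Covalent-range contacts (< 2.2 Å), intra-residue
pairs and the peptide N(i)–O(i−1) contact are excluded.

**Polar-network toggle.** The Y7.43 hydroxyl is classified `tm2_engaged`
(within 3.5 Å of T2.56 OG1 or W2.60 NE1), `tm3_tm6_engaged` (within 3.5 Å
of the Y3.32/Y6.51 hydroxyls), `mixed` (alternate rotamers disagree) or
`undetermined` (hydroxyl unresolved; warning).

**Angles.** Superposition uses the Kabsch algorithm (SVD with determinant
correction, so only proper rotations are returned; mirror-degenerate or
collinear selections are rejected). The interdomain rotation superposes the
two complexes on an alignment selection (receptor Cα) and reports the
residual rotation of a measurement selection (chemokine-core Cα,
corresponded by offset from the first core cysteine). Side-chain sway
superposes the local backbone (± 3 residues) and measures the angle between
CB→ring-centroid vectors (aromatics) or CB→distal-atom vectors; a
χ1-dihedral variant is available.

## 5. Open questions and decisions

* Sites may overlap in space; the disjointness rule assigns each *receptor*
  residue to exactly one site so per-site BSA sums remain interpretable.
  Chemokine sets are allowed to overlap (e.g. the core-disulfide region).
* The CRS2 pocket is distance-defined; `crs2_cutoff` is exposed because the
  literature uses 4–5 Å interchangeably.
* With cryo-EM coordinates (no hydrogens) hydrogen bonds are necessarily
  distance+chemistry calls; expect a small false-positive rate relative to
  hydrogen-aware criteria.
* The classification threshold `alpha = 0.05` and the two-pathway default
  pair are conventions, both overridable.

## 6. Limitations

* Non-anchor BW labels on the shipped CCR1 map are homology-based
  approximations; supply a curated map for residue-level claims outside the
  anchors.
* The 4PL assumes monotone single-site behaviour; biphasic or bell-shaped
  data will fit poorly and should be caught by inspecting `rss` and the
  per-experiment spread.
* SASA uses a fixed radius table; modified residues and ions beyond the
  table require explicit radius overrides.
* Angle measures assume the alignment selection is genuinely rigid between
  states; if the receptor core itself rearranges, the "interdomain" number
  mixes both motions.
* The statistical layer treats experiments as exchangeable replicates;
  batch structure, if present, must be handled upstream.
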