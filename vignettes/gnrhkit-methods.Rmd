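---
title: "Methods: decoy triage and activation analysis in gnrhkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decoy triage and activation analysis in gnrhkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnrhkit)
```

`gnrhkit` analyses two kinds of object from peptide–GPCR modelling
studies: score tables plus coordinates of protein–peptide docking
decoys, and multi-frame receptor trajectories.  This vignette explains
the procedures, the parameters that matter, the synthetic planted-truth
generators the tests run on, and the numerical and design choices made
where the methodology left room.

## Residue addressing

Class A GPCR residues are addressed by Ballesteros–Weinstein (BW) codes
`X.YY` (helix X, position YY relative to the helix's most conserved
residue, numbered 50).  A `bw_map` translates codes to concrete
(chain, residue-number) pairs of a model; the shipped GnRH1R map uses
author numbering (3.50 → R139, 6.33 → T265, 2.50 → N87, 6.48 → W280,
7.49 → D319, 7.53 → Y323, …) and lives in an editable YAML file so
other numbering conventions or chain labels drop in without code
changes.  Deposited models differ in chain labelling, which is why the
chain id is part of every map entry rather than an assumption.

## Decoy triage

Docking runs produce large decoy sets in which the near-native binding
mode, if sampled at all, sits in a well-populated, low-energy,
contact-forming cluster.  `run_triage()` composes four elimination
gates in sequence; because each gate is a pure per-decoy or per-cluster
predicate, the surviving set is independent of the order in which rows
arrive, and survivor sets are nested across stages by construction.

1. **Cluster population, strict `< 50`.**  Clustering is either taken
   from the input records or computed by `cluster_decoys()`: a greedy
   centroid scheme that visits decoys in ascending total score and
   assigns each to the first cluster whose seed lies within a backbone
   RMSD radius (default 2 Å, least-squares superposed).  Greedy
   centroid assignment is deterministic and cheap; it stands in for
   heavier energy-based clustering tools whose outputs can equally be
   ingested.
2. **Population gate and score gates.**  Clusters must exceed
   population 1000 (strict `≤` eliminates); surviving decoys must have
   total score ≤ −620 REU and interface ΔG ≤ 0 REU.  Both printed
   inequalities are implemented strictly.  Whether the score gates act
   on whole clusters or individual decoys is ambiguous in the source
   protocol; they are applied per decoy here, with cluster-level
   statistics reported alongside.
3. **General contacts.**  A contact is an inter-chain residue pair
   whose representative atoms (Cβ; Cα for glycine) lie within 5 Å.
   A non-glycine residue without a Cβ raises an error rather than
   silently substituting Cα, since a silent fallback would change
   contact counts invisibly.
4. **Candidate selection.**  Decoys need at least one contact with an
   experimentally important receptor residue (the shipped list covers
   the mutagenesis-supported GnRH1R set, e.g. W280^6.48, Y283^6.51,
   D302^7.31) and ΔG ≤ −20 REU; survivors are ranked by
   important-contact count (descending), then ΔG (ascending), then
   total score, then decoy id.  The two trailing tie-break keys are a
   package choice so that ranking is a total order and permutation
   tests can assert bitwise-identical output.

The protocol's running text and its summary table disagree about which
stage number holds the contact gate; the table ordering is implemented,
and the audit log names every elimination by criterion rather than by
stage number, which makes the disagreement immaterial.

### Cluster statistics

For each pair of clusters surviving the population gate and each score
metric, the package reports (never eliminates on): the two-sided
Mann–Whitney U (midrank ties; exact enumeration when
`min(n1, n2) ≤ 8` and tie-free, else normal approximation with tie and
continuity corrections), Bonferroni adjustment over the full family of
pairs × metrics (the most conservative family choice, since the
original analysis does not state its `m`), the rank-biserial effect
size, and a KS normality statistic per cluster computed against a
normal with the cluster's own fitted mean and standard deviation.
Fitting the reference parameters makes the asymptotic p-value
conservative (the Lilliefors caveat); the result carries a `caveat`
field saying so.

The effect-size formula is printed in the source material as
`EF = 1 − 2U/(n1 − n2)`, which is undefined for equal sample sizes —
exactly the balanced-cluster case it would be used on.  The package
treats the denominator as a typo for `n1·n2` (the rank-biserial
correlation, bounded in [−1, 1] and antisymmetric under sample swap)
and makes that the default, while an `"as_printed"` mode reproduces the
printed formula and raises an explicit division-by-zero error at
`n1 = n2` so the discrepancy is visible rather than papered over.

## Trajectory metrics

**Activation.**  The TM3–TM6 metric is the per-frame Euclidean distance
between the Cα atoms of BW 3.50 and 6.33.  Cα is the package's stated
convention: the source names only residues, and Cα is the choice that
reproduces the published inactive-state anchor of 7.9 Å.
`detect_activation()` applies a trailing rolling mean (default window
10 frames, shrinking at the start) and flags activation when the
smoothed trace reaches `baseline + threshold_delta` and stays there to
the end of the trajectory.  The default threshold of 3 Å is a
deliberately conservative gate under an activation-scale shift of
about 4 Å; both threshold and window are parameters.  The default
baseline is the mean of the first quarter of the trace (capped at 100
frames), standing in for an equilibrated inactive segment.

**Hydrogen bonds.**  Donor heavy atom D with explicit hydrogen H bonds
acceptor A when the D–A distance is ≤ 3.5 Å and the donor-centred angle
between D→H and D→A is ≤ 20°.  The donor-centred convention matches
the visualisation-tool criterion the distance/angle pair comes from; an
acceptor-centred variant was considered and rejected because the two
conventions disagree exactly in the marginal geometries the cutoff is
meant to arbitrate.  In the default `"n_o"` mode donors are nitrogens
and acceptors oxygens; `"generic"` mode allows both elements on both
sides.  A nitrogen donor without an explicit attached hydrogen (within
1.25 Å) is an error in `"n_o"` mode — silent skipping would
under-count bonds on structures stripped of hydrogens — while
occupancy scans (`hbond_occupancy()`) skip such donors, since partial
hydrogenation of side chains is normal there.

**Salt bridges.**  Present when any basic side-chain nitrogen (ARG
NE/NH1/NH2, LYS NZ) is within 3.5 Å of any acidic side-chain oxygen
(ASP OD1/OD2, GLU OE1/OE2).  Histidine is excluded by default because a
PDB file does not encode its protonation state; `include_his = TRUE`
opts in.  Lifetimes are maximal runs of consecutive present frames,
which reconstruct the boolean series exactly — the property the tests
assert.

**Signature panel.**  After superposing the active model onto the
inactive one over the TM1–TM4 core Cα (the part of the bundle that
moves least on activation), the panel reports: the TM6 rigid-body
rotation angle (from the optimal Kabsch rotation between the centred
TM6 Cα sets), the tilt between TM6 principal axes, the displacement of
the cytoplasmic third of TM6 split into components perpendicular and
parallel to the membrane normal (default the z axis), per-residue Cα
displacements of the micro-switch motif residues, and intracellular
loop centroid displacements.  The total rotation angle, rather than the
principal-axis tilt alone, is the headline `tm6_rotation` because a
rotation of a helix about its own axis — a real component of the
toggle-switch rearrangement — leaves the principal axis unchanged and
would read as zero under an axis-tilt definition; both numbers are
reported.  Exact TM6/loop segment boundaries are configuration, not
assertion: the shipped defaults are the synthetic bundle's spans.

## Water-mediated network

A frame is *bridged* for a residue pair when at least one water oxygen
lies within 3.5 Å of a polar heavy atom (N/O, side chain or backbone)
of **both** partners.  This criterion is deliberately distance-only —
distinct from the angular hydrogen-bond operation — because that is how
bridge occupancy is defined in the methodology this package implements;
"polar heavy atom" is interpreted as all N/O of the residue since no
atom list is given.  Occupancy is the bridged fraction of frames; the
significance threshold (default 10 %) is configuration.
`classify_interaction()` gives direct contact (any inter-partner
heavy-atom pair ≤ 3.5 Å) priority over water mediation, so the three
per-frame modes are mutually exclusive and exhaustive.  Time series are
smoothed by a centred 50-frame moving average whose window truncates at
the series edges (no extrapolation, length preserved); the edge policy
is a package choice, as is emitting both raw and smoothed series since
published occupancy windows do not state which was used.

**RDF.**  `g(r)` uses shell counts normalised by
`n_ref · 4πr²dr · ρ`, with the target density taken from the per-frame
orthorhombic box volume under the minimum-image convention; without a
box an explicit bulk density is required rather than guessed.  Bin
width defaults to 0.05 Å over 8 Å, resolving the ≈ 2.8 Å first
hydration-shell peak position to better than one bin.

## Sub-domain PCA

Frames are superposed on a core Cα selection (default: all Cα outside
the analysed range) to remove rigid-body tumbling — without this, PC1
simply captures global drift.  The selected atoms (default backbone
N/CA/C/O of residues 1–17, avoiding side-chain naming fragility; an
all-heavy mode exists) are flattened to a frames × 3N matrix,
column-centred, and the covariance matrix eigendecomposed.
Explained-variance ratios are eigenvalues over their sum; projection
variance along component k equals eigenvalue k, and component signs are
fixed so the largest-magnitude loading is positive, making the
decomposition reproducible to machine precision.  The KDE population
map uses Gaussian kernels with Scott's-rule bandwidths
(`σᵢ·n^(−1/6)`) on a grid extended three bandwidths beyond the data, so
its numerical integral is ≈ 1 (the tests require ≥ 0.97).  A
zero-variance projection is an error with advice, not a silent
degenerate surface.

## What the synthetic generators emulate — and what they do not

`gen_decoy_set()` draws per-cluster Gaussian scores (the continuous
unimodal shape that violin plots and normality testing of real decoy
clusters suggest) and docks a toy 10-residue peptide — the GnRH
sequence, pyroglutamate modelled as Glu — at one site per cluster of a
toy receptor.  Only the native site touches important residues; a
second site touches generic residues only; further sites are isolated.
The default plant is one native-like cluster of 1200 decoys satisfying
every survival criterion in expectation (total score −700 ± 15 REU,
ΔG −35 ± 4 REU) against competitors of 300 and 40 decoys that fail the
population, score and contact gates, emulating a triage-ready
clustering outcome at roughly half the scale of a real 27 000-decoy
campaign.

`gen_bundle_trajectory()` builds seven ideal α-helices (1.5 Å rise,
100°/residue) on an 11 Å ring, with helix spans carrying GnRH1R author
numbering so the shipped BW map resolves.  It plants, per frame:
Gaussian jitter (0.02 Å — detection-criteria noise, not thermal
motion), a rigid TM6 translation along the 3.50→6.33 direction from
the swing frame onward (so the planted distance increase is exact),
explicit three-site waters placed midway between partner polar atoms on
a seeded Bernoulli subset of frames, and a salt bridge whose acidic
oxygens sit at 3.2 Å of the basic nitrogen on pattern-true frames and
10 Å away otherwise, with the donor hydrogen collinear so the same
frames register under the hydrogen-bond criterion.  Default conditions
are a 1000-frame, 1 ns/frame observation with the swing at frame 500
(the activation-at-≈1 µs scenario) and an 88 % occupancy 2.50–2.53
bridge (the high-occupancy end of the published N87–E90 range).  After
generation, every planted feature is re-measured with plain distance
checks and any violation aborts — ground truth is guaranteed
detectable, never assumed.

These generators validate *detection*: geometry satisfying or violating
each criterion at known frames.  They are not physical simulations — no
force field, no solvent box beyond the planted waters, no realistic
side-chain rotamers, no correlated dynamics — so passing tests show the
operators measure what they claim on data with known answers, not that
any particular biological system behaves a certain way.

A companion `gnrh1r_synthetic_reference()` model anchors the
measurement pipeline: the same idealised bundle with TM6 placed so the
3.50–6.33 Cα distance equals the published inactive-state value of
7.9 Å by construction.  It is a synthetic stand-in, not the deposited
crystal structure; what its test verifies is the full path from BW code
to rounded distance.

## Numerical choices and conventions

* Coordinates are Å throughout; frame indices are 0-based in all
  interfaces (a 1000-frame run spans frames 0–999); residue numbers are
  author numbering.
* PDB round-trips are exact to the format's 0.001 Å precision; only
  altloc 'A' or blank is kept, giving an unambiguous single conformer.
* Waters are residues named HOH/TIP3/WAT/SOL with oxygen O/OH2/OW.
* Ties in Mann–Whitney ranks use midranks; identical pooled samples
  return p = 1 with a degenerate flag instead of NaN.
* Distance comparisons use `≤` at every published cutoff, so a pair at
  exactly 3.5 Å counts.
* Problem sizes in the test-suite and acceptance runs — 20 triage seeds
  of 1540 decoys, 1000-frame trajectories, a 10⁴-point RDF gas — are
  chosen as the smallest sizes at which the binomial and shell-count
  tolerances the checks assert are comfortably resolved.

## Known limitations

* The greedy clusterer is a stand-in; it recovers well-separated
  planted clusters exactly but is not a replacement for energy-based
  clustering of real decoy ensembles.
* Interaction typing beyond distances/angles (π–π, cation–π stacking
  classes) is out of scope; those assignments belong to dedicated
  interaction-typing tools.
* ΔSASA is ingested, never computed; surface-area algorithms are a
  separate concern.
* The RDF assumes an orthorhombic box; triclinic cells are not
  minimum-imaged.
* KS normality on fitted parameters is conservative; for decisive
  normality testing a Lilliefors-corrected p would be needed, which is
  why the statistic is reported with a caveat and never used as a gate.
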