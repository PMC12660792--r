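# gnrhkit

Docking-pose triage and activation analysis for peptide-bound class A
GPCRs, built around the gonadotrophin-releasing hormone receptor
(GnRH1R) system.

## The problem

Peptide–receptor docking produces tens of thousands of candidate poses
("decoys") of which at most a handful are near-native, and
microsecond-scale molecular dynamics of the selected complexes produces
trajectories whose activation-relevant geometry has to be distilled
into a few interpretable observables.  `gnrhkit` implements both halves
of that workflow as composable, tibble-returning R functions:

**Decoy triage.** A staged elimination protocol over clustered decoy
score tables (total score, interface binding energy ΔG, buried
interface area ΔSASA, all in Rosetta-style units):

| gate | criterion (eliminate when) |
|---|---|
| 1 — cluster population | population < 50 |
| 2 — population / scores | population ≤ 1000; total score > −620 REU; ΔG > 0 REU |
| 3 — general contacts | inter-chain Cβ–Cβ contacts (< 5 Å; Cα for Gly) < 1 |
| 4 — candidate selection | important contacts < 1; ΔG > −20 REU |

Survivors are ranked by important-contact count (descending) then ΔG
(ascending).  Alongside the gates, every surviving cluster pair is
compared per score metric with two-sided Mann–Whitney U tests
(Bonferroni-corrected over the pairs × metrics family) and the
rank-biserial effect size EF = 1 − 2U/(n₁n₂), with Kolmogorov–Smirnov
normality checks per cluster.

**Trajectory analysis.** The canonical class A activation metric — the
Cα–Cα distance between the Ballesteros–Weinstein 3.50 and 6.33 residues
(R139 and T265 in GnRH1R; ≈ 8 Å inactive, + ≈ 4 Å on TM6 outward
movement) — with sustained-shift detection; hydrogen bonds under the
3.5 Å N–O / 20° donor-centred criterion; salt bridges (3.5 Å N–O) with
run-length lifetimes; water-mediated bridges (one water oxygen within
3.5 Å of polar heavy atoms of both partners), their occupancies and the
10 % significance flag; direct-vs-water-mediated classification;
50-frame moving-average smoothing; radial distribution functions for
hydration structure; backbone RMSD; a TM6 rotation/translation
signature panel; and sub-domain PCA with Gaussian-KDE population maps.

Everything is testable without external downloads: the package ships
planted-truth synthetic generators (`gen_decoy_set()`,
`gen_bundle_trajectory()`) that build decoy sets and 7-helix-bundle
trajectories whose cluster structure, TM6 swing, water-bridge
occupancies and salt-bridge patterns are known exactly, plus a
synthetic inactive-receptor reference model
(`gnrh1r_synthetic_reference()`) constructed to the published inactive
TM3–TM6 geometry.

## Worked example

```r
library(gnrhkit)

# a 300-frame synthetic receptor trajectory with a +4 Å TM6 swing
# planted at frame 150 and an N87–E90 water bridge at 88 % occupancy
out  <- gen_bundle_trajectory(bundle_plant_spec(n_frames = 300,
                                                swing_frame = 150,
                                                seed = 42))
traj <- out$trajectory
traj
#> <trajectory> 300 frames x 1447 atoms, 1 ns/frame

act <- detect_activation(tm3_tm6_trace(traj), baseline_frames = 75)
act
#> <activation_report> activated at frame 157; delta = 4.01 A over baseline 21.54 A

water_bridges(traj, c("A/87", "A/90"))
#> <bridge_series> A/87 - A/90: occupancy 0.867 (significant at 10%)

tm3_tm6_distance(gnrh1r_synthetic_reference())
#> [1] 7.9
```

The activation report says the rolling mean of the TM3–TM6 trace rose
by 4.01 Å over the pre-swing baseline and stayed there from frame 157
(the detector's 10-frame window lags the planted swing at frame 150 by
design); the bridge series recovers the planted 88 % water-bridge
occupancy as 0.867 over 300 frames and flags it significant at the 10 %
threshold; and the synthetic inactive reference reproduces its
constructed 7.9 Å TM3–TM6 anchor through the full measurement path
(Ballesteros–Weinstein resolution → Cα extraction → distance).

`autoplot()` methods draw each result type (activation trace, bridge
series, PCA projection, KDE surface, RDF curve), and `tidy()`/
`glance()` return per-frame and one-row summary tibbles.

The triage half runs the same way:

```r
dec <- gen_decoy_set(decoy_plant_spec(seed = 1))
res <- run_triage(dec$decoys, triage_config(), dec$structures)
glance(res)        # counts per stage, top candidate
tidy(res)          # full audit log of eliminations with reasons
```

A config-driven end-to-end run (`run_pipeline()`) writes all of the
above as seed-stamped TSV/JSON reports.

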