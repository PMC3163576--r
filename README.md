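# histomri

Spatial registration of 3D tumor histology to in vivo MRI.

MRI can monitor tumors non-invasively, but only histology tells you what a
voxel's signal actually means. `histomri` establishes that correspondence in
3D for serially sectioned tumors: it reconstructs a stack of digitized
H&E sections into a 3D color volume, registers it to the in vivo MR image
through an intermediate ex vivo MRI of the fixed specimen, and uses the
result to quantify registration accuracy and to characterize tissue classes
by their MR intensities.

The chain is anchored by a **reference cutting plane** (cut through the
fixed tumor along its longest axis, perpendicular to the subcutaneous side)
shared by all three images, and consists of:

| step | moving → fixed | transform models |
|---|---|---|
| `stack_sections()` | section *i* → aligned section *i−1* | 2D rigid |
| `stack2ex()` | histology stack → ex vivo MRI | rigid → affine → B-spline |
| `ex2in()` | ex vivo MRI → realigned in vivo MRI | rigid → similarity → B-spline |
| `stack2in()` | concatenation; warps the color stack onto the in vivo grid | composite |

Registration is intensity-based (mutual information for inter-modality
steps, normalized correlation for mono-modal stacking) with a
multiresolution pyramid, adaptive stochastic gradient descent and a
deterministic full-sample refinement; all of it is seeded and
bit-reproducible. The transforms follow the pull-back convention, so each
stage's linear determinant is the physical volume change of the
corresponding processing step:

- `global_volume_change(ex2in)` ≈ −13% — fixation shrinkage,
- `global_volume_change(stack2ex)` ≈ +2% — sectioning expansion,

and `angulation_report()` gives the out-of-plane angulation of the rigid
stage (the residual reference-plane positioning error, in degrees).
Accuracy is measured as the RMS distance between corresponding landmarks
(`landmark_rms()`, `stagewise_landmark_rms()`), and tissue classes are
characterized by the interquartile range of their intensity PDFs
(`estimate_pdf()`, `interquartile_segment()`).

Because no imaging data are deposited with the methodology, the package
ships a seeded phantom generator (`generate_phantom()`) that produces the
entire study setup with exact ground truth — an in vivo tumor volume with
viable/necrotic/hemorrhagic compartments, its shrunk and deformed ex vivo
counterpart, a jittered H&E-like section stack, landmarks and VOI masks in
every frame — so every claim the package makes is testable against known
truth.

## Worked example

```r
library(histomri)

res <- run_all(out_dir = "phantom_run", seed = 1)

round(res$evaluation$rms, 3)
#> initial   rigid  affine elastic
#>   2.740   0.698   0.605   0.264

res$evaluation$table
#>       step dV_global_percent angulation_deg
#> 1 stack2ex          4.031398       2.964499
#> 2    ex2in        -13.234945       1.992302
```

Reading the output: the reference plane alone aligns the phantom's ten
landmarks to 2.74 mm RMS; the rigid stages bring that to 0.70 mm, the
affine/similarity stages (which absorb the programmed 13.2% fixation
shrinkage and the anisotropic sectioning expansion) to 0.60 mm, and the
elastic refinement to 0.26 mm — about a tenth of the initial mismatch.
The recovered ex2in volume change of −13.2% matches the phantom's
programmed fixation shrinkage, and the recovered angulations are within a
degree of the simulated reference-plane tilts. `out_dir` receives the
warped color stack, all transform files (plain text, lossless), per-stage
metric logs, the landmark/angulation/volume-change tables as CSV, and a
JSON run manifest whose seed reproduces every transform byte-for-byte.

A thin command-line wrapper is installed at
`system.file("cli", "histomri", package = "histomri")` with subcommands
`phantom`, `stack`, `run-all` and `evaluate`.

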