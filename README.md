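# flexalign

Single-particle cryo-EM processing for large, flexible, multi-module
complexes — the regime where whole-particle ("consensus") alignment
fails because rigid-body motion between modules blurs every part of the
map that is far from the alignment centre.

The package implements, in R with a small C++ core, the module-wise
processing strategy used for elongated secretin-type channels: after a
consensus alignment,

1. **residual signal subtraction (RSS)** removes the CTF-modulated
   projection of everything *outside* a chosen module from each
   particle image:
   `out_i = img_i − s_i · CTF_i{ P[(1 − keep) · V](e_i, o_i) }`,
   where `P` is the projection operator, `V` the consensus map,
   `keep` a soft 3D mask of the module, `e_i, o_i` the particle's
   Euler angles (ZYZ, `M = Rz(ψ) Ry(θ) Rz(φ)`) and origin;
2. **recentering** maps a chosen 3D point `c` of the reference into
   every image (`(M c)_xy + o`), re-windows each particle about that
   point in a smaller box, stores the sub-pixel remainder in the
   origin fields, and depth-corrects the defocus by `(M c)_z` times
   the pixel size;
3. **local projection matching** realigns the recentered module
   against its own reference with a per-particle CTF-matched
   normalised cross-correlation.

Around this core the package provides the validation toolbox that such
a study needs: an **eigenimage MSA test** for the cyclic symmetry order
of top views (randomly rotated copies → translational alignment → PCA →
angular harmonic analysis), **FSC** with threshold-crossing resolution,
**global and per-voxel local cross-correlation**, **B-factor
sharpening**, low-pass and MTF correction, plus STAR and MRC2014
readers/writers. A built-in **synthetic flexible-particle simulator**
(stacked C13 rings + membrane barrel with a rocking hinge, helical
protomer arrangement, CTF at 300 kV, white noise) supplies ground truth
for scoring every stage.

## Worked example

```r
library(flexalign)

# a small flexible phantom: 64 px box, 13-fold rings, 8-degree hinge
spec <- phantom_spec(box = 64, ring_z = c(-24, -20, -12, -8, -1, 7),
                     ring_radii = c(10, 10, 11, 11, 10, 12),
                     barrel_z = 15, barrel_radius = 13,
                     barrel_half_len = 5, hinge_z = 4)
cfg <- default_config(seed = 1)
cfg$phantom <- spec
cfg$simulate$n <- 100
res <- run_pipeline(cfg, verbose = TRUE)
```

which prints, stage by stage:

```
simulate: n=100 box=64 snr=0.08
consensus: global 5 deg (C13), 2-fold binned
consensus: local rounds (two hypotheses)
consensus: full-resolution refinement of both hypotheses
consensus: alternative hypothesis won for 43 of 100 particles
consensus: whole-particle median 5.29 deg; cap median 7.85 deg
subtract+recenter: cap centroid (0.0, -0.0, 13.5), box 48
module align: subtract, recenter, local rounds
module align: cap median 7.20 deg (consensus gave 7.85)
symmetry: order C13 (confidence 272704.2)
metrics: FSC 0.143 threshold crossing at 15.5 A, CC 0.686
```

Read: consensus alignment of the whole flexible particle leaves a
median error of 7.9 degrees on the rocking cap module; after tail
subtraction and recentering, local matching of the cap alone reduces
it to 7.2 degrees on this deliberately tiny example. On the standard
full-size run (96 px box, n = 800, ~13 minutes on one CPU) the same
pipeline prints a consensus cap error of 4.0 degrees and a module
error of 2.8 degrees — a 1.4-fold improvement. The eigenimage test on
a top view returns the built 13-fold order, and the cap
reconstruction from the realigned sub-particles reaches 15.5 Å (FSC
0.143 against the reference) with a map correlation of 0.69 at that
resolution.

Individual stages are ordinary functions (`simulate_particles()`,
`subtract_signal()`, `recenter_stack()`, `assign_orientations()`,
`assess_symmetry()`, `fsc()`, `local_cc()`, ...) and a thin command
line lives in `inst/cli/flexalign`
(`simulate | subtract | recenter | align | symmetry | fsc | localcc |
postprocess | convert | run`).

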