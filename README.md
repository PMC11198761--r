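# slipsir

Slip interface recognition for MR elastography (MRE) of tumor–brain
adhesion.

## The scientific problem

Whether a meningioma is adherent to the surrounding brain, or separated
from it by a cleavage plane that lets it slip, is one of the main
determinants of how difficult and risky its resection will be — and it is
poorly predicted by conventional preoperative MRI. MRE offers a mechanical
probe: the scanner vibrates the head at 60 Hz, motion-encoding gradients
turn the micron-scale tissue displacement into image phase, and the
displacement field is sampled at 8 evenly spaced phase offsets of the
vibration cycle in 6 encoding polarities (±x, ±y, ±z).

At a *slip interface* the tumor and brain move independently, so the
displacement field is discontinuous across the boundary and the local
shear strain is anomalously high there. At an *adherent* interface motion
is transmitted continuously and no such strain band appears. `slipsir`
turns this observation into a quantitative, per-boundary-point adhesion
classification and a whole-tumor adhesion percentage, together with a
synthetic phantom generator with known ground truth, a baseline boundary
metric, and the statistics used to evaluate such metrics against surgical
findings.

## The measurement chain

**Phase to displacement.** For each encoding direction $d$, the two
polarities give $u_d = (\varphi_{+d} - \varphi_{-d}) / (2s)$, cancelling
static phase; $s$ is the encoding sensitivity.

**Octahedral shear strain (OSS).** From the symmetric strain tensor
$\varepsilon_{ij} = \tfrac12(\partial_i u_j + \partial_j u_i)$, computed by
central differences in physical spacing,

$$\mathrm{OSS} = \tfrac23\bigl[(\varepsilon_{xx}-\varepsilon_{yy})^2 +
(\varepsilon_{yy}-\varepsilon_{zz})^2 + (\varepsilon_{zz}-\varepsilon_{xx})^2 +
6(\varepsilon_{xy}^2+\varepsilon_{xz}^2+\varepsilon_{yz}^2)\bigr]^{1/2},$$

a rotation-invariant scalar, averaged over the 8 phase offsets.

**Normalized OSS (NOSS).** Strain scales with the locally delivered
vibration, so OSS is divided by the combined first-harmonic displacement
amplitude $A = (A_x^2 + A_y^2 + A_z^2)^{1/2}$, where $A_c$ is twice the
magnitude of the first DFT bin of the 8-offset series divided by 8. NOSS
is invariant to the overall drive amplitude; voxels with $A$ below a small
guard are masked.

**Slip interface recognition (SIR).** On each axial slice, the region of
interest around the tumor ROI (bounding box + 3 px) is standardized so its
maximum NOSS is 1, the ROI boundary is traced (Moore neighborhood,
clockwise), and each boundary point $a$ with intensity $I_a$ and
surrounding patch $P$ (3×3, escalated to 5×5 when
$|\bar{P}_{3\times3} - I_a| < 0.065$) is called **non-adherent** if any of:

- **Condition I** — $I_a > 0.85\,\max(\mathrm{RP})$ or
  $I_a < 1.15\,\min(\mathrm{RP})$: the point is itself a strain extreme;
- **Condition II** — $|I_a - \bar{P}| > \tau$ with
  $\tau = 0.20\,(\max P - \min P)$: the point sits off its local
  neighborhood, as on the flank of a strain band;
- **Condition III** — $|I_a - \bar{P}| \le \tau$ and
  $\max P - \min P > 0.80\,I_a$: the neighborhood itself straddles a steep
  band.

The adhesion percentage pools all boundary points of all slices:
$\%\,\text{non-adhesion} = 100\,\cdot n_{\text{non-adherent}} / n_{\text{total}}$.

## Worked example

A 64×64×32 phantom (1.875×1.875×3 mm voxels) with a 15 mm tumor whose
upper half slips against the background wave:

```r
library(slipsir)

spec <- phantomSpec(slipFraction = 0.5, seed = 42)
spec
#> PhantomSpec: grid 64 x 64 x 32 @ (1.875, 1.875, 3.000) mm
#>   tumor: radius 15 mm at voxel (31.5, 31.5, 15.5), slip fraction 0.5
#>   wave: A = 1 um, lambda = 30 mm; tumor A = 1 um, lag = 1.571 rad

ph   <- simulatePhantom(spec)
maps <- computeNOSS(phantomPhase(ph), mask = brainMask(ph))
maps$noss
#> ScalarMap <NOSS>: grid 64 x 64 x 32
#>   defined voxels: 100800 / 131072; range [0.06067, 0.3702]

res <- runSIR(maps$noss, tumorMask(ph))
res
#> AdhesionResult: 336 boundary points over 10 slices
#>   non-adhesion: 71.73%  adhesion: 28.27%
#>   fired conditions  I: 99  II: 127  III: 15

trueSlipFraction(ph)       # 0.5
nonAdhesionPct(res)        # 71.73
```

A fully adherent phantom (`slipFraction = 0`) under the same conditions
scores ≈ 28% and a fully slipping one (`slipFraction = 1`) ≈ 97%, so the
score rises monotonically with the true slip extent.

The baseline comparator — Shannon entropy of the across-boundary NOSS
differences sampled along outward boundary normals:

```r
base <- runEntropyBaseline(maps$noss, tumorMask(ph))
base$entropy               # 3.602 bits over 336 boundary values
```

And the agreement statistics, here Cohen's kappa on a 3×3 contingency
table of a preoperative ordinal grade against surgical findings:

```r
k <- cohensKappa(matrix(c(4, 7, 6,  5, 9, 10,  2, 3, 6), 3, byrow = TRUE))
#> kappa = 0.057 (SE 0.095, 95% CI -0.13 to 0.24)
```

`aucMannWhitney()`, `delongTest()` (paired ROC comparison from structural
components) and `iccTwoWay()` (ICC(2,1)) complete the evaluation module,
and `runPipeline()` binds all stages into one seeded, provenance-stamped
on-disk run.

## Command line

A thin CLI over the exported functions is installed at
`system.file("cli", "slipscan.R", package = "slipsir")`:

```sh
Rscript slipscan.R phantom  --out ph/ --seed 5 --slip-fraction 1
Rscript slipscan.R noss     --out run/ --phase p_xp.nii.gz,...(6) --tumor-mask t.nii.gz
Rscript slipscan.R sir      --out sir/ --noss run/noss.nii.gz --tumor-mask t.nii.gz
Rscript slipscan.R baseline --out b/   --noss run/noss.nii.gz --tumor-mask t.nii.gz
Rscript slipscan.R eval kappa --counts table.csv
```

Logs with stage timers go to stderr; exit codes are 0 (ok), 1 (validation
error), 2 (compute error). A YAML `--config` can supply any pipeline
field; flags win.

## License

MIT.
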