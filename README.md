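# SpringCranio

Radiation-free planning of spring-assisted cranioplasty (SAC) from 3D
head-surface scans, in R.

## The problem

Scaphocephaly — premature fusion of the sagittal suture — leaves an infant
skull long and narrow. SAC corrects it with two parasagittal osteotomies
and two pre-crimped metallic spring distractors (models S10/S12/S14,
nominal fully-open length 60 mm) that push the parietal flaps apart over
the days after surgery. Finite-element models can predict the expansion,
but conventionally need a CT scan, which most SAC candidates never
receive.

SpringCranio builds the simulation model from a surface scan instead. A
head surface is cut at the nasion–tragion plane and offset inward by the
population-average scalp thickness (2.8 mm) to estimate the outer skull
table; population-average suture-plane angles (coronal α = 83°, lambdoid
β = 68°, measured at the feet B and L of the planes on the
antero-posterior segment AP, with AB/AP = 0.30 and LP/AP = 0.25) split the
shell into frontal bone, coronal suture (2 mm band), parietal bone,
lambdoid suture and occipital bone; osteotomies and spring notches are
carved; the shell (homogeneous thickness 2.5 mm, the population-average
skull thickness) is clamped at the base rim and expanded by linear
push-only springs, `F = k (60 − opening)`, in a quasi-static, geometrically
nonlinear viscoelastic shell finite-element model (St. Venant–Kirchhoff
membrane + discrete hinge bending, Prony relaxation series per material,
Newton with sparse Cholesky). Outputs are the spring openings (reported as
% of the 60 mm nominal) and the cranial shape metrics

    CI = BPD / OFD

(biparietal over occipitofrontal diameter) at PREOP, POSTOP (t = 1 s) and
FU (t = 5 days, 432 000 s).

Since no patient data can ship with the package, a deterministic
synthetic-phantom module generates scaphocephalic superellipsoid heads with
analytic landmarks and two-layer skin/skull phantoms with exactly known
thicknesses — every operator is testable against construction.

## Worked example

```r
library(SpringCranio)

ph  <- generateHead(phantomSpec(meshResolution = 6)) # OFD 125, BPD 96 mm
mod <- buildSModel(ph$mesh, ph$landmarks)            # population averages
mod <- attachSprings(mod, c("S12", "S12"))
sys <- femAssemble(mod)                               # clamped base rim
sol <- solveQuasistatic(sys, mod@springs, femSchedule(nLog = 20))
rep <- extractOutputs(sol, mod@frame)
rep$openings
rep$metrics
```

prints (openings in mm and % of the 60 mm nominal; CI = BPD/OFD):

```
     spring model POSTOP_mm POSTOP_pct    FU_mm   FU_pct
1  anterior   S12  51.31545   85.52575 51.60548 86.00914
2 posterior   S12  51.30254   85.50423 51.57888 85.96480

  timepoint      bpd      ofd        ci
1     PREOP 90.35965 119.2218 0.7579124
2    POSTOP 90.37438 119.2141 0.7580848
3        FU 90.39433 119.2068 0.7582984
```

The springs, inserted at their geometric opening of ~51 mm, push toward
their 60 mm nominal; the biparietal diameter grows, the occipitofrontal
diameter shrinks slightly, and the cephalic index rises monotonically from
PREOP through POSTOP to FU — the directional signature of SAC. (BPD/OFD
here are measured on the *skull* shell, i.e. after the 2.8 mm inward skin
offset, hence smaller than the phantom's outer-head 96/125 mm.) Material
and spring constants are configuration defaults, not calibrated device
data; see `defaultMaterials()`, `defaultSpringTable()` and the vignette.

A file-based pipeline with the same stages is available as
`runPipeline()`, or from the shell:

```sh
Rscript inst/cli/cranio.R pipeline --out results/demo --seed 1
```

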