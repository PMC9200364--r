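# spindlesim

A desk-scale simulator of the **search-and-capture** phase of mitotic
spindle assembly, for cell biophysicists and modelers who want to probe how
kinetochore–microtubule attachment errors (amphitelic vs merotelic,
monotelic, syntelic outcomes) arise from the interplay of microtubule
dynamic instability, Ndc80-mediated attachment mechanics, and
Aurora-kinase/phosphatase phospho-regulation — without a GPU cluster.

## The model

Two coupled engines:

* **Reaction–diffusion master equation (RDME).** The cell volume is
  discretized into cubic subcells of side *l*<sub>SV</sub> = 250 nm holding
  integer molecule counts *x*<sub>j,ν</sub>. Reactions fire within a
  subcell with propensities *a*<sub>uni</sub> = *c x*<sub>A</sub> and
  *a*<sub>bi</sub> = *c x*<sub>A</sub>*x*<sub>B</sub> (per-pair propensity
  *c* = *k*/(*N*<sub>A</sub>*l*<sub>SV</sub>³)); molecules hop to face
  neighbors with propensity *d*<sub>j</sub> = *D*<sub>j</sub>/*l*<sub>SV</sub>².
  Sampling is exact: the next-subvolume method for reactions, synchronous
  multi-particle diffusion for transport.
* **Overdamped Langevin bead–spring mechanics.** Centrosomes, three-bead
  elastic microtubules, a sister-kinetochore pair with an Ndc80-bearing
  corona grid, and optional chromosome arms evolve by the Ermak–McCammon
  step *r*<sub>i</sub> ← *r*<sub>i</sub> + (*F*<sub>i</sub>/γ<sub>i</sub>)δ*t* + *g*<sub>i</sub>,
  Var(*g*) = 2*k*<sub>B</sub>*T*δ*t*/γ<sub>i</sub>, with forces from
  harmonic stretch/bend terms, Ndc80 attachment springs, a repulsive
  ε(σ/*r*)¹² excluded-volume term, and a soft harmonic membrane.

Biological time advances only by kinetic waiting times; mechanics-changing
events (growth/shortening by Δ*l* = 24 nm, catastrophe/rescue,
attachment/detachment) trigger a *T* = 0 relaxation to mechanical
equilibrium. A growing plus-end within 65 nm of a free corona site attaches
at the tabulated propensity (3.8×10² s⁻¹ per pair), suffers an immediate
catastrophe, and pulls the kinetochore; detachment occurs at
(1.5 + 0.2 *p*)×10⁻³ s⁻¹ where *p* ∈ [0, 7] is the linker's
phosphorylation state set by Aurora B (cloud around the centromere),
Aurora A (poles, optional) and explicit phosphatase molecules.

See the methods vignette
(`vignettes/spindle-search-and-capture.Rmd`) for the full account of
parameters, numerical choices and desk-scale protocols.

## A worked example

```r
library(spindlesim)

# 20 microtubules per pole in a 5-um cell, 60 s of biological time
cfg <- mini_spindle_config(bio_time = 60, seed = 4)
tr  <- run_simulation(cfg)
m   <- spindle_metrics(tr$cell)
```

prints, via the summary lines in the example script:

```
t = 60 s  angle = 76.8 deg  KT-KT = 724 nm  |x| = 79 nm
attachments L1=0 L2=0 R1=0 R2=0 -> unattached
```

The spindle angle (kinetochore axis vs pole–pole axis, folded to 0–90°)
started at 90° and has begun to turn under microtubule pushing; the
centromere spring holds the sister kinetochores at ~725 nm; the pair is
still within 0.1 µm of the equatorial plane; no capture has occurred yet in
this minute (captures are rare at desk scale — see the vignette). L1/L2 and
R1/R2 count microtubules from the left/right pole bound to each sister;
`classify_attachment()` maps them to
amphitelic/merotelic/monotelic/syntelic/unattached.

The stationary Ndc80 phosphorylation benchmark (kinetics + diffusion only,
100 s, 8 replicates) responds to the phosphatase:Aurora-B balance:

```r
set.seed(1)
nphos_benchmark(P_count = 10,  AB_count = 100)   # N_phos 5.72 +- 0.57
nphos_benchmark(P_count = 100, AB_count = 100)   # N_phos 2.91 +- 0.56
```

and the closed-form kinetochore-pair (cylinder) diffusion coefficients are

```r
cylinder_diffusion_exact(1450, 725)
#>       D_x   D_theta
#> 0.1517992 0.8663928    # um^2/s, rad^2/s
```

A thin command-line front end is installed at
`system.file("cli", "spindlesim", package = "spindlesim")`
(`spindlesim run --config FILE --seed N --out DIR`, and
`spindlesim benchmark NAME`); configurations are YAML with
`morphology`/`kinetics`/`mechanics` sections (see `read_config()`).

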