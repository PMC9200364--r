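---
title: "Methods: a stochastic reaction-diffusion-dynamics model of kinetochore capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a stochastic reaction-diffusion-dynamics model of kinetochore capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`spindlesim` simulates the search-and-capture phase of mitotic spindle
assembly: dynamically unstable microtubules (MTs), anchored at two fixed
centrosomes, probe the cell volume until their plus-ends are captured by
Ndc80 linkers on the kinetochores (KTs) of a chromosome. The model couples
two descriptions:

* **Chemistry and transport** are a reaction-diffusion master equation
  (RDME) on a cubic lattice of subcells of side $l_{SV}$ = 250 nm. The state
  is the integer copy number $x_{j,\nu}$ of every species $j$ in every
  subcell $\nu$; reactions fire only between molecules of the same subcell
  with propensities $a_{\mathrm{uni}} = c\,x_A$ and
  $a_{\mathrm{bi}} = c\,x_A x_B$, where the per-pair propensity $c$ of a
  bimolecular channel is the molar rate constant divided by $N_A l_{SV}^3$;
  molecules hop to the 6 face neighbors with per-molecule propensity
  $d_j = D_j / l_{SV}^2$. Reactions are sampled exactly, event by event, by
  the next-subvolume method (NSM: an indexed queue of per-subcell next-event
  times, the earliest subcell fires one channel chosen proportionally to its
  propensity and is rescheduled from its refreshed total propensity).
  Transport uses the synchronous multi-particle diffusion (MPD) scheme:
  every molecule hops with probability $p = D\tau/l_{SV}^2$ per direction
  per epoch $\tau$.

* **Mechanics** is an overdamped (Ermak-McCammon) Langevin bead-spring
  system,
  $r_i(t+\delta t) = r_i(t) + \frac{F_i}{\gamma_i}\delta t + g_i$,
  $\mathrm{Var}(g_i) = 2 k_B T \,\delta t / \gamma_i$ per coordinate, with
  $F_i = -\partial U/\partial r_i$. The total energy is a sum of harmonic
  stretching and bending terms for MTs (3 beads each) and chromosome arms,
  the centromere spring and the corona grid of the kinetochore pair, Ndc80
  attachment springs of rest length $l_{Ndc}$ = 65 nm, a purely repulsive
  $\varepsilon(\sigma/r)^{12}$ excluded-volume term with
  $\sigma = R_i + R_j$, and a soft harmonic membrane repulsion applied
  outside the ellipsoidal cell boundary
  $\zeta_i = (x_i/a)^2 + (y_i/b)^2 + (z_i/c)^2 = 1$.

The two layers are coupled by the scheduler: biological time is advanced
only by the kinetic waiting times. Events that change the mechanical state
(MT growth or shortening by $\Delta l$ = 24 nm, catastrophe and rescue,
attachment formation and release) hand control to a $T=0$ Langevin
relaxation toward mechanical equilibrium before chemistry resumes;
phosphorylation events only refresh propensities.

Capture follows four rules: a growing plus-end within 65 nm of a free
corona bead is a formation candidate at the per-pair attachment propensity;
formation creates the Ndc80 spring and triggers an *immediate catastrophe*;
the shortening attached MT pulls the kinetochore through the spring; and
detachment is stochastic with rate $(1.5 + 0.2p)\times 10^{-3}\ \mathrm{s^{-1}}$,
where $p \in [0,7]$ is the number of phosphorylated sites of that linker,
set by Aurora kinase (up) and phosphatase (down) kinetics.

# Parameters

All defaults live in `default_params()` (internal units nm, pN, pN ps/nm;
kinetic rates in 1/s): component radii (centrosome 400 nm, MT beads 12 nm,
kinetochore/arm beads 362.5 nm, corona beads 4 nm), the corona patch area
0.15 um^2 and curvature parameter $\chi \in [0,1]$, the stiffnesses
(MT stretch 16.7 pN/nm, MT bend 7.7e5 kJ/mol rad^2, centromere/corona
3.3e3 pN/nm, Ndc80 310 pN/nm, membrane 3.3e3 pN/nm, excluded-volume scale
2.1e5 kJ/mol), the dynamic-instability rates (growth 5.0/s, shortening
18.6/s, catastrophe 2.5e-3/s, rescue 3.0e-2/s, step 24 nm), the
phospho-kinetics (1.5e7 and 3.0e7 /s/M, attachment 3.8e9 /s/M, detachment
(1.5+0.2p)e-3 /s), and transport (Aurora D = 7.3e7 nm^2/s, T = 300 K).
`validate_params()` rejects non-physical values and converts the molar
energies to pN nm (1 kJ/mol = 1.66 pN nm).

Bimolecular conversions default to the *rounded* convention
(multiply the molar rate by 1e-7 for a 250-nm subcell), which reproduces
the conventional printed propensity values exactly; the exact conversion
$k/(N_A l_{SV}^3)$ differs by about 6% and is available as
`mode = "exact"`.

Two deliberately redundant viscous parameters coexist: the quoted friction
coefficients (6.8e6 pN ps/nm for kinetochore-sized beads, 4.5e5 for MT
beads) and the Aurora diffusion constant are mutually consistent with
Stokes-Einstein only to a few percent, so each is used where it is quoted;
the viscosity (default the value making Stokes-Einstein at 2.9 nm reproduce
D = 7.3e7 nm^2/s, about 1.04 cP) backs only the fallback friction.

Unprinted geometry was fixed once: ellipsoid semi-axes a = 8, b = c = 5.04
um (volume ~850 um^3), pole separation 12 um, initial MT lengths uniform on
[36 nm, 1 um], cohesin stiffness equal to the arm stretching stiffness, and
the anchor restraints of MT minus-ends (positional 3.3e3 pN/nm, angular
equal to the MT bending rigidity).

# Enzyme fields

Aurora B lives in a gaussian cloud centered on the kinetochore midpoint
(sigma = (R_CH + 250)/2 nm) and confined to within 250 nm of the
*centromere surface*, i.e. within R_CH + 250 nm of either kinetochore
center -- the shell where the 65-nm Ndc80 linkers actually sit. Aurora A
(off by default) is a pair of gaussians on the poles. Both kinases default
to the implicit *field* mode: a static expected-count per subcell entering
the phosphorylation propensities directly; an explicit-particle mode with
reflecting confinement is available. The cloud is re-centered whenever the
centromere has moved by more than half a subcell.

Phosphatase is different: it is always an explicit, immobile set of integer
molecules placed uniformly over the corona neighborhood. At ~10 copies per
corona its discreteness is load-bearing -- most subcells contain no
phosphatase at all, so the sites they host phosphorylate to saturation
while sites sharing a subcell with an enzyme stay low. This per-subcell
occupancy statistics, not the mean rate balance, is what makes the
stationary phosphorylation level respond so strongly to the
phosphatase-to-kinase ratio; a smoothed phosphatase field would flatten the
response entirely.

# Numerical choices

* **Stability.** The explicit overdamped update is stable for
  $\delta t < 2\gamma_i / k_i$ where $k_i$ is the *total* stiffness a bead
  feels (a corona bead carries dozens of 3.3e3 pN/nm grid bonds). Dynamical
  (thermal) runs use a uniform timestep checked against the global bound
  and refuse to run above it. $T=0$ relaxation instead uses per-bead steps
  at a fixed fraction (0.25) of each bead's own bound -- diagonally
  preconditioned gradient descent, which reaches the same equilibria while
  letting soft, high-friction beads take full steps -- plus a 5-nm
  per-step trust region that tames the steep $r^{-12}$ contacts the
  harmonic bound does not cover.
* **Relaxation budget.** After each mechanics-changing event only the
  affected neighborhood is relaxed: the event's filament alone when it is
  free (and only if it pokes the membrane; a repositioned free filament is
  already at rest), or the kinetochore assembly plus every filament
  attached to or pressing on it (inside 1.7 sigma, the ~10 pN contact
  range). Step caps keep each relaxation cheap; a whole-cell relaxation
  every 10 s of biological time mops up sub-tolerance residuals.
  Unconverged relaxations are counted in the run statistics, never fatal.
* **MPD epoch.** The physical diffusion timescale $l_{SV}^2/2D$ violates
  the synchronous-hopping constraint $6p \le 1$; epochs default to the
  stability rule $6p = 0.5$, i.e. $\tau \approx 7.1\times10^{-5}$ s for
  Aurora. All diffusion results are epoch-size-insensitive (the law
  $\sigma^2 = 2Dt$ holds for any admissible $p$).
* **Corona geometry.** The patch is a cylindrical surface fragment of
  curvature $(1-\chi)/R_{CH}$ tangent to the kinetochore sphere, with arc
  extent chosen so the area is exactly $A_{KT}$ for every $\chi$; the
  flexible-kinetochore variant softens the corona-to-center springs
  40-fold and shrinks the grid cutoff to 50 nm.
* **Stalling rule.** A free MT that would shorten below 3 bead diameters
  re-nucleates (growing, anchor direction kept). An *attached* MT at that
  floor instead stalls -- zero shortening propensity -- and waits for
  stochastic detachment. Without the stall every capture would end within
  seconds by re-nucleation and the phospho-dependent detachment rates
  (lifetimes of 5.7-11.1 min) could never act; with it, a captured
  chromosome is held at the pole for a detachment-controlled time, which
  is the behavior the attachment-error statistics rest on.
* **Scheduler sampling.** The microtubule, attachment and detachment
  channels are sampled by a direct Gillespie draw over channel groups
  (their propensities change after nearly every event, so a per-subcell
  queue would be rebuilt constantly); lattice chemistry keeps the NSM
  queue. Both are exact samplers of the same master equation.
* **Excluded volume.** Pair rules connect MT beads with
  kinetochore/arm beads and bulky beads with each other; bonded pairs are
  excluded; the cutoff is 3 sigma (truncation error < 2e-6 of
  $\varepsilon$). Pairs are enumerated directly -- at desk scale
  (hundreds of beads in the interacting classes) a cell list would be
  overhead.
* **Membrane distance.** The penetration depth is the exact Euclidean
  distance to the ellipsoid, from a projected-Newton solve of the Lagrange
  condition (monotone from t = 0; tolerance far below 1e-3 nm), and the
  restoring force is exactly $-K_{mem}(p - q)$ for surface point $q$, so
  analytic forces match numerical gradients to machine-level tolerance.

# Desk-scale protocols

The full-scale system of the study (750 MTs per pole, 750 Ndc80 sites per
corona, ~30 min of biological time) is far beyond a single CPU. The
package's validation therefore runs the same model at documented smaller
sizes, chosen once:

* *Phosphorylation stationarity*: full-size corona (2 x 750 sites), 100 s
  of biological time with the first 20 s discarded, 8 replicates. The
  phospho-dephospho relaxation times are ~1 s, so 100 s is deep in the
  stationary regime.
* *Mini spindle* (`mini_spindle_config()`): 20 MTs per pole, 32 corona
  beads per kinetochore (site spacing ~70 nm, commensurate with the 65-nm
  capture radius, so capture coverage stays contiguous), a 5-um cell with
  3-um pole separation, 750-nm initial offset, 120 s of biological time,
  16 seeds per condition for the detachment-rate trend comparison.
* *Benchmarks*: the three-bead drift test, the Brownian-oscillator
  ensemble, the rigid-dimer diffusion run (which is assigned the cylinder
  mobilities directly -- per-bead Stokes frictions cannot reproduce them --
  and therefore validates the integrator-estimator pair), the lattice
  spread test against $2Dt$, and the two kinetic schemes against their
  closed forms.

What the mini spindle does and does not show: captures at this scale are
rare (anchor directions are fixed and only a fraction of a ray's solid
angle intersects the capture region), so attachment-type fractions per
condition are small-sample estimates; the trend comparison is one-sided at
the sampling level. The generator also omits molecular motors, lateral
attachments, interpolar bundles and pole movement -- conclusions about
real spindles should rest on the full-scale model, not the desk protocol.

# Known limitations

* Quasi-static mechanics: relaxation budgets (step caps) make effective
  kinetochore mobility somewhat slower than fully converged relaxation;
  both arms of any comparison share the budget.
* No force dependence of detachment, no rescue of attached filaments, no
  growth while attached (immediate-catastrophe rule).
* The thermal-noise pathway for bulky components during biological time is
  exercised by the diffusion benchmarks through time-matched Brownian
  integration of free bodies, not interleaved with the event loop.
* Validation covers a single chromosome; the data model carries more, but
  no multi-chromosome behavior is tested.
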