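---
title: "Modeling localization-enhanced Arp2/3 actin nucleation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling localization-enhanced Arp2/3 actin nucleation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curvactin)
```

# The scientific question

Membrane-curvature-sensing scaffolds such as FBP17 concentrate the
nucleation-promoting factor N-WASP at curved membrane sites, and N-WASP in
turn activates the Arp2/3 complex, which nucleates new ("offspring") actin
filaments as 70-degree branches on existing ("mother") filaments.
`curvactin` asks the purely computational part of that question: **is
spatial localization of N-WASP, by itself, sufficient to enhance
Arp2/3-mediated nucleation**, holding total amounts of every component
fixed? Experiments cannot dial the degree of N-WASP clustering on a
membrane; a model can.

The package also implements the image-quantification machinery used for the
experimental read-outs (nanobar-array end/center densities, curvature
response and binding-curve fits, single-particle intensities), driven
entirely by synthetic data generators with known ground truth, so every
stage is testable without any microscope data.

# Entropy-controlled localization fields

Spatial clustering of N-WASP over the 16 x 16 lattice of 500 x 500 x 500
nm^3 compartments (an 8 um x 8 um x 0.5 um slab) is quantified by the
discrete Shannon entropy

$$S(p) = -\sum_i p_i \ln p_i, \qquad 0 \le S \le S_{\max} = \ln(256),$$

of the compartment probability field $p$. A *localization factor*
$f \in (0, 1]$ prescribes the target entropy $f\,S_{\max}$: $f = 1$ is the
uniform field, lower $f$ means stronger clustering. Fields are produced by
minimizing the squared mismatch $G = (S - f S_{\max})^2$ over the
probability simplex.

Design choices that were genuinely open:

* **Entropy base.** Natural log throughout. The constraint
  $S = f S_{\max}$ is invariant under a change of base, so nothing depends
  on this; it is recorded in the object.
* **Parameterization.** A softmax map $p_i \propto e^{z_i}$ turns the
  constrained problem into an unconstrained one with exact positivity and
  normalization, and $G$ has a closed-form gradient
  ($\partial S / \partial z_k = -p_k(\ln p_k + S)$); BFGS converges to
  $|S - fS_{\max}|/S_{\max} \le 10^{-3}$ in milliseconds.
* **Initialization.** The entropy constraint fixes one scalar functional,
  leaving a huge solution manifold; which optimum is reached is decided by
  the start point. Restarts are initialized from seeded, *spatially
  smoothed* Gaussian lattice fields whose amplitude is pre-solved (1-D root
  find) to start near the target entropy. This makes the optima contiguous
  hotspot maps — the morphology of membrane-bound activator clusters —
  rather than spatially uncorrelated spikes. Unstructured starts produce
  heavy-tailed fields whose sampled-map entropy fluctuates several-fold
  more, which would misrepresent the sampling-fidelity regime the model is
  validated in. Everything is deterministic given `(grid, f, seed,
  restarts)`.
* **$f$ below 0.02 is rejected**: the target entropy approaches 0, forcing
  near-delta solutions on a flat-gradient plateau.

Fields are realized as integer copy-number maps by **multinomial** sampling
with the total fixed by the concentration (`copies_from_concentration`:
1 uM in the 32 um^3 slab is 19,271 copies) — the total is a controlled
experimental quantity, so independent per-cell Poisson sampling would be
wrong. Sampling fidelity is monitored as the relative entropy error between
map and field; at 1 uM it stays below 1% for every studied $f$ (1.0, 0.99,
0.95, 0.8, 0.5), and it decreases with total copy number.

# Stochastic reaction-diffusion chemistry

Chemistry evolves by the Gibson-Bruck **next-reaction method**: every
reaction channel keeps a tentative firing time
$\tau_\mu = t + (1/a_\mu)\ln(1/r)$ in an indexed priority queue; after an
event only dependency-graph neighbours are updated, reusing unfired waiting
times by propensity rescaling. Propensities are $a_\mu = c_\mu\gamma_\mu$
with the mesoscopic rate $c_\mu = k_\mu / (N_A V_r)^{n-1}$ for a reaction
of order $n$ in compartment volume $V_r$ (this is the dimensionally
consistent form), and combinatorial degeneracy $\gamma$ ($N_A N_B$ for
hetero-, $N(N-1)/2$ for homo-bimolecular pairs).

The dendritic scheme, per compartment (all rates configuration values):

| step | scheme | default |
|---|---|---|
| activation | NWASP + Arp$_{inactive}$ → NWASP + Arp$_{active}$ | 1 uM⁻¹s⁻¹ |
| branching | Arp$_{active}$ + site (+ G-actin) → offspring at 70° | 5 uM⁻¹s⁻¹ |
| de novo nucleation | Arp$_{active}$ + G-actin → new filament (Arp-capped) | 0.01 uM⁻¹s⁻¹ |
| spontaneous seeding | G-actin + G-actin → seed (config-gated, off) | 10⁻³ uM⁻¹s⁻¹ |
| polymerization | plus end + G-actin → +2.7 nm | 11.6 uM⁻¹s⁻¹ |
| depolymerization | plus end → −2.7 nm + G-actin | 1.4 s⁻¹ |
| diffusion | G-actin, Arp$_{inactive}$ hop to 4-neighbours | D = 5 um²/s |

N-WASP is immobile (membrane-bound), and activated Arp2/3 is immobile in
the compartment where it was activated — this is what converts a clustered
N-WASP field into clustered nucleation potential. Binding sites for
branching occur every 27 nm of filament contour, each usable once, and live
in the compartment containing their midpoint. Diffusion is reflecting at
the boundary (closed reaction volume); hop channels are aggregated over a
compartment's outgoing directions with the destination drawn uniformly at
firing, which is exact and quarters the channel count.

Choices worth stating:

* The detailed activation/branching stoichiometry is a **reconstruction**
  — no published measurement pins down every step of this scheme:
  activation treats N-WASP catalytically, branching consumes the
  active Arp2/3, one local G-actin, and one site. Every rate is exposed in
  `dendritic_config()`; plus-end kinetics use the classic single-filament
  values (11.6 uM⁻¹s⁻¹ on, 1.4 s⁻¹ off).
* **Calibrating the adequate activation regime.** Localization-driven
  enhancement is known to require an adequate Arp2/3 activation rate: if
  activation is too slow relative to the observation window, activated
  Arp2/3 appears late and sparsely and replicate noise swamps the response.
  The activation and branching defaults were therefore calibrated by a
  small sweep (replicate seeds disjoint from any validation seeds): at
  1 uM⁻¹s⁻¹ the per-molecule activation time at mean N-WASP density is
  ~1 s ≪ 100 s, so essentially all Arp2/3 is deposited according to the
  N-WASP field early in the run, and at 5 uM⁻¹s⁻¹ branching ignites a
  cascade promptly once any filament grows through an activator hotspot.
  In this regime the localization response is well separated across
  replicates; at ten-fold slower activation the same monotone trend exists
  but with several-fold larger replicate spread.
* D = 5 um²/s for G-actin and inactive Arp2/3, in the cytoplasmic-mobility
  range for monomeric actin; with 500-nm compartments this is an 80 s⁻¹
  total hop rate per molecule.
* First filaments: activated Arp2/3 is a bona fide nucleator, so besides
  branching it can slowly seed a fresh filament in place (de novo channel,
  retaining the Arp2/3 at the new minus end — such filaments cannot fully
  depolymerize). Ten two-segment seed filaments are also placed at uniform
  random positions/orientations per replicate, and a config-gated
  Arp-independent spontaneous dimer-seeding channel exists (off by
  default). The de novo channel matters structurally: it is what the
  "number of filaments nucleated" read-out counts, and it ties nucleation
  to the activator field itself rather than to the chance geometry of
  pre-placed seeds.
* First filaments, tie-breaks, and every random draw come from one seeded
  generator per simulation; replicate index offsets the seed. Trajectories
  are bit-reproducible.

The engine's correctness is cross-checked against closed forms
(exponential decay, two-compartment equilibration, dimerization ODE) and
against an independently implemented direct Gillespie SSA
(Kolmogorov-Smirnov on inter-event waiting times), and a full propensity
recomputation after long runs audits the incremental cache to 1e-9.

# Filament mechanics

Filaments are chains of 27-nm cylindrical segments (10 monomers of
2.7 nm). The energy is

* stretching $\tfrac{k_{str}}{2}(l - l_0)^2$ per segment
  ($k_{str} = 100$ pN/nm);
* bending $k_{bend}(1 - \cos\theta)$ per hinge, with
  $k_{bend} = L_p k_B T / l_{cyl}$ from the persistence length
  ($L_p = 17$ um, $k_BT = 4.11$ pN nm at 298 K gives 2588 pN nm);
* excluded volume $K_{vol}\iint ds\,dt\, |r_i - r_j|^{-4}$ between
  non-adjacent segments, evaluated by fixed 8 x 8 Gauss-Legendre
  quadrature with a 1-nm singularity cap, and a 100-nm neighbour cutoff
  (the $r^{-4}$ kernel makes the truncation error at 100 nm about $10^{-5}$
  of contact-scale energies, and the short cutoff keeps cell-list
  neighbourhoods small enough for the 5-ms mechanics cadence at desk
  scale);
* boundary repulsion $\epsilon e^{-d/\lambda}$ from each slab face
  ($\epsilon = 100$ pN nm, $\lambda = 2.7$ nm);
* branch-bond terms tying an offspring minus end to its parent site: bond
  stretch $k(L_{bond} - L_0)^2$ (no 1/2 factor — the conventions follow
  the printed forms exactly so tests and code agree), two angular terms
  referenced to 90° (parent-bond) and 1.222 rad = 70°
  (parent-offspring), and a dihedral $k\cos(n_1, n_2)$ between the plane
  normals, which is minimal (−k) for the coplanar branch. When parent and
  bond are collinear the normals are undefined and the term is skipped
  with a flag.

All gradients are analytic and are property-tested against central finite
differences (1e-5 relative) on randomized branched configurations.
Relaxation is Polak-Ribière conjugate gradient with a backtracking Armijo
line search (energy trace non-increasing by construction), converged at a
1-pN max per-bead force.

Polymerization at boundary-loaded tips is slowed by the Brownian-ratchet
factor $e^{-F/F_0}$ with $F_0 = 1.5$ pN, where $F$ is the boundary
repulsion force on the tip bead projected on the outward tangent (clamped
at zero; "close to the boundary" means within $3\lambda$). Ratchet factors
are recomputed after each relaxation — forces are only defined then.

# The coupled simulation

`run_simulation()` alternates chemistry and mechanics: 5 ms of
next-reaction events, then conjugate-gradient relaxation, then ratchet and
site/tip reassignment, with snapshots every 1 s. Each chemical event also
has a geometric action (`apply_event_geometry`): ±2.7 nm at the plus end
(a new bead when the tip segment fills), or a fresh 2-bead offspring at
exactly 70° with uniform azimuth. Between relaxations only the filaments
touched by events are mobile (their tip neighbourhood, or the branch
junction region); the whole network is relaxed on a coarser cadence
(`full_relax_dt`, default every 10 s). Because frozen-frozen interaction
terms are constants, minimizing the reduced energy also lowers the total
energy, and the local scheme only defers — never skips — global
equilibration. Snapshots record the full-system energy (a single
evaluation) every second regardless of the relaxation cadence. The
production engine evaluates the excluded-volume quadrature at 4 x 4 nodes
with a 50-nm pair cutoff (truncation error ~10⁻⁶ of contact-scale
energies under the 1/r⁴ kernel); the user-facing
`excluded_volume_energy()` retains the 8 x 8 reference quadrature.

Two bookkeeping rules follow from scope: offspring filaments cannot
depolymerize below one monomer (their minus end is tethered by the branch
junction and debranching is not modeled), which keeps Arp2/3 exactly
conserved across inactive/active/branch-incorporated pools; and parents
cannot depolymerize past a bonded site.

**Problem sizes.** The default study runs 100 s of simulated time on the
16 x 16 grid (about 10⁸ chemical events and 20,000 relaxation cycles per
replicate); the full-scale 400 s production setting is a config preset
(`t_end = 400`). The
localization sweep uses $f \in \{1.0, 0.8, 0.5\}$ with N = 5 replicates.

# Nucleation metrics

* `filament_count_series`: per-time mean ± SEM (SD/√N) across replicates.
* `identify_branch_clusters`: a branch cluster is a **connected component
  of the branch-bond graph** — bonds are explicit in this representation,
  so graph connectivity is the faithful, parameter-free reading of
  "cluster"; unbranched singletons are excluded. Per cluster: branch count
  (= members − roots) and the convex-hull area of the bead xy-projection
  (the slab is one compartment thick).
* `branches_per_area_scaled`: per-cluster branch density times a reference
  area (default 20 x 20 um² = 400 um²) for cross-condition comparison;
  interpreting the reference-area scaling as density × area is a
  documented choice, with a 0.25 um² (one compartment footprint) floor on
  tiny hulls.
* `localization_response_summary`: per-f table plus Spearman rank
  correlation of each metric against f over replicate-level points (three
  per-f means alone cannot reach p < 0.05).

The mechanism behind the headline result is worth spelling out: total
activation propensity is nearly independent of f (it is a sum of local
products with a fixed total), but **where** Arp2/3 is activated follows
the N-WASP field, and activated Arp2/3 cannot move. Arp2/3 then leaves the
active pool by the fast branching channel where filament binding sites are
locally available, or by the slow de novo channel where they are not.
Under localization, activated Arp2/3 piles up in a few compartments; as
soon as filaments exist there (grown through, or seeded de novo), a
branching cascade ignites — each offspring adds binding sites in place —
and the local Arp2/3 pool is consumed quickly. Under a uniform field most
activated Arp2/3 sits in compartments with no sites and trickles out
through the slow de novo pathway instead. Lower f therefore converts the
Arp2/3 pool into filaments faster and into far more branches, provided
activation is fast enough that Arp2/3 is deposited where N-WASP sits,
which is why the activation rate is the critical sweep parameter.

# Nanobar image quantification

The pipeline mirrors standard nanostructure-array analysis: 71 x 71-pixel
crops centred on each bar, rotated to a canonical horizontal orientation
(nearest-neighbour, intensity-preserving); background subtraction by a
bilinear surface through four 8 x 8 corner ROIs (exact on planes;
saturated corners fall back to the median of the rest); per-width
averaging; and three ROIs per bar — two semicircular end caps of diameter
width + 2 px and a middle-third center. In SLB mode, end densities are
protein/lipid ratios after normalizing each channel to its 600-nm-bar
center intensity from the same image; in cell mode the end mean is
normalized to the average of the two center halves (two end ROIs plus two
averaged center ROIs — the convention used for intracellular actin
quantification on these arrays).
Coordinates are 0-based, pixel centers at integers, x = column — asserted
in round-trip tests.

Fits: OLS of density on 1/width (curvature response, with an
interaction-term F-test for slope differences), Hill and Gaussian
nonlinear least squares via Levenberg-Marquardt with data-driven starts
(saturated designs flag an unidentifiable half-point), and the
polymerization-rate slope as OLS restricted to the 105-350 s window.
Single-particle quantification is threshold-based Laplacian-of-Gaussian
detection at the 0.65-um (10 px) particle scale with sub-pixel quadratic
peak refinement and disk-minus-annulus integrated intensities (the disk
spans one full diameter, capturing ~94% of a matched Gaussian spot; the
annulus sits clear of the tail).

# What the synthetic data do and do not show

The generators emulate: stadium-shaped bars under a 150-nm Gaussian PSF
over a planar background, lipid-proportional protein body signal with a
programmed end enrichment E(width) rising on sub-500-nm bars, Poisson shot
noise plus Gaussian read noise; Gaussian particles at the detection scale;
and tabular Hill/Gaussian/time-series fixtures. Each generator is a pure
function of (spec, seed) and emits a ground-truth table.

One optical fact shapes the validation: with caps smaller than the PSF,
cap and body signal mix, so no ROI quantification can return the raw
programmed E at 200-300 nm widths — in the real experiment as much as
here. The truth table therefore records both the programmed E and the
*measurable* end density (the same quantification applied to the
noise-free expected images); pipeline recovery is validated against the
latter at 5%, alongside an exact null (E ≡ 1 gives density 1 at every
width, since the normalizations cancel identically) and monotone-profile
checks. Passing these shows the pipeline is unbiased against its own
optical model and robust to the stated noise — not that it deconvolves
real optics, models membrane topography on the bar sidewalls, or handles
drift, bleaching and debris, which real data contain and these generators
deliberately do not.

Similarly, the simulation sweep shows the localization effect in a
reconstructed reaction scheme at desk scale; it is a semi-quantitative
statement about mechanism, not a parameter-calibrated reproduction of any
experimental fold-change.

# Numerical choices and degenerate inputs

* Entropy of empty cells: $0\ln 0 = 0$; distributions failing
  non-negativity or unit mass (1e-6) are rejected.
* Degenerate (zero-entropy) reference fields make the relative entropy
  error undefined; the absolute error is returned with a flag.
* Excluded-volume singularity: pair distances capped at 1 nm (finite
  energy, zero gradient on the capped set).
* Angle terms guard collinear configurations (gradient skipped on the
  measure-zero set); tie-breaking of equal firing times follows channel
  index order (reproducibility over a correctness-neutral choice).
* Serialization is plain text: CSV matrices for fields and maps, CSV
  layouts and truth tables, multi-page TIFF for image pairs, JSON-friendly
  snapshot structures.

# Known limitations

* No thermal fluctuation dynamics during production runs
  (minimization-only mechanics); no severing, annealing, capping,
  debranching, or Arp2/3 recycling; no explicit membrane.
* The activation/branching stoichiometry is a documented reconstruction;
  all rates are config values, none are fitted to data.
* Reduced-scale defaults (100 s, 16 x 16) are chosen for a desk-scale
  study; absolute filament counts scale with the reconstruction's rate
  choices even though the monotone localization response is robust.
* The nanobar generator does not model sidewall membrane area, real PSFs,
  or detector artefacts; see above for what recovery tests do and do not
  demonstrate.
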