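# curvactin

Mechanochemical modeling of how spatial localization of the
nucleation-promoting factor **N-WASP** enhances **Arp2/3-mediated dendritic
actin nucleation**, together with the nanobar-array image quantification
used for curvature-sensing read-outs. The package is aimed at cytoskeleton
modelers and quantitative microscopists who want a desk-scale, fully
synthetic-data-driven version of this analysis: no microscope data are
required anywhere — generators with known ground truth stand in for them.

## What it computes

**Localization fields.** Clustering of membrane-bound N-WASP over a
16 × 16 lattice of 500-nm compartments (an 8 µm × 8 µm × 0.5 µm slab) is
quantified by the Shannon entropy *S* = −Σ pᵢ ln pᵢ. A localization factor
*f* ∈ (0, 1] prescribes the target entropy as a fraction of the uniform
maximum, *S* = *f*·ln 256; fields are produced by minimizing
*G* = (*S* − *f S*max)² over the probability simplex and realized as
molecule copy-number maps by multinomial sampling at a fixed total
concentration (1 µM ⇒ 19,271 copies).

**Stochastic mechanochemistry.** An exact Gibson–Bruck next-reaction-method
engine (indexed priority queue, dependency-graph updates) evolves
N-WASP-dependent Arp2/3 activation, dendritic branching at 70°,
polymerization/depolymerization (±2.7 nm per event) and diffusion hopping,
alternating every 5 ms with conjugate-gradient relaxation of an explicit
semiflexible filament network (stretching, bending, 1/r⁴ excluded volume,
boundary repulsion, branch-bond potentials) and Brownian-ratchet scaling
k_poly = k₀·e^(−F/F₀) at boundary-loaded tips (F₀ = 1.5 pN).

**Nucleation metrics.** Filament-count time series (mean ± SEM across
replicates), branch clusters as connected components of the branch-bond
graph, branch densities scaled to a 20 × 20 µm² reference, and Spearman
rank statistics of each metric against *f*.

**Nanobar quantification.** 71 × 71 crops around each bar, corner-mesh
bilinear background correction, per-width averaging, semicircular end-cap /
center ROIs, lipid-normalized end densities, 1/width curvature-response
regression, Hill and Gaussian binding-curve fits, 105–350 s
polymerization-rate slopes, and Laplacian-of-Gaussian single-particle
intensity quantification.

## Worked example

```r
library(curvactin)

g <- grid_spec()                          # 16 x 16 x 1, 500-nm compartments
d <- optimize_density(g, f = 0.8, seed = 7)
print(d)
#> Localization field 16 x 16: f_target = 0.8, S = 4.4361 nats (S_max = 5.5452)
#>   achieved f = S/S_max = 0.800000; max mass 0.1036, min mass 2.296e-05

total <- copies_from_concentration(1, g)  # 1 uM in the 32 um^3 slab
total
#> [1] 19271

m <- sample_copy_map(d, total, seed = 7)
relative_entropy_error(m, d)              # percent
#> 0.476
```

The field hits the prescribed entropy (*S*/*S*max = 0.8) exactly to the
10⁻³ contract, 1 µM of N-WASP corresponds to 19,271 molecules in the slab,
and the sampled integer map reproduces the field's entropy to 0.48% —
inside the <1% regime in which the copy-number representation is a faithful
realization of the continuous field.

A localization sweep then runs the coupled simulation (this is the
long-running part; ~minutes per replicate):

```r
cfg <- dendritic_config(t_end = 100)      # reduced-scale study conditions
runs <- lapply(c(1, 0.8, 0.5), function(f)
  lapply(1:5, function(s) run_simulation(cfg, f = f, seed = s)))
names(runs) <- c("1", "0.8", "0.5")
localization_response_summary(runs)$table
```

which reports mean final filament counts and median branch densities per
*f*; lower *f* (stronger N-WASP clustering) yields more filaments and
denser branch clusters at fixed totals of every species.

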