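# icmfate

Agent-based modelling and quantitative analysis of epiblast versus
primitive endoderm (PrE) fate choice in the inner cell mass (ICM) of the
mouse blastocyst.

The ICM allocates bipotent progenitors (co-expressing NANOG and GATA6,
"double positive", DP) to the epiblast and PrE lineages in reproducible
proportions, robustly against changes in embryo size, addition of
lineage-restricted cells, and cell loss. `icmfate` implements a minimal
explanation: fate choice coordinated entirely by growth-factor (FGF4)
signalling between neighbours. Each cell carries one variable, its NANOG
level $x_i$, produced under self-activation and repressed by the
neighbourhood mean $\langle x \rangle_i$ (the local growth-factor readout):

$$\frac{dx_i}{dt} =
  \alpha\,\frac{(1+x_i^n)^m}{(1+x_i^n)^m+\left(\langle x\rangle_i/K\right)^{2m}}
  - x_i .$$

For two perfectly mixed clusters this reduces to a planar system whose
phase portrait has two stable mirror equilibria (one cluster high-NANOG =
epiblast, one low = PrE) and an unstable symmetric state: a split
population is an attractor. The package embeds this circuit in a 3D
soft-sphere model of a growing ICM and reproduces, in silico, the embryo's
responses to scaling, embryonic stem cell (ESC) chimeras and staged laser
ablation of lineages — together with the measurement pipeline used for
segmented-fluorescence tables and time-lapse GFP tracks (depth-decay and
empirical-Bayes slope correction, antibody harmonisation, per-litter
rescaling, UPGMA identity clustering, persistence-rule track classifier,
Kaplan–Meier half-life estimation) and synthetic-data generators with known
truth to validate it end to end.

## Worked example

```r
library(icmfate)

p <- circuit_params()
p
#> <circuit_params> alpha = 4.5, K = 0.9, n = 2, m = 2

find_equilibria(p)[, c("xa", "xb", "stability")]
#> # A tibble: 3 × 3
#>      xa    xb stability
#>   <dbl> <dbl> <chr>
#> 1 0.147 4.10  stable
#> 2 2.20  2.20  saddle
#> 3 4.10  0.147 stable

traj <- run_wildtype(embryo_config(), seed = 1)
glance(traj)
#> # A tibble: 1 × 10
#>   t_final n_live n_epi n_pre  n_dp n_esc frac_epi frac_pre frac_dp ln_ratio
#>     <dbl>  <int> <int> <int> <int> <int>    <dbl>    <dbl>   <dbl>    <dbl>
#> 1    40.0     27    14    13     0     0    0.519    0.481       0  -0.0741
```

The equilibria are the two-cluster fate-split states (NANOG ≈ 0.147 in the
PrE cluster, ≈ 4.10 in the epiblast cluster) and the unstable undecided
state at 2.20. The wild-type run grows from 2 cells to a 27-cell ICM in
about 40 model hours and ends with 14 epiblast and 13 PrE cells and no
remaining progenitors — a balanced split, as the attractor predicts.
`autoplot(traj)` draws the lineage dynamics; `plot_phase_plane(p)` the
portrait. Perturbation experiments follow the same shape:
`run_scaling(0.5, ...)`, `run_chimera(13, ...)`,
`run_ablation_series("PrE", 1.0, at_icm_size = 26, ...)`.

On the measurement side:

```r
tracks <- synth_timelapse(synth_track_config(), n_cells = 200,
                          targeted_ids = 1:200, seed = 11)
glance(survival_curve(tracks))
#> # A tibble: 1 × 6
#>   group        n n_deaths half_life half_life_lcl half_life_ucl
#>   <chr>    <dbl>    <dbl>     <dbl>         <dbl>         <dbl>
#> 1 targeted   200      199         3          2.75          3.5
```

i.e. the Kaplan–Meier half-life of 200 synthetic targeted-cell tracks
(generated at half-life 3.4 h, censored at 18 h) is estimated at 3.0 h with
a 95% CI of 2.75–3.5 h, which covers the generating value.

A thin command-line wrapper (`inst/scripts/icmfate`) exposes the same
operations as subcommands (`simulate`, `scale`, `chimera`, `ablate`,
`sweep`, `classify`, `synth`), each writing tidy CSV outputs and a JSON run
manifest.

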