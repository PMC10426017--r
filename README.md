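# demodiff

Do nations that share linguistic or religious ancestry — or a stretch of
geography — hold similar levels of democracy, and does democracy spread
between cultural relatives over time? `demodiff` implements the full
analytical machinery for both questions as a reusable, tested R pipeline,
exercised end to end on synthetic data with a known diffusion process. It is
aimed at researchers in cultural evolution and comparative politics who need
the method validated before pointing it at real panels.

## The models

**Cultural connections.** Trait trees (language families, religious
lineages) get ultrametric branch lengths by Grafen's method — node height
`((L - 1)/(L_root - 1))^rho`, root at 1, leaves at 0 — and leaf-pair
cophenetic distances are reversed to proximities `s_ij = 1 - d/d_max`. The
connection between nations *r* and *k* weights trait proximity by population
shares:

    c_rk = sum_i sum_j p_ik * p_jr * s_ij

Geographic proximity is the reversed log10 WGS84 geodesic distance between
capitals. An alternative edge-count (patristic) proximity,
`s_ij = (d_r - d_m)/d_r`, supports model comparison by AICc.

**Cross-sectional dyadic model.** Per year, for every unordered pair of
nations (all variables scaled by their SD):

    dem.diff ~ ling.con + rel.con + geo.prox + (1|id_i) + (1|id_j)

fitted by REML with crossed random intercepts for the two node identities
(each nation recurs across dyads). Negative coefficients mean closer nations
are more politically similar. Semi-partial R² (Nakagawa-style variance
decomposition) gives each predictor's unique variance share.

**Longitudinal contagion model.** Per base year T1 and lag (5/10/20 years):

    dem_T2 ~ dem_T1 + dem.ling.relatives_T1 + dem.rel.relatives_T1 + dem.geo.neighbours_T1

where each neighbour term is the connection-weighted sum of the other
nations' T1 scores. Positive coefficients indicate diffusion.

**Synthetic world.** `simulate_study()` generates every input from one seed
— trees, national trait shares, capitals and borders, and a democracy panel
evolving by `dem[t+1] = a dem[t] + b_ling W_l dem[t] + b_rel W_r dem[t] +
b_geo W_g dem[t] + noise` on row-normalised layers (defaults a = 0.55,
b = 0.30/0/0.15, 80 nations, 40 years).

## Worked example

The `analysis/` scripts run the whole study on a seeded synthetic world:

```sh
Rscript analysis/01_simulate.R        # world + panel -> results/inputs/
Rscript analysis/02_networks.R        # connection + contiguity layers -> results/layers/
Rscript analysis/03_cross_sectional.R # one dyadic LMM per year
Rscript analysis/04_longitudinal.R    # contagion fits at lags 5/10/20
Rscript analysis/05_model_selection.R # Grafen vs patristic proximities by AICc
```

Step 3 prints, for the seed-1 world:

```
fitted 40 yearly models over 1970-2009 (40 converged)
  ling.con  median beta -0.055 | significant-negative in 28/40 years | median R2 0.0021
  rel.con   median beta +0.010 | significant-negative in 0/40 years | median R2 0.0001
  geo.prox  median beta +0.001 | significant-negative in 8/40 years | median R2 0.0003
```

Only the linguistic channel — the one with generative diffusion 0.30 — shows
a consistent negative coefficient: linguistically connected nations hold
more similar democracy scores. Step 4's lag-10 profile recovers the
contagion directly:

```
lag 10: 30 base years
  dem.ling.relatives_T1  mean beta +0.300 | positive in 25/30 slices | significant in 10
  dem.rel.relatives_T1   mean beta -0.046 | positive in 11/30 slices | significant in 0
  dem.geo.neighbours_T1  mean beta -0.071 | positive in 13/30 slices | significant in 0
```

Nations whose linguistic relatives were more democratic ten years earlier
became more democratic themselves; the religious channel, generated with
zero diffusion, stays flat. (The weaker geographic channel is recovered in
sign in roughly three quarters of replicate worlds — see the vignette for
why it is structurally confounded with language at this lag.)

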