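# fragdd

Shape of density dependence and population limitation in fragmented
landscapes.

## The problem

Forest fragmentation lowers nest survival in many territorial songbirds
(wood thrush, *Hylocichla mustelina*, is the canonical case), yet broad-scale
monitoring sometimes shows the **steepest declines in the best, least
fragmented landscapes** — an *inverse buffer effect*. `fragdd` implements the
modelling chain that explains this pattern:

1. **Landscapes** are described by binned forest patch-size distributions
   (counts and total area per size class, for all forest and for *core*
   forest — forest more than 30 m from an edge). Landscape quality is
   `Q = core area / total forest area`, with classes good (`Q > 0.7`),
   moderate (`0.6 ≤ Q ≤ 0.7`) and poor (`Q < 0.6`).
2. **Vital rates** depend on patch size `s`: nest survival saturates,
   `f(s) = f_max s / (s_half + s)` (defaults `f_max = 0.85`,
   `s_half = 42` ha), and saturation density follows a sigmoid that falls
   from ~1 pair ha⁻¹ in small patches to `l = 0.13` in large ones
   (`alpha = 0.18` ha⁻¹, midpoint `t = 13.4` ha).
3. **Site dependence**: breeders fill patches largest-first, each to its
   saturation density. With every class of mean size `a` and larger
   saturated,

       F(a) = Σ_{s≥a} f(s) d(s) A(s) / Σ_{s≥a} d(s) A(s)
       D(a) = Σ_{s≥a} d(s) A(s) / Σ_s A(s)

   trace the landscape's fecundity–density curve.
4. **Shape analysis**: the generalized Beverton–Holt
   `F = F_max / (1 + (D/K)^γ)` is fitted to each curve. `γ` (*abruptness*)
   controls the shape; for `γ > 1` the curve has an inflection at
   `K((γ−1)/(γ+1))^{1/γ}` and a *tipping point* below it where `|F″|` peaks —
   the onset of strong density dependence. The realized strength of density
   dependence is `b′ = |dF/dD|` at the landscape's breeding density.
5. **Two-season diagnosis** (Sutherland): a shift of magnitude `|ΔF|` in the
   breeding curve or `|ΔM|` in the non-breeding curve changes population
   size by `|Δn| = |ΔF|·b′/(b′+d′) + |ΔM|·d′/(b′+d′)`. The sign of the
   `(b′, |Δn|)` relation across landscapes — together with least-squares
   fits of `|Δn| = c·d′/(b′+d′)` (non-breeding-limited) versus
   `c·b′/(b′+d′)` (breeding-limited) — diagnoses which season limits the
   population. Trend magnitudes are also tested against `Q`
   (buffer / inverse-buffer classification, Pearson).

A synthetic-data module generates log-normal patch mosaics along a
fragmentation gradient (square-patch 30 m core geometry), noisy vital-rate
observations, and abundance-index series under two-season scenarios, so the
whole pipeline runs end to end without field data.

## Worked example

```r
library(fragdd)
rep <- run_full_analysis(demo_config(seed = 1))
rep$summaries[, c("landscape_id","Q","quality_class","b_prime","gamma","tipping_density")]
```

```
   landscape_id     Q quality_class b_prime gamma tipping_density
1           L01 0.524          poor  10.479 0.510              NA
...
10          L10 0.894          good   1.373 2.118        2.64e-02
11          L11 0.913          good   0.746 2.800        8.49e-02
```

Abruptness `γ` rises along the quality gradient (near-linear curves in poor
landscapes, abruptly convex in good ones) while `b′` falls: good landscapes
sit on the flat part of their curves and are weakly regulated. The
cross-landscape tests then recover both signatures:

```r
rep$buffer
#> Buffer-effect test (n = 11): inverse_buffer
#>   trend  vs Q: r = -0.863 (df = 9, p = 0.000626)
#>   |trend| vs Q: r = +0.863 (df = 9, p = 0.000626)
rep$limitation
#> Limitation diagnosis: nonbreeding-limited (Spearman rho = -0.900)
#> Sutherland fit (nonbreeding-limited variant): c = 0.124, d' = 0.7803 (RSS = 0.000148)
#> Sutherland fit (breeding-limited variant): c = 0.02737, d' = 1e-08 (RSS = 0.00276)
```

Declines are largest where `b′` is smallest (the non-breeding signature),
and trend magnitude *increases* with quality — the inverse buffer effect.
With `out_dir` set, every intermediate table is written as comma-separated
text; `system.file("cli", "fragdd.R", package = "fragdd")` is a thin
command-line wrapper with `simulate`, `quality`, `curves`, `diagnose` and
`run` subcommands.

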