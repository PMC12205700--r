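# phytoind

Quantitative vegetation assessment from relevé data, for plant-community
ecologists working with phytoindication: the package takes plot × species
projective-cover tables plus a species indicator-value table (Didukh and
Ellenberg ordinal scales, hemeroby grades) and produces

* **community indicator scores** per plot, converted to physical
  environmental quantities by the published formulas — productive soil
  moisture `W = 18.65·e^(0.15·Hd)` (mm), moisture irregularity
  `ω = 0.042·fH − 0.032`, `pH = 2.26·ln(Rc) + 1.88`, salt content
  `S = 2^(0.6·Sl+1)` (µg/l), carbonates `14·Ca⁴·⁵/(Ca⁴·⁵+45000)` (%),
  nitrogen `5·Nt³·⁷/(Nt³·⁷+345)` (g/kg), radiation balance `0.21·Tm`,
  ombroclimate `0.54·Om − 7` (mm/day), Ivanov continentality `10·Kn + 41`,
  coldest-month temperature `3.83·Cr − 38.17` (°C), aeration
  `(100−Ae⁴)/(100·(Ae⁴+1700))` and relative light `0.22·L` (log₁₀);
* **hemeroby and naturalness indices** of anthropogenic transformation
  (community-weighted mean grade on the 7-step hemeroby scale; cover share
  of near-natural grades);
* **TWINSPAN-style classification** — pseudospecies at cover cuts
  0/2/5/10/20%, divisive splits on the first correspondence-analysis axis
  (reciprocal averaging), diagnostic species by the group-size-corrected
  phi coefficient `φ = (N·n_p − n·N_p)/√(n·N_p·(N−n)·(N−N_p))` with Fisher
  exact significance, and synoptic tables;
* **correlation-matrix PCA** of the per-plot environment/hemeroby block
  with Kaiser retention and significance-filtered loadings;
* **water-body morphometry** from a DEM — shoreline length, surface area
  and volume at given water levels, with percent-change tables between
  seasonal or pre-/post-disturbance scenarios;
* a **niche-based synthetic generator** (associations on latent moisture /
  trophy / light gradients, dry–disturbed coupling) so the whole pipeline
  is testable without field data.

The methods, parameter defaults and numerical conventions are documented in
`vignettes/vegetation-assessment-methods.Rmd`.

## Worked example

```r
library(phytoind)

scen <- community_scenario()                      # 12 associations, 135 plots
tab  <- generate_indicator_table(scen, seed = 1)  # species indicator values
gen  <- generate_releves(scen, tab, seed = 1)     # releves + true labels
gen$releves
#> Releve set: 135 plots, 146 species, 1685 occurrences
#> Plot area: 16 m^2

reg <- plot_regimes(gen$releves, tab)             # scores + physical units
reg[1:3, c("plot_id", "Hd", "W_mm", "Rc", "pH", "Nt", "N_gkg")]
#>    plot_id   Hd  W_mm   Rc   pH   Nt N_gkg
#> 1 plot_001 6.85 52.08 7.98 6.57 4.03  1.67
#> 2 plot_002 2.62 27.64 8.91 6.82 1.93  0.16
#> 3 plot_003 2.86 28.65 8.72 6.77 1.83  0.13
```

Plot 1 averages a moisture score of 6.9, i.e. ~52 mm of productive moisture
in the one-metre soil layer (`classify_moisture(52)` → "very_low"), with a
slightly acid pH of 6.6 and 1.7 g/kg soil nitrogen. Hemeroby, classification
and ordination:

```r
hem <- plot_hemeroby(gen$releves, tab)
hem[1:3, c("hemeroby_index", "naturalness_index")]
#>   hemeroby_index naturalness_index
#> 1           5.78              0.06
#> 2           6.49              0.00
#> 3           6.89              0.00

tree <- twinspan(make_pseudospecies(gen$releves))
groups <- twinspan_groups(tree, k = 12)           # cut to 12 associations

block <- merge(reg[c("plot_id", scale_definitions("didukh")$scale_id)],
               hem[c("plot_id", "hemeroby_index", "naturalness_index")],
               by = "plot_id")
pca <- pca_environment(block)
pca
#> Correlation-matrix PCA: 135 plots, 14 variables
#> Retained (eigenvalue > 1): 2 components
#>                PC1    PC2   PC3   PC4   PC5   PC6
#> eigenvalue   9.935  2.585 0.599 0.412 0.172 0.139
#> explained % 70.962 18.462 4.280 2.941 1.230 0.996

round(pca$loadings[c("Hd", "hemeroby_index", "naturalness_index"), 1:2], 2)
#>                     PC1   PC2
#> Hd                -0.99 -0.08
#> hemeroby_index     0.99  0.01
#> naturalness_index -0.94  0.01
```

The dominant component is a moisture axis on which soil humidity (Hd) and
hemeroby load with opposite signs — drier plots carry the more
anthropogenically transformed communities, wetter plots the more natural
ones. `fidelity()` / `synoptic_table()` then flag each group's diagnostic
species, and `run_pipeline()` executes all stages and writes every
intermediate artifact (CSV/JSON plus a run manifest) into an output
directory.

For DEM work, `read_esri_ascii()` → `inundate()` → `measure_waterbody()` →
`change_table()` compute shoreline/area/volume per water level and the
percent changes between scenarios.

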