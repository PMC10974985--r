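# schooldust

Heavy metals accumulate in settled dust inside schools, where children — who
ingest and inhale proportionally more dust than adults — spend most of their
day. Given a site-by-element concentration table (mg/kg of dry dust),
`schooldust` answers the three questions an environmental-health study of
such data asks:

1. **How contaminated is each site and element?** Classical pollution
   indices against a geochemical background *B*:
   geo-accumulation index `Igeo = log2(C / 1.5 B)` with Müller's seven
   classes; contamination factor `CF = C / B`; modified degree of
   contamination `mCd = mean(CF)`; pollution load index
   `PLI = (∏ CF)^(1/n)` per site and its geometric mean over sites for the
   zone; enrichment factor `EF = (C/C_Fe)_sample / (C/C_Fe)_background`
   with iron as the crustal reference.
2. **Does the dust pose a health risk?** A US EPA-style non-carcinogenic
   exposure model for child and adult receptors over three pathways
   (ingestion, inhalation, dermal contact): average daily doses
   `ADD = C · IngR · EF_freq · ED / (BW · AT) · 10⁻⁶` (and its inhalation/
   dermal analogues), hazard quotients `HQ = ADD / RfD` against
   pathway-specific reference doses, and the hazard index `HI = Σ HQ` with
   risk flagged at `HI ≥ 1`.
3. **Where does the contamination come from?** Pearson correlation, PCA,
   Ward/Euclidean hierarchical clustering and k-means with elbow and
   silhouette diagnostics — plus an uncertainty-weighted **positive matrix
   factorization (PMF)** receptor model, `X ≈ G F` with `G, F ≥ 0`,
   fitted by multiplicative updates minimizing
   `Q = Σ ((x_ij − (GF)_ij) / u_ij)²` over 20 random starts, with
   factor-count selection by the lowest and most reliable `Q/Q_expected`.

Because raw school-dust measurements of this kind are typically not
released, the package ships a synthetic-data generator
(`generate_dataset()`) that plants a known five-factor source structure
(road dust, vehicle wear, construction, combustion, legacy Pb–As) with
three correlated element groups, lognormal noise, and per-element ranges
anchored to published school-dust spans (As 4.55–69.96 mg/kg,
Cu 51.28–395.37 mg/kg). Every pipeline stage is validated against this
ground truth.

## Worked example

```r
library(schooldust)

ds <- generate_dataset(synthetic_spec(seed = 1))   # 24 sites x 11 elements
bg <- default_background()                          # world-soil medians, mg/kg

# contamination summary
s <- site_contamination_summary(ds$conc, bg)
subset(s, site == "zone")
#>    site    index    value        class
#> 49 zone pli_zone 1.049724 deteriorated

# child health risk
hz <- hazard_index(ds$conc, exposure_parameters("child"))
#> Warning: element(s) without reference doses excluded from hazard index: Rb, Sc
head(risk_report(hz)$flagged[, c("site", "element", "hi")], 3)
#>   site element       hi
#> 1  S11      Zr 9.109589
#> 2   S4      Zr 7.966167
#> 3  S15      Zr 5.647339

# source apportionment
u <- build_uncertainty(ds$conc)                     # 10%/20% XRF error classes
sel <- select_factor_count(ds$conc, u, k_candidates = 3:5, seed = 1)
sel$k_selected
#> [1] 5
profile_recovery(sel$fits$k5, ds)$mean_cosine       # planted-profile recovery
#> [1] 0.9545923
```

The zone-level pollution load index just above 1 marks an overall
deteriorated environment; zirconium's child hazard index exceeds 1 at every
site (its ingestion reference dose is tiny, 8e-5 mg/(kg·day)) while all
adult indices stay below 1; and the Q-based factor-count selection recovers
the five planted sources with a mean matched-profile cosine of 0.95.

## Command line

A thin wrapper over the same functions lives at `inst/scripts/schooldust`:

```sh
inst/scripts/schooldust simulate --seed 7 --out dust.csv
inst/scripts/schooldust indices --in dust.csv --out-dir results
inst/scripts/schooldust risk --in dust.csv --out-dir results
inst/scripts/schooldust pmf --in dust.csv --out-dir results --seed 7
```

See `vignettes/schooldust-methods.Rmd` for the model assumptions, parameter
provenance, and design choices.
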