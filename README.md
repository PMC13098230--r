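# fmtrewire

Statistical analysis of fecal microbiota transplantation (FMT) cohorts in
inflammatory bowel disease (IBD), for microbiome researchers and
biostatisticians working with paired donor–patient multi-omic designs:
genus-level 16S tables, quantified metabolite panels, and clinical markers
collected at baseline and post-treatment, each patient linked to a fixed
stool donor.

The package implements, as composable tidyverse-style functions:

* **Clinical outcome classification** — UC week-4 response (partial Mayo
  reduction ≥ 2 with rectal-bleeding decrease ≥ 1), CD response (CDAI
  decrease ≥ 100), week-14 clinical remission (partial Mayo < 3; CDAI
  < 150) and endoscopic remission (Mayo endoscopic ≤ 1; SES-CD ≤ 2), plus
  per-cohort outcome counting. The modelled cohort's per-patient outcome
  table ships as a CSV fixture (`table1_outcomes()`).
* **Alpha diversity** — observed richness, bias-corrected Chao1
  `S_obs + F1(F1−1)/(2(F2+1))`, Chao & Lee ACE (rare cutoff 10), Shannon
  entropy (nats), Simpson dominance `D = Σ pᵢ²`, with Mann–Whitney
  two-group comparison.
* **Three-criterion response screen** — a feature is FMT-response
  associated when it is (i) differential between patient baseline and
  donors at Benjamini–Hochberg q < 0.05, (ii) shifted to donor levels in
  responders post-FMT (non-significant vs donors *and* moved toward the
  donor mean), and (iii) persistent at baseline levels in non-responders.
* **Ternary correlation networks and rewiring** — Spearman co-abundance
  networks over clinical markers, taxa (prevalence ≥ 60%) and metabolites,
  keeping edges with |ρ| > 0.6 and p < 0.05; class-pair censuses with
  metabolite–metabolite exclusion; and the edge-persistence fraction — the
  share of baseline (non-metabolite–metabolite) edges whose node pair and
  sign recur post-treatment. A persistence near zero quantifies the network
  "rewiring" that accompanies successful FMT.
* **PCA / PLS-DA** — NIPALS PLS1 with VIP scores (mean squared VIP ≡ 1,
  selection at VIP > 0.9) and stratified 7-fold cross-validated Q²Y.
* **Synthetic cohort generator** — paired donor/baseline/post samples with
  planted response features and planted (latent-factor) correlation edges
  whose baseline→post overlap is an exact, configurable persistence target,
  so every stage has a ground-truth recovery test.
* **Pipeline** — `run_pipeline()` orchestrates simulate → outcomes →
  diversity → screen → ordination → networks → persistence into one
  reproducible run with a manifest and JSON report
  (`inst/scripts/fmt_rewire.R` is a thin command-line wrapper).

## Worked example

```r
library(fmtrewire)

# the published per-patient outcome table
summarize_outcomes(table1_outcomes(), "UC")
#> # A tibble: 1 × 5
#>   cohort n_total response_w4 remission_w14 endo_remission_w14
#>   <chr>    <int>       <int>         <int>              <int>
#> 1 UC          15          12            12                  8

# a synthetic UC-like cohort with known ground truth
cohort <- simulate_cohort(synth_config(seed = 7))
cohort
#> <fmt_cohort>
#>   46 samples (16 donor, 15 patients x baseline/post), 60 taxa, 60 metabolites
#>   ground truth: 39 response features, 8/16 planted baseline/post edges

screen <- screen_cohort(cohort)
sum(screen$taxa$selected); sum(screen$metabolites$selected)
#> [1] 12
#> [1] 23

meta <- cohort$metadata
tables <- list(clinical = clinical_markers(meta), taxon = cohort$taxa,
  metabolite = cohort$metabolites)
net_b <- build_network(tables,
  samples = meta$sample_id[meta$timepoint %in% "baseline"], context = "baseline")
net_p <- build_network(tables,
  samples = meta$sample_id[meta$timepoint %in% "post"], context = "post")
net_b; net_p
#> <fmt_network> baseline: 122 nodes, 145 edges (|rho| > 0.6, p < 0.05, n = 15)
#> <fmt_network> post: 122 nodes, 224 edges (|rho| > 0.6, p < 0.05, n = 15)

edge_persistence(net_b, net_p)$fraction
#> [1] 0.01680672
```

Reading: of the 15 UC patients, 12 responded at week 4 and 12 were in
clinical remission at week 14, 8 endoscopically. In the simulated cohort
the screen recovers 12 of 14 planted response taxa and 23 of 25 planted
response metabolites. The post network carries more edges than the
baseline network (the planted expansion), and under 2% of baseline
non-metabolite–metabolite correlation pairs persist after treatment — at
n = 15 most threshold-crossing edges are sampling noise, so the pooled
structure is almost completely rewired.

`autoplot()` methods exist for screens, networks and ordinations, and
`tidy()`/`glance()` for networks and ordination fits.

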