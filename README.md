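# germtrace

Pedigree- and marker-based germplasm analysis of released crop cultivar
populations, written for breeding programs of fully inbred lines (the
motivating system is the modern Chinese soybean cultivar population with its
three cultivation ecoregions: NNC, HHH and SC).

Breeders ask two linked questions of a released-cultivar panel: *where did
its germplasm come from* (parental-pedigree analysis) and *how diverse and
differentiated is it really* (genomic-marker analysis). `germtrace`
implements both halves and the comparison between them:

* **Pedigree accounting.** A validated pedigree DAG with typed breeding
  events (cross / selection / mutation / terminal). Nuclear genetic
  contribution propagates as NGC(parent→cross child) = 1/2 per
  hybridization and 1 through pure-line selection or mutation, so every
  cultivar's founder contributions sum to 1. The cytoplasm follows the
  maternal line to a single terminal female ancestor. The coefficient of
  parentage (COP, identity by descent) uses the standard rules:
  `cop(x,x) = 1`, distinct founders 0, a selected line and its source 0.75,
  and `COP = Σ (1/2)^n` over paths through common parents. Core-terminal
  ancestors are nominated among candidates with ≥ 3 breeding cycles when
  ≥ 2 of 4 prominence indicators (NGC %, CGC %, derived-cultivar count,
  cycle count) strictly exceed the candidate mean; each core ancestor with
  its derived cultivars forms an ancestor-derived family.
* **Marker statistics.** SNP QC (missing ≤ 20 %, heterozygous ≤ 10 %,
  MAF ≥ 0.01), greedy assembly of multi-allelic SNP
  linkage-disequilibrium blocks (SNPLDBs, |D′| > 0.7) whose alleles are
  haplotypes, genetic richness and allele load, allele-frequency dispersion
  `π = n/(n−1) Σ pᵢ(1−pᵢ)`, specific present/deficient alleles (SPA/SDA),
  the coefficient of genetic similarity `s_ij = Σ C_ijk / (2m)` (identity
  by state) with distance `d = 1 − s`, the multi-allelic Weir–Cockerham
  `F_ST = Σa / Σ(a+b+c)`, seeded Mantel tests and PCA.
* **Clustering and phenotypes.** Saitou–Nei neighbor joining on `d_ij`
  with a reproducible longest-internal-edge cut into k groups and
  group-by-ecoregion tables; multi-environment RCBD ANOVA with variance
  components from expected mean squares and `GCV = 100·σ_g/μ`.
* **Simulation.** A seeded generator of multi-ecoregion breeding programs
  (diverged founder pools, crossing with migration, pure-line selection)
  and block-wise gene dropping of fully inbred genotypes, used to validate
  every stage end to end (e.g. gene-drop identity-by-descent frequencies
  reproduce COP).

## Worked example

The package ships the published worked example: the pedigree of the
cultivar Nannong 32 (intermediate lines reconstructed, see
`inst/extdata/nannong32_pedigree_synthetic.tsv`).

```r
library(germtrace)
g <- read_pedigree(system.file("extdata",
        "nannong32_pedigree_synthetic.tsv", package = "germtrace"))
nuclear_contribution(g, "Nannong 32")
#>               51-83             73-01-1   Dangshanwandousha Fengxiansuidaohuang
#>              0.1250              0.2500              0.1250              0.1250
#>       Huaiyindasili             Mamotan    Tongshantianedan
#>              0.2500              0.0625              0.0625
cytoplasmic_ancestor(g, "Nannong 32")
#> [1] "Fengxiansuidaohuang"
breeding_cycles(g, "Mamotan", "Nannong 32")
#> [1] 4
```

Seven terminal ancestors are traced; their nuclear contributions sum to 1,
the deepest founder (Mamotan) sits four breeding cycles away
(contribution (1/2)^4 = 0.0625), and the cytoplasm traces maternally to
the landrace Fengxiansuidaohuang (cytoplasmic contribution 1).

## Analysis workflow

The `analysis/` directory holds the numbered drivers of the full workflow
over a simulated program (each takes an optional seed argument and writes
its tables under `results/`):

```sh
Rscript analysis/01_simulate_program.R 1   # pedigree TSV + genotypes VCF
Rscript analysis/02_pedigree_analysis.R 1  # trace, COP, core ancestors, families
Rscript analysis/03_marker_diversity.R 1   # QC, SNPLDBs, richness/pi/SPA/SDA, F_ST
Rscript analysis/04_clustering.R 1         # CGS, NJ tree, groups x ecoregion
Rscript analysis/05_cop_vs_cgs.R 1         # Mantel test, joint COP x CGS bins
Rscript analysis/06_phenotypes.R 1         # RCBD ANOVA, variance components, GCV
```

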