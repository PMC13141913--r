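# phagemine

Toolkit for the computational stages of an infant gut phageome study:
mining phage contigs out of bulk metagenomic assemblies, quantifying them as
viral relative units, and testing how enrichment protocol, delivery mode and
age shape the observed phageome.

Shotgun metagenomes of infant stool are dominated by bacterial DNA, so the
viral fraction is both under-represented and entangled with prophages
integrated in bacterial contigs. This package implements the bespoke
computational steps such a study needs, downstream of the standard external
tools (assembler, aligner, phage classifiers, host/taxonomy predictors),
whose tabular outputs it consumes:

- **Reference unphaging** (`unphage_database`): viral regions detected on
  bacterial reference contigs by alignment (at ≥ 70% identity and ≥ 70%
  coverage of the viral query) are merged, excised, and the residual
  bacterial sequence split into fragments — so that the reference can later
  be used to remove bacterial contigs without swallowing the prophages they
  carry.
- **Mining cascade** (`mine_phages`): 2,000 bp contig length floor,
  prophage excision from study assemblies, removal of bacteria-classified
  contigs, and consensus phage calling. A contig is called phage iff its
  PhaMer-style score is ≥ 0.9 **and** the sum of its PhaMer-style and
  MetaPhaPred-style scores exceeds 1.
- **Dereplication** (`greedy_derep`): greedy longest-first clustering at
  ≥ 98% identity over ≥ 85% coverage of the shorter sequence, both strands,
  with exact local alignment.
- **Annotation post-processing** (`filter_taxonomy`, `filter_lifestyle`,
  `filter_hosts`, `propagate_bin_taxonomy`, `merge_host_sources`):
  rejection-score filters (0.7 for family and lifestyle), a family
  whitelist, host-prediction confidence cutoff (95, with shared proteins
  required), and bin-level taxonomy propagation with conflict discard.
- **Quantification** (`compute_vru`, `group_phages`): per-contig viral
  relative units

  VRU_i = (mdepth_i · coverage_i) / Σ_j (mdepth_j · coverage_j)

  where `mdepth` is the mean depth over covered bases and `coverage` the
  covered fraction of the contig; contigs sharing (family, lifestyle, host
  genus) are summed into phage groups.
- **Statistics** (`shannon_diversity`, `log_transform`, `pearson_distance`,
  `pcoa`, `permanova`, `fit_abundance_lmm`, `fit_presence_glmm`,
  `screen_groups`): Shannon alpha diversity, PCoA on the Pearson-correlation
  distance (d = 1 − r) of log-transformed VRU, PERMANOVA with sequential
  sums of squares, and mixed models with a per-infant random intercept —
  Gaussian on log abundance, log(Y_ij) = β0 + β_treatment·treatment + R_j + ε_ij,
  and binomial on presence,
  logit P(Y_ij = 1) = β0 + β_treatment·treatment + β_delivery·delivery + β_age·age + R_j.
- **Synthetic data** (`simulate_database`, `simulate_scores`,
  `simulate_cohort`, `write_fixtures`): generators with planted ground truth
  for every stage, so the whole pipeline is testable without any external
  download.

## Worked example

```r
library(phagemine)

cfg <- sim_config(seed = 42, n_bacterial_contigs = 50, prophage_rate = 0.4)
db  <- simulate_database(cfg)           # planted prophages + matching hits
res <- unphage_database(db$contigs, db$hits,
                        min_identity = 70, min_coverage = 0.70,
                        min_fragment_len = 2000)
res
#> Unphaged database:
#>   prophages removed: 23
#>   residual fragments: 59
#>   bp excised:        61762

shannon_diversity(rep(0.25, 4))         # uniform over 4 families
#> [1] 1.386294

co  <- simulate_cohort(sim_config(seed = 42))   # 8 infants x 10 samples
fit <- fit_abundance_lmm(co$response, co$meta,
                         c("treatment", "delivery", "age_months"))
fit
#> Mixed model (gaussian_log), 80 obs, random-intercept sd = 0.162
#>             term estimate std_error   p_value
#>      (Intercept)  0.09282    0.1336 4.872e-01
#>      treatmentPE  0.91753    0.1062 5.553e-18
#>  deliveryvaginal -0.11825    0.1563 4.492e-01
#>     age_months12  0.96027    0.1062 1.511e-19
```

The 23 removed prophages are exactly the planted insertions whose hits pass
the 70/70 thresholds; fragment + prophage + dropped base counts conserve
every input base. The mixed-model estimates recover the planted effects
(treatment 0.8, age 1.0) within their standard errors.

A command-line front end over the same functions is installed at
`inst/scripts/phagemine-cli.R` with subcommands `unphage`, `mine`, `derep`,
`annotate`, `quantify`, `stats` and `simulate`.

## Documentation

Every exported function carries roxygen documentation; the methods vignette
(`vignettes/phageome-methods.Rmd`) explains the models, thresholds, design
choices and limitations in detail.
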