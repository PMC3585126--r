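# lipidscreen

Analysis of cell-based RNAi screens for cellular cholesterol phenotypes.

High-content siRNA screens measure, by automated fluorescence microscopy,
how gene knockdown perturbs (i) endocytic uptake of labelled LDL and (ii)
free cellular cholesterol (filipin-stained perinuclear structures). This
package implements the full analysis chain for such screens — for
screeners who need control-anchored scoring and hit calling, and for
methodologists who want the statistics testable against synthetic data
with known ground truth:

* **Imaging** — per-cell quantification: nuclear segmentation,
  cell-region approximation (dilation or intensity-guided propagation),
  structure detection by local adaptive thresholding with size/shape
  filters, and extraction of seven phenotypic parameters (`total`,
  `concentration`, `structures` per assay, plus `area` for free
  cholesterol).
* **Screen statistics** — the *deviation value*: for siRNA $s$ and
  replicate $r$,

  $$d_{r,s} = \frac{\bar{x}_{r,s} - \bar{c}_r}{2\,E_r},$$

  the siRNA replicate mean centred on the 16 negative-control means of
  the identical replicate and scaled by twice their mean absolute
  deviation, averaged over replicates. Plate-region normalization (edge /
  neighbour / interior wells against same-region controls),
  control-anchored effector thresholds (extreme control mean ± 3 SEM),
  two-independent-siRNA hit-gene calling, Shapiro–Wilk control checks,
  screen-to-screen validation rates, parameter correlations, and an
  empirical-FDR procedure.
* **Profiling** — 2 siRNA × 7 parameter phenotypic fingerprints,
  sign-pattern functional groups (co-correlated / FC-only / inverse /
  LDL-only), and ±50 kb locus-level aggregation of effector genes.
* **Secondary assays** — enzymatic cholesterol calls, HuH7 validation,
  LDLR qPCR 2^−ΔΔCT calls, Western densitometry calls, and
  GFP-overexpression analysis, all with the conjunctive
  2-sd-plus-t-tests decision rules.
* **Synthetic data** — seeded generators for plate layouts, per-cell
  populations, rendered multi-channel 16-bit images and secondary-assay
  tables, with ground truth for every cell and siRNA.

See the methods vignette (`vignettes/lipidscreen-methods.Rmd`) for the
model, parameter defaults and design decisions.

## Worked example

Simulate a 384-position screen in which the three siRNAs of one gene halve
total free cholesterol, then score and call it:

```r
library(lipidscreen)

cands <- data.frame(sirna_id = sprintf("s%03d", 1:30),
                    gene = paste0("GENE", rep(1:10, each = 3)))
fx <- list()
for (sid in cands$sirna_id[cands$gene == "GENE1"])
  fx[[sid]] <- effect_spec(sid, fc_total = 0.5)   # strong FC knockdown

layout    <- make_plate_layout("plate_384", cands, seed = 1)
sim       <- simulate_screen(layout, fx, n_replicates = 3, seed = 1)
summaries <- summarize_replicates(sim$cells, layout)
scored    <- score_deviations(summaries)           # region-normalized
ctrl      <- subset(scored$replicate_deviations,
                    role %in% c("negative_control", "mock"))
th        <- effector_thresholds(ctrl)
subset(th, parameter == "total")
#>   assay parameter     lower    upper       sem control_n n_replicates
#> 1    fc     total -2.495885 2.103665 0.4219624        19            3

calls <- call_effector_sirnas(scored$deviations, th)
subset(calls, direction != "none")[, c("sirna_id", "mean_deviation", "direction")]
#>    sirna_id mean_deviation direction
#> 4      s001      -9.123465  decrease
#> 15     s003      -7.156135  decrease
#> 19     s002      -6.961969  decrease

subset(call_hit_genes(calls, cands), is_hit)[, 1:5]
#>    gene is_hit assay supporting_sirnas n_sirnas_tested
#> 4 GENE1   TRUE    fc    s001,s002,s003               3
```

The thresholds are derived purely from the 19 control positions
(extreme control mean ± 3·SEM in deviation units); the three planted
siRNAs fall far below the lower bound (`decrease`), and GENE1 is called a
hit because ≥ 2 independent siRNAs are effectors in the same assay. On a
null screen the same pipeline calls (almost always) nothing — the control
self-exclusion and false-positive calibration are part of the test suite.

Published thresholds can be supplied verbatim instead of being derived,
to re-classify reported per-siRNA deviations:

```r
th_pub <- subset(published_thresholds(), screen == "GWAS2" & assay == "ldl")
call_effector_sirnas(data.frame(sirna_id = "s224006", mean_deviation = -1.47),
                     th_pub, parameter = NULL, roles = NULL)$direction
#> [1] "decrease"
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/lipidscreen.R` (`simulate` and `report` subcommands).

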