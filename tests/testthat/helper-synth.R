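# shared builders for the test suite; everything is generated in code

demo_candidates <- function(n_genes = 20, sirnas_per_gene = 3) {
  n <- n_genes * sirnas_per_gene
  data.frame(sirna_id = sprintf("s%04d", seq_len(n)),
             gene = paste0("G", rep(seq_len(n_genes), each = sirnas_per_gene)))
}

# null screen scored end to end; returns the scored pieces used repeatedly
demo_scored_screen <- function(seed = 1, cands = demo_candidates(),
                               effects = list(), n_replicates = 3,
                               region_normalize = TRUE, ...) {
  lay <- make_plate_layout("plate_384", cands, seed = seed)
  sim <- simulate_screen(lay, effects, n_replicates = n_replicates,
                         seed = seed + 1000, ...)
  summ <- summarize_replicates(sim$cells, lay)
  scored <- suppressWarnings(
    score_deviations(summ, region_normalize = region_normalize))
  ctrl <- scored$replicate_deviations[
    scored$replicate_deviations$role %in% c("negative_control", "mock"), ]
  list(layout = lay, sim = sim, summaries = summ, scored = scored,
       control_reps = ctrl,
       thresholds = effector_thresholds(ctrl))
}

# effects list giving `n_genes` genes a strong shift on the given driver
planted_effects <- function(cands, n_genes = 10, shift = 0.6,
                            field = "fc_total") {
  genes <- unique(cands$gene)[seq_len(n_genes)]
  fx <- list()
  for (sid in cands$sirna_id[cands$gene %in% genes]) {
    e <- effect_spec(sid)
    e[[field]] <- shift
    fx[[sid]] <- e
  }
  fx
}

# draw a disc image: background bg plus discs given as (cx, cy, r, value)
disc_image <- function(width, height, discs, bg = 0.05) {
  img <- matrix(bg, height, width)
  for (i in seq_len(nrow(discs))) {
    d2 <- outer((seq_len(height) - 1 - discs$cy[i])^2,
                (seq_len(width) - 1 - discs$cx[i])^2, `+`)
    img[d2 <= discs$r[i]^2] <- bg + discs$value[i]
  }
  img
}
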