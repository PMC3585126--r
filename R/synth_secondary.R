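#' Simulate secondary-assay tables with known ground truth
#'
#' Generates the four secondary-assay inputs from a design table of true
#' effects:
#' \itemize{
#'   \item qPCR: cycle-threshold values as
#'     `CT = baseline - log2(expression) + noise` for LDLR and the two
#'     housekeepers GAPDH and ACTB, in technical triplicate over biological
#'     replicates, plus untreated and mock calibrator samples.
#'   \item Western: integrated band densities proportional to protein level
#'     times a per-lane loading factor, for LDLR and tubulin, grouped by
#'     gel with untreated and control-siRNA lanes on every gel.
#'   \item Enzymatic: plate-reader fluorescence proportional to cellular
#'     cholesterol mass, for test siRNAs plus control-siRNA and mock
#'     groups.
#'   \item Overexpression: per-cell GFP and filipin totals for mock and
#'     cDNA-transfected dishes; in construct dishes a fraction of cells
#'     expresses GFP at `gfp_multiplier` times the mock scale and has its
#'     filipin signal scaled by the true FC ratio.
#' }
#'
#' @param design data.frame with one row per siRNA/construct; recognised
#'   columns (all optional except `sirna_id`): `gene`, `true_mrna_fold`
#'   (LDLR mRNA fold change, 1 = null), `true_protein_fold`,
#'   `true_chol_fold`, `true_fc_ratio` (filipin in transfected vs
#'   untransfected), `gfp_multiplier`, `transfected_fraction`.
#' @param n_replicates biological replicates per siRNA (default 4).
#' @param n_cells_per_dish cells sampled per overexpression dish.
#' @param ct_noise_sd,density_noise_sd,enzymatic_noise_sd,cell_noise_sd
#'   noise scales of the four generators; set to 0 for exact closed-form
#'   recovery.
#' @param seed integer seed.
#' @return named list `qpcr`, `western`, `enzymatic`, `overexpression` of
#'   data.frames, plus `design` echoing the ground truth.
#' @export
simulate_secondary_tables <- function(design, n_replicates = 4L,
                                      n_cells_per_dish = 500L,
                                      ct_noise_sd = 0.15,
                                      density_noise_sd = 0.08,
                                      enzymatic_noise_sd = 0.05,
                                      cell_noise_sd = 0.35, seed = 1L) {
  stopifnot(is.data.frame(design), "sirna_id" %in% names(design))
  d <- design
  defcol <- function(col, default) if (col %in% names(d)) d[[col]] else
    rep(default, nrow(d))
  d$true_mrna_fold <- defcol("true_mrna_fold", 1)
  d$true_protein_fold <- defcol("true_protein_fold", 1)
  d$true_chol_fold <- defcol("true_chol_fold", 1)
  d$true_fc_ratio <- defcol("true_fc_ratio", 1)
  d$gfp_multiplier <- defcol("gfp_multiplier", 200)
  d$transfected_fraction <- defcol("transfected_fraction", 0.3)
  d$gene <- if ("gene" %in% names(d)) d$gene else d$sirna_id

  with_seed(seed, {
    baseline <- c(LDLR = 24, GAPDH = 17, ACTB = 16)
    samples <- rbind(
      data.frame(sample_id = paste0("untreated_", seq_len(4)),
                 sirna_id = "untreated", expr = 1, role = "calibrator"),
      data.frame(sample_id = paste0("mock_", seq_len(4)),
                 sirna_id = "mock", expr = 1, role = "calibrator"),
      do.call(rbind, lapply(seq_len(nrow(d)), function(i)
        data.frame(sample_id = paste0(d$sirna_id[i], "_", seq_len(n_replicates)),
                   sirna_id = d$sirna_id[i], expr = d$true_mrna_fold[i],
                   role = "test"))))
    qpcr <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
      do.call(rbind, lapply(1:3, function(tr) {
        data.frame(sample_id = samples$sample_id[i],
                   sirna_id = samples$sirna_id[i], role = samples$role[i],
                   technical_rep = tr,
                   LDLR = baseline["LDLR"] - log2(samples$expr[i]) +
                     rnorm(1, 0, ct_noise_sd),
                   GAPDH = baseline["GAPDH"] + rnorm(1, 0, ct_noise_sd),
                   ACTB = baseline["ACTB"] + rnorm(1, 0, ct_noise_sd),
                   row.names = NULL)
      }))
    }))

    # Western: one gel per pair of test siRNAs, controls on every gel
    western <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
      do.call(rbind, lapply(seq_len(n_replicates), function(r) {
        gel <- sprintf("gel_%s_%d", d$sirna_id[i], r)
        gel_scale <- exp(rnorm(1, 0, 0.3))
        mk <- function(sid, role, prot) {
          lane_f <- exp(rnorm(1, 0, density_noise_sd))
          data.frame(gel_id = gel, lane_id = paste0(gel, "_", sid),
                     sirna_id = sid, role = role,
                     density_ldlr = 1000 * gel_scale * prot * lane_f *
                       exp(rnorm(1, 0, density_noise_sd)),
                     density_tubulin = 800 * gel_scale * lane_f,
                     flagged = FALSE, row.names = NULL)
        }
        rbind(mk("untreated", "control", 1), mk("s229174", "control", 1),
              mk(d$sirna_id[i], "test", d$true_protein_fold[i]))
      }))
    }))

    enzymatic <- rbind(
      data.frame(sirna_id = "s229174", role = "negative_control",
                 replicate = seq_len(6),
                 reading = 100 * exp(rnorm(6, 0, enzymatic_noise_sd))),
      data.frame(sirna_id = "mock", role = "mock", replicate = seq_len(6),
                 reading = 100 * exp(rnorm(6, 0, enzymatic_noise_sd))),
      do.call(rbind, lapply(seq_len(nrow(d)), function(i)
        data.frame(sirna_id = d$sirna_id[i], role = "test",
                   replicate = seq_len(n_replicates),
                   reading = 100 * d$true_chol_fold[i] *
                     exp(rnorm(n_replicates, 0, enzymatic_noise_sd))))))

    mock_gfp_meanlog <- log(50)
    ovx <- list()
    for (r in seq_len(n_replicates)) {
      ovx[[length(ovx) + 1L]] <- data.frame(
        dish_id = sprintf("mock_%d", r), construct = "mock", replicate = r,
        cell_id = seq_len(n_cells_per_dish), gene = NA_character_,
        gfp_total = rlnorm(n_cells_per_dish, mock_gfp_meanlog,
                           cell_noise_sd),
        filipin_total = rlnorm(n_cells_per_dish, log(200), cell_noise_sd),
        true_transfected = FALSE)
    }
    for (i in seq_len(nrow(d))) {
      for (r in seq_len(n_replicates)) {
        tf <- runif(n_cells_per_dish) < d$transfected_fraction[i]
        gfp <- rlnorm(n_cells_per_dish, mock_gfp_meanlog, cell_noise_sd)
        gfp[tf] <- gfp[tf] * d$gfp_multiplier[i]
        fil <- rlnorm(n_cells_per_dish, log(200), cell_noise_sd)
        fil[tf] <- fil[tf] * d$true_fc_ratio[i]
        ovx[[length(ovx) + 1L]] <- data.frame(
          dish_id = sprintf("%s_%d", d$sirna_id[i], r),
          construct = d$sirna_id[i], replicate = r,
          cell_id = seq_len(n_cells_per_dish), gene = d$gene[i],
          gfp_total = gfp, filipin_total = fil, true_transfected = tf)
      }
    }
    list(qpcr = qpcr, western = western, enzymatic = enzymatic,
         overexpression = do.call(rbind, ovx), design = d)
  })
}
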