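#' Construct a secondary-assay call
#'
#' @param id siRNA or gene identifier.
#' @param assay assay name.
#' @param direction `"+"`, `"-"`, `"n.s."` or `"untestable"`.
#' @param p_values t-test p-values supporting the call.
#' @param strength `"two-siRNA"` / `"one-siRNA"` when known.
#' @param details assay-specific diagnostics.
#' @return list of class `"secondary_call"`.
#' @export
secondary_call <- function(id, assay, direction, p_values = numeric(0),
                           strength = NA_character_, details = list()) {
  structure(list(id = id, assay = assay, direction = direction,
                 strength = strength, p_values = p_values,
                 details = details), class = "secondary_call")
}

#' @export
print.secondary_call <- function(x, ...) {
  cat(sprintf("<secondary_call> %s [%s]: %s\n", x$id, x$assay, x$direction))
  invisible(x)
}

ttest_p <- function(x, y, pooled = FALSE) {
  if (length(unique(c(x, y))) == 1) return(1)
  t.test(x, y, var.equal = pooled)$p.value
}

#' Enzymatic cholesterol effector call
#'
#' A siRNA is an effector on cellular cholesterol when its replica mean
#' deviates more than 2 standard deviations from the mean of the negative
#' controls (control siRNA and mock pooled) AND two two-sided t-tests,
#' against the control siRNA group and against the mock group, are both
#' p < 0.05.
#'
#' @param readings numeric vector of the siRNA's replica readings
#'   (>= 3).
#' @param control_sirna,mock numeric vectors of the two control groups.
#' @param sirna_id identifier for the call.
#' @param alpha t-test significance level (default 0.05).
#' @param pooled use pooled-variance t-tests instead of Welch.
#' @return a `"secondary_call"` with direction `"+"`, `"-"` or `"n.s."`.
#' @export
enzymatic_call <- function(readings, control_sirna, mock,
                           sirna_id = "siRNA", alpha = 0.05,
                           pooled = FALSE) {
  if (length(readings) < 3) stop("need >= 3 experimental replicas")
  if (!length(control_sirna) || !length(mock))
    stop("both control groups are required")
  ctl <- c(control_sirna, mock)
  dev2sd <- abs(mean(readings) - mean(ctl)) > 2 * sd(ctl)
  p1 <- ttest_p(readings, control_sirna, pooled)
  p2 <- ttest_p(readings, mock, pooled)
  sig <- dev2sd && p1 < alpha && p2 < alpha
  dir <- if (!sig) "n.s." else if (mean(readings) > mean(ctl)) "+" else "-"
  secondary_call(sirna_id, "enzymatic", dir, c(p1, p2),
                 details = list(deviation_sds =
                                  (mean(readings) - mean(ctl)) / sd(ctl)))
}

#' HuH7 free-cholesterol validation call
#'
#' A siRNA validates in HuH7 cells when (i) at least 50 cells per
#' experiment could be quantified (replicas below that are excluded; if
#' none remain the siRNA is untestable), (ii) the mean deviation value
#' lies outside the control confidence interval (control mean +/- 2 SEM of
#' both negative controls), and (iii) a two-sided t-test of the siRNA's
#' cells against control cells is p < 0.05 in at least two biological
#' replicas.
#'
#' @param replica_deviations per-replica mean deviation values of the
#'   siRNA.
#' @param replica_n_cells per-replica quantified cell counts (same
#'   length).
#' @param control_deviations pooled per-replica deviation values of the
#'   negative controls.
#' @param replica_p per-replica t-test p-values (siRNA cells vs control
#'   cells, computed upstream per experiment).
#' @param sirna_id identifier.
#' @param min_cells cell-count rule (default 50).
#' @return a `"secondary_call"`; direction `"untestable"` when no replica
#'   reaches `min_cells`.
#' @export
huh7_fc_call <- function(replica_deviations, replica_n_cells,
                         control_deviations, replica_p,
                         sirna_id = "siRNA", min_cells = 50L) {
  ok <- replica_n_cells >= min_cells
  if (!any(ok))
    return(secondary_call(sirna_id, "huh7_fc", "untestable"))
  dev <- mean(replica_deviations[ok])
  sem <- sd(control_deviations) / sqrt(length(control_deviations))
  ci <- mean(control_deviations) + c(-2, 2) * sem
  outside <- dev < ci[1] || dev > ci[2]
  n_sig <- sum(replica_p[ok] < 0.05, na.rm = TRUE)
  sig <- outside && n_sig >= 2
  dir <- if (!sig) "n.s." else if (dev > mean(control_deviations)) "+" else "-"
  secondary_call(sirna_id, "huh7_fc", dir, replica_p[ok],
                 details = list(mean_deviation = dev, ci = ci,
                                n_significant_replicas = n_sig))
}

#' Relative qPCR quantification (2^-ddCT)
#'
#' For each sample, `dCT = CT_target - CT_housekeeper` (technical
#' triplicates averaged on the CT scale first); `ddCT` subtracts the mean
#' `dCT` of the calibrator samples, and the fold change is `2^-ddCT`.
#'
#' @param qpcr data.frame with columns `sample_id`, `sirna_id`, `role`
#'   (`"test"`/`"calibrator"`), `technical_rep`, and CT columns for
#'   `target` and `housekeeper`.
#' @param target CT column of the target gene (default `"LDLR"`).
#' @param housekeeper CT column of the housekeeping gene (`"GAPDH"` or
#'   `"ACTB"`).
#' @return data.frame per sample: `sample_id`, `sirna_id`, `role`,
#'   `dct`, `ddct`, `fold_change`.
#' @export
ddct_fold_change <- function(qpcr, target = "LDLR",
                             housekeeper = c("GAPDH", "ACTB")) {
  housekeeper <- match.arg(housekeeper)
  if (!all(c(target, housekeeper) %in% names(qpcr)))
    stop("missing CT column: ", target, " or ", housekeeper)
  dt <- data.table::as.data.table(qpcr)
  per_sample <- dt[, .(ct_target = mean(.SD[[target]]),
                       ct_hk = mean(.SD[[housekeeper]]),
                       sirna_id = sirna_id[1], role = role[1]),
                   by = sample_id, .SDcols = c(target, housekeeper)]
  if (any(is.na(per_sample$ct_hk)))
    stop("missing housekeeper CT values")
  per_sample[, dct := ct_target - ct_hk]
  cal <- per_sample[role == "calibrator"]
  if (!nrow(cal)) stop("no calibrator samples")
  per_sample[, ddct := dct - mean(cal$dct)]
  per_sample[, fold_change := 2^(-ddct)]
  data.table::setDF(per_sample)
  per_sample[, c("sample_id", "sirna_id", "role", "dct", "ddct",
                 "fold_change")]
}

#' LDLR mRNA regulation call from qPCR fold changes
#'
#' A siRNA differentially regulates LDLR mRNA when its mean fold change
#' deviates more than 2 control standard deviations from the control mean
#' on BOTH housekeeper normalizations, AND four two-sided t-tests (against
#' untreated and mock calibrators, for each housekeeper) are all p < 0.01.
#' The control standard deviations may be supplied verbatim (the original
#' screen used 0.21 for the GAPDH and 0.20 for the ACTB normalization) or
#' recomputed from the calibrator fold changes.
#'
#' @param folds_gapdh,folds_actb [ddct_fold_change()] tables for the two
#'   housekeepers.
#' @param sirna_id siRNA to call.
#' @param control_sd named numeric `c(GAPDH = ..., ACTB = ...)`; `NULL`
#'   recomputes from calibrator samples.
#' @param alpha significance level (default 0.01).
#' @param pooled pooled-variance t-tests.
#' @return a `"secondary_call"`; `"untestable"` when a housekeeper table
#'   is missing the siRNA.
#' @export
ldlr_mrna_call <- function(folds_gapdh, folds_actb, sirna_id,
                           control_sd = c(GAPDH = 0.21, ACTB = 0.20),
                           alpha = 0.01, pooled = FALSE) {
  get <- function(tab, who) tab$fold_change[tab$sirna_id == who]
  test_g <- get(folds_gapdh, sirna_id); test_a <- get(folds_actb, sirna_id)
  if (!length(test_g) || !length(test_a))
    return(secondary_call(sirna_id, "ldlr_mrna", "untestable"))
  unt_g <- get(folds_gapdh, "untreated"); mock_g <- get(folds_gapdh, "mock")
  unt_a <- get(folds_actb, "untreated"); mock_a <- get(folds_actb, "mock")
  cal_g <- c(unt_g, mock_g); cal_a <- c(unt_a, mock_a)
  if (is.null(control_sd))
    control_sd <- c(GAPDH = sd(cal_g), ACTB = sd(cal_a))
  dev_g <- abs(mean(test_g) - mean(cal_g)) > 2 * control_sd[["GAPDH"]]
  dev_a <- abs(mean(test_a) - mean(cal_a)) > 2 * control_sd[["ACTB"]]
  ps <- c(ttest_p(test_g, unt_g, pooled), ttest_p(test_g, mock_g, pooled),
          ttest_p(test_a, unt_a, pooled), ttest_p(test_a, mock_a, pooled))
  sig <- dev_g && dev_a && all(ps < alpha)
  dir <- if (!sig) "n.s." else if (mean(test_g) > mean(cal_g)) "+" else "-"
  secondary_call(sirna_id, "ldlr_mrna", dir, ps,
                 details = list(fold_gapdh = mean(test_g),
                                fold_actb = mean(test_a)))
}

#' Normalize Western band densities within gels
#'
#' Divides each lane's integrated densities (LDLR absolute, and LDLR over
#' tubulin) by the average of the control lanes (untreated and control
#' siRNA) on the identical gel; flagged lanes are excluded.
#'
#' @param densitometry data.frame: `gel_id`, `lane_id`, `sirna_id`,
#'   `role` (`"control"`/`"test"`), `density_ldlr`, `density_tubulin`,
#'   optional `flagged`.
#' @return the table with `norm_ldlr` and `norm_ldlr_tub` appended; gels
#'   without control lanes raise an error.
#' @export
normalize_densitometry <- function(densitometry) {
  dt <- data.table::as.data.table(densitometry)
  if ("flagged" %in% names(dt)) dt <- dt[flagged != TRUE | is.na(flagged)]
  dt[, ratio_tub := density_ldlr / density_tubulin]
  dt[, `:=`(norm_ldlr = {
    ctl <- density_ldlr[role == "control"]
    if (!length(ctl)) stop("gel without control lanes: ", gel_id[1])
    density_ldlr / mean(ctl)
  }, norm_ldlr_tub = ratio_tub / mean(ratio_tub[role == "control"])),
  by = gel_id]
  data.table::setDF(dt)
  dt
}

#' LDLR protein regulation call from densitometry
#'
#' After per-gel normalization ([normalize_densitometry()]), a siRNA
#' regulates LDLR protein when its mean normalized level deviates more
#' than 2 control standard deviations from the control mean on BOTH scales
#' (absolute LDLR and LDLR/tubulin; original control SDs 0.13 and 0.18),
#' AND four two-sided t-tests (vs untreated and control-siRNA lanes, on
#' both scales) are all p < 0.01.
#'
#' @param densitometry raw densitometry table (see
#'   [normalize_densitometry()]).
#' @param sirna_id siRNA to call.
#' @param control_sd named numeric `c(ldlr = 0.13, ldlr_tub = 0.18)`;
#'   `NULL` recomputes from control lanes.
#' @param alpha significance level (default 0.01).
#' @param pooled pooled-variance t-tests.
#' @return a `"secondary_call"`.
#' @export
ldlr_protein_call <- function(densitometry, sirna_id,
                              control_sd = c(ldlr = 0.13, ldlr_tub = 0.18),
                              alpha = 0.01, pooled = FALSE) {
  nd <- normalize_densitometry(densitometry)
  test <- nd[nd$sirna_id == sirna_id & nd$role == "test", ]
  if (!nrow(test))
    return(secondary_call(sirna_id, "ldlr_protein", "untestable"))
  gels <- unique(test$gel_id)
  ctl <- nd[nd$role == "control" & nd$gel_id %in% gels, ]
  unt <- ctl[ctl$sirna_id == "untreated", ]
  csi <- ctl[ctl$sirna_id != "untreated", ]
  if (is.null(control_sd))
    control_sd <- c(ldlr = sd(ctl$norm_ldlr),
                    ldlr_tub = sd(ctl$norm_ldlr_tub))
  dev1 <- abs(mean(test$norm_ldlr) - mean(ctl$norm_ldlr)) >
    2 * control_sd[["ldlr"]]
  dev2 <- abs(mean(test$norm_ldlr_tub) - mean(ctl$norm_ldlr_tub)) >
    2 * control_sd[["ldlr_tub"]]
  ps <- c(ttest_p(test$norm_ldlr, unt$norm_ldlr, pooled),
          ttest_p(test$norm_ldlr, csi$norm_ldlr, pooled),
          ttest_p(test$norm_ldlr_tub, unt$norm_ldlr_tub, pooled),
          ttest_p(test$norm_ldlr_tub, csi$norm_ldlr_tub, pooled))
  sig <- dev1 && dev2 && all(ps < alpha)
  dir <- if (!sig) "n.s." else
    if (mean(test$norm_ldlr) > mean(ctl$norm_ldlr)) "+" else "-"
  secondary_call(sirna_id, "ldlr_protein", dir, ps,
                 details = list(norm_ldlr = mean(test$norm_ldlr),
                                norm_ldlr_tub = mean(test$norm_ldlr_tub)))
}

#' Classify cells by GFP expression
#'
#' Untransfected cells show GFP intensities below the 97th percentile of
#' the mock-transfected GFP distribution; transfected cells show GFP more
#' than 4-fold above that upper untransfected threshold; cells in between
#' are intermediate and excluded from ratio statistics.
#'
#' @param cells data.frame of cDNA-dish cells with `gfp_total`.
#' @param mock_cells data.frame (or numeric vector) of mock-dish GFP
#'   totals (>= 50 cells).
#' @param percentile mock percentile defining the untransfected bound.
#' @param fold fold factor above the bound defining transfected.
#' @return `cells` with `transfection_class` appended; the threshold is
#'   stored in attribute `"gfp_threshold"`.
#' @export
classify_transfection <- function(cells, mock_cells, percentile = 0.97,
                                  fold = 4) {
  mock_gfp <- if (is.data.frame(mock_cells)) mock_cells$gfp_total
    else mock_cells
  if (length(mock_gfp) < 50) stop("need >= 50 mock cells")
  thr <- unname(quantile(mock_gfp, percentile))
  cls <- ifelse(cells$gfp_total < thr, "untransfected",
                ifelse(cells$gfp_total > fold * thr, "transfected",
                       "intermediate"))
  cells$transfection_class <- cls
  attr(cells, "gfp_threshold") <- thr
  cells
}

#' Overexpression effect on free cholesterol
#'
#' Per replica, computes the ratio of mean filipin signal in transfected
#' cells relative to untransfected cells of the same dish, and relative to
#' mock-transfected cells; ratios are averaged over replicas. Significance
#' stars count replicas whose two-tailed t-test (transfected vs
#' untransfected filipin) is p < 0.01: 2 replicas = `"*"`, 3-4 = `"***"`.
#' A per-cell filipin-vs-GFP regression slope (on log GFP) reports the
#' concentration-dependent trend.
#'
#' @param classified_cells construct-dish cells with `replicate`,
#'   `filipin_total`, `gfp_total` and `transfection_class` (from
#'   [classify_transfection()]).
#' @param mock_cells mock-dish cells with `replicate` and
#'   `filipin_total`.
#' @param gene identifier for the call.
#' @param alpha per-replica significance level (default 0.01).
#' @return list: `gene`, `ratio_vs_untransfected`, `ratio_vs_mock`,
#'   `n_replicas_used`, `n_significant`, `stars` (`""`, `"*"` or
#'   `"***"`), `trend_slope`, `per_replica` data.frame. Replicas lacking
#'   transfected cells are excluded; fewer than 2 usable replicas ->
#'   `"untestable"`.
#' @export
overexpression_fc_effect <- function(classified_cells, mock_cells,
                                     gene = "gene", alpha = 0.01) {
  reps <- sort(unique(classified_cells$replicate))
  rows <- list()
  for (r in reps) {
    d <- classified_cells[classified_cells$replicate == r, ]
    tr <- d[d$transfection_class == "transfected", ]
    un <- d[d$transfection_class == "untransfected", ]
    mo <- mock_cells[mock_cells$replicate == r, ]
    if (nrow(tr) < 2 || nrow(un) < 2) next
    p <- ttest_p(tr$filipin_total, un$filipin_total)
    rows[[length(rows) + 1L]] <- data.frame(
      replicate = r,
      ratio_vs_untransfected = mean(tr$filipin_total) /
        mean(un$filipin_total),
      ratio_vs_mock = if (nrow(mo)) mean(tr$filipin_total) /
        mean(mo$filipin_total) else NA_real_,
      p_value = p)
  }
  if (length(rows) < 2)
    return(list(gene = gene, status = "untestable",
                n_replicas_used = length(rows)))
  pr <- do.call(rbind, rows)
  n_sig <- sum(pr$p_value < alpha)
  stars <- if (n_sig >= 3) "***" else if (n_sig >= 2) "*" else ""
  keep <- classified_cells$transfection_class != "intermediate"
  slope <- unname(coef(lm(filipin_total ~ log(gfp_total),
                          data = classified_cells[keep, ]))[2])
  list(gene = gene, status = "ok",
       ratio_vs_untransfected = mean(pr$ratio_vs_untransfected),
       ratio_vs_mock = mean(pr$ratio_vs_mock, na.rm = TRUE),
       n_replicas_used = nrow(pr), n_significant = n_sig, stars = stars,
       trend_slope = slope, per_replica = pr)
}

#' Combine secondary calls into a gene-by-assay symbol matrix
#'
#' Two concordant flagged siRNAs give `+`/`-`, a single flagged siRNA
#' `(+)`/`(-)`, discordant flagged siRNAs `-/+`, otherwise `n.s.`; genes
#' not tested in an assay are `n.d.`.
#'
#' @param calls list of `"secondary_call"` objects.
#' @param sirna_gene_map data.frame `sirna_id` -> `gene`.
#' @return character matrix gene x assay.
#' @export
secondary_call_matrix <- function(calls, sirna_gene_map) {
  df <- do.call(rbind, lapply(calls, function(cl)
    data.frame(id = cl$id, assay = cl$assay, direction = cl$direction)))
  df$gene <- sirna_gene_map$gene[match(df$id, sirna_gene_map$sirna_id)]
  df$gene[is.na(df$gene)] <- df$id[is.na(df$gene)]
  genes <- unique(df$gene); assays <- unique(df$assay)
  m <- matrix("n.d.", length(genes), length(assays),
              dimnames = list(genes, assays))
  for (g in genes) for (a in assays) {
    d <- df$direction[df$gene == g & df$assay == a]
    if (!length(d)) next
    flag <- d[d %in% c("+", "-")]
    m[g, a] <- if (length(unique(flag)) == 2) "-/+"
      else if (length(flag) >= 2) flag[1]
      else if (length(flag) == 1) paste0("(", flag, ")")
      else if (any(d == "untestable") && all(d == "untestable")) "n.d."
      else "n.s."
  }
  m
}
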