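#' Summarize per-cell records into replicate means
#'
#' Means are taken over all cells of an image, then image means are
#' averaged within each biological replicate, separately per phenotypic
#' parameter. Images flagged as failing QC are excluded before averaging.
#'
#' @param cell_records per-cell data.frame as produced by
#'   [simulate_screen()] or [extract_cell_features()]; must carry
#'   `position_id`, `replicate`, `image`, and the parameter columns.
#' @param layout plate layout joined by `position_id` (supplies `sirna_id`,
#'   `role`, `region` when missing from the records).
#' @param qc optional data.frame (`position_id`, `replicate`, `image`,
#'   `pass`) from [qc_images()]; failed images are dropped.
#' @param parameters parameter columns to summarize; defaults to the
#'   assay's parameter set plus `cell_area`.
#' @return long data.frame: `position_id`, `sirna_id`, `role`, `region`,
#'   `assay`, `replicate`, `parameter`, `mean_value`, `n_cells`,
#'   `n_images`. Positions with no passing image in a replicate get
#'   `n_images = 0` and `NA` mean.
#' @export
summarize_replicates <- function(cell_records, layout, qc = NULL,
                                 parameters = NULL) {
  dt <- data.table::as.data.table(cell_records)
  need <- c("position_id", "replicate", "image")
  if (!all(need %in% names(dt)))
    stop("cell_records must have columns: ", paste(need, collapse = ", "))
  for (col in c("sirna_id", "role", "region", "assay"))
    if (!col %in% names(dt) && col %in% names(layout))
      dt[, (col) := layout[[col]][match(dt$position_id, layout$position_id)]]
  if (is.null(parameters)) {
    parameters <- intersect(c("total", "concentration", "structures",
                              "area", "cell_area", "nucleus_area"),
                            names(dt))
    if ("area" %in% parameters && all(is.na(dt$area)))
      parameters <- setdiff(parameters, "area")
  }
  if (!is.null(qc)) {
    qcdt <- data.table::as.data.table(qc)
    dt <- merge(dt, qcdt[, c("position_id", "replicate", "image", "pass"),
                         with = FALSE],
                by = c("position_id", "replicate", "image"), all.x = TRUE)
    dt <- dt[is.na(pass) | pass == TRUE]
  }
  img <- dt[, c(lapply(.SD, mean), list(.n_cells = .N)),
            by = .(position_id, sirna_id, role, region, assay, replicate,
                   image),
            .SDcols = parameters]
  rep_ <- img[, c(lapply(.SD, mean),
                  list(n_cells = sum(.n_cells), n_images = .N)),
              by = .(position_id, sirna_id, role, region, assay, replicate),
              .SDcols = parameters]
  long <- data.table::melt(rep_, measure.vars = parameters,
                           variable.name = "parameter",
                           value.name = "mean_value",
                           variable.factor = FALSE)
  data.table::setDF(long)
  long
}

#' Deviation value of one siRNA against negative controls
#'
#' The screen's core statistic: the siRNA replicate mean minus the mean of
#' the negative-control replicate means, divided by twice the error of
#' those controls. The default error is the mean absolute deviation of the
#' control means about their mean (a z-score-like statistic where twice the
#' absolute error replaces the standard deviation); `"sd"` and `"sem"`
#' variants are available.
#'
#' @param sirna_mean replicate mean signal of the siRNA (vectorised).
#' @param control_means numeric vector (length >= 2) of negative-control
#'   replicate means from the identical replicate.
#' @param error error estimator: `"mad"` (mean absolute deviation, the
#'   default), `"sd"`, or `"sem"`.
#' @return deviation value(s), dimensionless ("deviation units").
#' @export
deviation_value <- function(sirna_mean, control_means,
                            error = c("mad", "sd", "sem")) {
  error <- match.arg(error)
  if (length(control_means) < 2) stop("need >= 2 control means")
  ctr <- mean(control_means)
  err <- switch(error,
                mad = mean_abs_dev(control_means),
                sd = sd(control_means),
                sem = sd(control_means) / sqrt(length(control_means)))
  if (!is.finite(err) || err <= 0)
    stop("degenerate controls: zero error")
  (sirna_mean - ctr) / (2 * err)
}

#' Score a screen: per-replicate and mean deviation values
#'
#' Computes the deviation value of every position for every parameter and
#' replicate, centring on the negative-control positions of the identical
#' replicate. With `region_normalize = TRUE` (the plate-effect correction
#' used for 384-well plate assays) only controls of the same plate region
#' are used, falling back to plate-wide controls with a warning when a
#' region holds fewer than `min_region_controls` negative controls.
#'
#' @param summaries long replicate summaries from [summarize_replicates()].
#' @param error error estimator, see [deviation_value()].
#' @param region_normalize use same-region controls (default `TRUE`; cell
#'   array assays should pass `FALSE`).
#' @param min_region_controls minimum negative controls per region before
#'   falling back (default 2).
#' @param fallback if `FALSE`, a control-poor region is an error instead.
#' @return list with `replicate_deviations` (long: position, parameter,
#'   replicate, deviation) and `deviations` (the aggregated table from
#'   [aggregate_deviations()]).
#' @export
score_deviations <- function(summaries, error = c("mad", "sd", "sem"),
                             region_normalize = TRUE,
                             min_region_controls = 2L, fallback = TRUE) {
  error <- match.arg(error)
  dt <- data.table::as.data.table(summaries)
  dt <- dt[!is.na(mean_value)]
  ctrl <- dt[role == "negative_control"]
  if (!nrow(ctrl)) stop("no negative-control positions in summaries")

  dev_one <- function(values, ctrl_values) {
    (values - mean(ctrl_values)) /
      (2 * switch(error, mad = mean_abs_dev(ctrl_values),
                  sd = sd(ctrl_values),
                  sem = sd(ctrl_values) / sqrt(length(ctrl_values))))
  }

  out <- vector("list", 0L)
  warned <- FALSE
  for (grp in split(dt, by = c("assay", "parameter", "replicate"))) {
    cg <- grp[role == "negative_control"]
    if (nrow(cg) < 2) stop("fewer than 2 negative controls in replicate")
    if (region_normalize) {
      grp[, deviation := NA_real_]
      for (reg in unique(grp$region)) {
        creg <- cg[region == reg]
        if (nrow(creg) < min_region_controls) {
          if (!fallback)
            stop(sprintf("region %s has < %d negative controls", reg,
                         min_region_controls))
          if (!warned) {
            warning("region with too few controls; falling back to plate-wide controls")
            warned <- TRUE
          }
          creg <- cg
        }
        err <- switch(error, mad = mean_abs_dev(creg$mean_value),
                      sd = sd(creg$mean_value),
                      sem = sd(creg$mean_value) / sqrt(nrow(creg)))
        if (!is.finite(err) || err <= 0) stop("degenerate controls: zero error")
        grp[region == reg,
            deviation := (mean_value - mean(creg$mean_value)) / (2 * err)]
      }
    } else {
      err <- switch(error, mad = mean_abs_dev(cg$mean_value),
                    sd = sd(cg$mean_value),
                    sem = sd(cg$mean_value) / sqrt(nrow(cg)))
      if (!is.finite(err) || err <= 0) stop("degenerate controls: zero error")
      grp[, deviation := (mean_value - mean(cg$mean_value)) / (2 * err)]
    }
    out[[length(out) + 1L]] <- grp
  }
  repdev <- data.table::rbindlist(out)
  for (cc in c("n_cells", "n_images"))
    if (!cc %in% names(repdev)) repdev[, (cc) := NA_integer_]
  repdev <- repdev[, .(position_id, sirna_id, role, region, assay,
                       parameter, replicate, deviation, n_cells, n_images)]
  data.table::setDF(repdev)
  list(replicate_deviations = repdev,
       deviations = aggregate_deviations(repdev))
}

#' Average per-replicate deviation values
#'
#' The functional effect of a siRNA is the arithmetic mean of its
#' deviation values over biological replicates; per-replicate values are
#' retained upstream for SEM-based thresholding.
#'
#' @param replicate_deviations long data.frame with `deviation` per
#'   (`position_id`, `parameter`, `replicate`).
#' @return data.frame: `position_id`, `sirna_id`, `role`, `region`,
#'   `assay`, `parameter`, `mean_deviation`, `n_replicates`.
#' @export
aggregate_deviations <- function(replicate_deviations) {
  dt <- data.table::as.data.table(replicate_deviations)
  if (!nrow(dt)) stop("empty deviation table")
  agg <- dt[!is.na(deviation),
            .(mean_deviation = mean(deviation), n_replicates = .N),
            by = .(position_id, sirna_id, role, region, assay, parameter)]
  data.table::setDF(agg)
  agg
}

#' Shapiro-Wilk and QQ check of control deviation values
#'
#' Controls that the deviation values of the negative controls are
#' compatible with a normal distribution, per parameter.
#'
#' @param control_deviations numeric vector of control deviation values
#'   (n >= 3, not constant).
#' @param parameter label stored in the result.
#' @return list: `parameter`, `statistic`, `p_value`, and `qq_points`
#'   (data.frame of theoretical and sample quantiles).
#' @export
control_normality_check <- function(control_deviations, parameter = "total") {
  x <- control_deviations[!is.na(control_deviations)]
  if (length(x) < 3) stop("need >= 3 control deviation values")
  if (sd(x) == 0) stop("degenerate controls: constant deviations")
  sw <- shapiro.test(x)
  qq <- data.frame(theoretical = qnorm(ppoints(length(x))),
                   sample = sort(x))
  list(parameter = parameter, statistic = unname(sw$statistic),
       p_value = sw$p.value, qq_points = qq)
}

#' Control-anchored effector thresholds
#'
#' A siRNA is an effector when its mean deviation value lies above or
#' below the mean of any of the negative controls (non-silencing siRNA and
#' mock positions) plus/minus three times the standard error of the mean,
#' where the SEM is the standard deviation of all control deviation values
#' divided by the square root of the number of biological replicates. The
#' default `"extreme"` mode takes the outermost control bound
#' (`max(control means) + 3 SEM`, `min(control means) - 3 SEM`); mode
#' `"nearest"` uses the innermost bounds instead.
#'
#' @param control_replicate_deviations per-replicate deviation values of
#'   the control positions (long data.frame with `position_id`,
#'   `parameter`, `deviation`; typically the `replicate_deviations` of
#'   [score_deviations()] filtered to roles `negative_control` and
#'   `mock`).
#' @param n_replicates number of biological replicates; inferred from the
#'   table when `NULL`.
#' @param mode `"extreme"` (default) or `"nearest"`.
#' @return data.frame with one row per (`assay`, `parameter`): `lower`,
#'   `upper`, `sem`, `control_n`, `n_replicates`.
#' @export
effector_thresholds <- function(control_replicate_deviations,
                                n_replicates = NULL,
                                mode = c("extreme", "nearest")) {
  mode <- match.arg(mode)
  dt <- data.table::as.data.table(control_replicate_deviations)
  dt <- dt[!is.na(deviation)]
  if (!"assay" %in% names(dt)) dt[, assay := NA_character_]
  if (!nrow(dt)) stop("no control deviations")
  out <- dt[, {
    nrep <- n_replicates %||% max(table(position_id))
    means <- tapply(deviation, position_id, mean)
    if (length(means) < 2) stop("need >= 2 control positions")
    s <- sd(deviation)
    if (!is.finite(s) || s == 0) stop("degenerate controls")
    sem <- s / sqrt(nrep)
    if (mode == "extreme")
      list(lower = min(means) - 3 * sem, upper = max(means) + 3 * sem,
           sem = sem, control_n = length(means),
           n_replicates = as.integer(nrep))
    else
      list(lower = max(means) - 3 * sem, upper = min(means) + 3 * sem,
           sem = sem, control_n = length(means),
           n_replicates = as.integer(nrep))
  }, by = .(assay, parameter)]
  bad <- out$lower >= out$upper
  if (any(bad)) stop("degenerate thresholds (lower >= upper)")
  data.table::setDF(out)
  out
}

#' Published effector thresholds on parameter "total"
#'
#' The control-derived bounds (deviation units) under which the original
#' screens classified siRNAs on the parameter "total", accepted verbatim
#' as configuration so that published per-siRNA deviations can be
#' re-classified without raw data.
#'
#' @return data.frame: `screen`, `assay`, `parameter`, `lower`, `upper`.
#' @export
published_thresholds <- function() {
  data.frame(screen = c("GWAS1", "GWAS2", "GWAS1", "GWAS2"),
             assay = c("ldl", "ldl", "fc", "fc"),
             parameter = "total",
             lower = c(-0.50, -0.55, -1.11, -1.06),
             upper = c(0.81, 1.02, 1.70, 1.05))
}

#' Classify siRNAs as effectors against thresholds
#'
#' Direction is `"increase"` when the mean deviation is strictly above the
#' upper bound, `"decrease"` strictly below the lower bound, `"none"`
#' otherwise (boundary equality is not an effect). Missing deviations are
#' called `"none"` with `missing = TRUE`.
#'
#' @param deviations aggregated deviation table
#'   ([aggregate_deviations()]), or any data.frame with `sirna_id` and
#'   `mean_deviation` (and optionally `parameter`, `assay`).
#' @param thresholds data.frame with `lower` and `upper` (single row, or
#'   rows matched by `assay`/`parameter`).
#' @param parameter parameter to classify on (default `"total"`, the hit
#'   calling parameter; the identical rule is applied to other parameters
#'   for fingerprints).
#' @param roles which layout roles to classify (default `"candidate"`;
#'   pass `c("negative_control", "mock")` for control self-exclusion
#'   checks, or `NULL` for all rows).
#' @return data.frame of effector calls: inputs plus `direction` and
#'   `missing`.
#' @export
call_effector_sirnas <- function(deviations, thresholds,
                                 parameter = "total", roles = "candidate") {
  par_sel <- parameter; role_sel <- roles
  dv <- data.table::as.data.table(deviations)
  if ("parameter" %in% names(dv) && !is.null(par_sel))
    dv <- dv[dv[["parameter"]] %in% par_sel]
  if ("role" %in% names(dv) && !is.null(role_sel))
    dv <- dv[dv[["role"]] %in% role_sel]
  th <- data.table::as.data.table(thresholds)
  bycols <- intersect(intersect(c("assay", "parameter"), names(th)),
                      names(dv))
  bycols <- bycols[vapply(bycols, function(cc)
    any(dv[[cc]] %in% th[[cc]]), logical(1))]
  if (length(bycols)) {
    dv <- merge(dv, th[, c(bycols, "lower", "upper"), with = FALSE],
                by = bycols, all.x = TRUE)
  } else {
    if (nrow(th) != 1)
      stop("ambiguous thresholds: supply one row or matching assay/parameter")
    dv[, `:=`(lower = th$lower, upper = th$upper)]
  }
  dv[, missing := is.na(mean_deviation) | is.na(lower)]
  dv[, direction := data.table::fcase(
    missing, "none",
    mean_deviation > upper, "increase",
    mean_deviation < lower, "decrease",
    default = "none")]
  data.table::setDF(dv)
  dv
}

#' Call hit genes from effector siRNAs
#'
#' A gene is a hit when at least two distinct siRNAs targeting it are
#' effectors in the same assay. Genes with fewer than two tested siRNAs
#' can never satisfy the rule and are flagged untestable.
#'
#' @param effector_calls calls from [call_effector_sirnas()] (rows may
#'   span assays; must carry `sirna_id`, `direction`, and `assay`).
#' @param sirna_gene_map data.frame `sirna_id` -> `gene` (each siRNA maps
#'   to one gene); defaults to `gene` column of `effector_calls`.
#' @return data.frame per gene: `gene`, `is_hit`, `assay` (the assay
#'   supporting the hit, or NA), `supporting_sirnas`
#'   (comma-separated), `n_sirnas_tested`, `direction_consistent`,
#'   `untestable_by_rule`.
#' @export
call_hit_genes <- function(effector_calls, sirna_gene_map = NULL) {
  ec <- data.table::as.data.table(effector_calls)
  if (!is.null(sirna_gene_map)) {
    ec[, gene := sirna_gene_map$gene[match(sirna_id,
                                           sirna_gene_map$sirna_id)]]
  }
  if (!"gene" %in% names(ec)) stop("no gene mapping available")
  ec <- ec[!is.na(gene)]
  if (!"assay" %in% names(ec)) ec[, assay := "assay1"]
  out <- ec[, {
    tested <- unique(sirna_id)
    eff <- .SD[direction != "none"]
    per_assay <- if (nrow(eff))
      eff[, .(n = data.table::uniqueN(sirna_id),
              dirs = list(unique(direction)),
              sirnas = list(sort(unique(sirna_id)))), by = assay]
    else NULL
    hit_row <- if (!is.null(per_assay) && any(per_assay$n >= 2))
      per_assay[which.max(per_assay$n)] else NULL
    list(is_hit = !is.null(hit_row),
         assay = if (!is.null(hit_row)) hit_row$assay else NA_character_,
         supporting_sirnas = if (!is.null(hit_row))
           paste(hit_row$sirnas[[1]], collapse = ",") else
             paste(sort(unique(eff$sirna_id)), collapse = ","),
         n_sirnas_tested = length(tested),
         direction_consistent = if (!is.null(hit_row))
           length(hit_row$dirs[[1]]) == 1L else NA,
         untestable_by_rule = length(tested) < 2L)
  }, by = gene]
  out[untestable_by_rule == TRUE, is_hit := FALSE]
  data.table::setDF(out)
  out
}

#' Validation rate between two screens
#'
#' Fraction of the siRNAs scored as effectors in screen 1 (restricted to
#' siRNAs re-analyzed in screen 2) that also meet the effector criteria in
#' screen 2, each screen scored against its own thresholds.
#'
#' @param calls_screen1,calls_screen2 effector call tables.
#' @param shared_sirnas siRNA ids analyzed in both screens; defaults to the
#'   intersection of the call tables.
#' @return list: `n_effectors_s1`, `n_validated`, `rate` (integer percent,
#'   `NA` when screen 1 has no effectors).
#' @export
validation_rate <- function(calls_screen1, calls_screen2,
                            shared_sirnas = NULL) {
  if (is.null(shared_sirnas))
    shared_sirnas <- intersect(calls_screen1$sirna_id,
                               calls_screen2$sirna_id)
  e1 <- unique(calls_screen1$sirna_id[calls_screen1$direction != "none"])
  e1 <- intersect(e1, shared_sirnas)
  e2 <- unique(calls_screen2$sirna_id[calls_screen2$direction != "none"])
  nv <- length(intersect(e1, e2))
  list(n_effectors_s1 = length(e1), n_validated = nv,
       rate = if (length(e1)) percent_ratio(nv, length(e1)) else NA_real_)
}

#' Pairwise Pearson correlations between phenotypic parameters
#'
#' Correlates the per-siRNA mean deviation values of the seven phenotypic
#' parameters (plus optional extra columns such as cell number and cell
#' area) across the screen.
#'
#' @param deviations aggregated deviation table (long), or an
#'   already-wide matrix/data.frame of siRNA x parameter values.
#' @param extra optional data.frame of additional per-siRNA columns
#'   (matched by `sirna_id`).
#' @param use observation handling passed to [stats::cor()]
#'   (default pairwise complete).
#' @return symmetric correlation matrix with unit diagonal; entries for
#'   constant columns are `NA`.
#' @export
parameter_correlations <- function(deviations, extra = NULL,
                                   use = "pairwise.complete.obs") {
  if (is.matrix(deviations) ||
      !all(c("parameter", "mean_deviation") %in% colnames(deviations))) {
    wide <- as.matrix(deviations)
  } else {
    dt <- data.table::as.data.table(deviations)
    key <- if ("assay" %in% names(dt) &&
               data.table::uniqueN(dt$assay) > 1)
      dt[, paste(assay, parameter, sep = "_")] else dt$parameter
    dt[, pcol := key]
    w <- data.table::dcast(dt, sirna_id ~ pcol,
                           value.var = "mean_deviation",
                           fun.aggregate = mean)
    if (!is.null(extra))
      w <- merge(w, extra, by = "sirna_id", all.x = TRUE)
    wide <- as.matrix(w[, -1])
    rownames(wide) <- w$sirna_id
  }
  if (nrow(wide) < 3) stop("need >= 3 siRNAs")
  suppressWarnings(cor(wide, use = use))
}

#' Empirical false-discovery rate against the control distribution
#'
#' Two-sided empirical p-value of each siRNA's mean deviation against the
#' pooled control deviation values, with the add-one rule
#' `p = 2 * (1 + #{controls at least as extreme on the nearer side}) /
#' (n + 1)` capped at 1, followed by Benjamini-Hochberg adjustment across
#' all siRNAs of the assay/parameter.
#'
#' @param deviations aggregated deviation table restricted to one
#'   assay/parameter (or any data.frame with `sirna_id` and
#'   `mean_deviation`).
#' @param control_deviations numeric vector of >= 10 control deviation
#'   values.
#' @return the input with columns `p_empirical` and `fdr` appended.
#' @export
empirical_fdr <- function(deviations, control_deviations) {
  ctl <- control_deviations[!is.na(control_deviations)]
  if (length(ctl) < 10) stop("need >= 10 control deviation values")
  dv <- data.table::as.data.table(deviations)
  n <- length(ctl)
  p <- vapply(dv$mean_deviation, function(d) {
    if (is.na(d)) return(NA_real_)
    hi <- (1 + sum(ctl >= d)) / (n + 1)
    lo <- (1 + sum(ctl <= d)) / (n + 1)
    min(1, 2 * min(hi, lo))
  }, numeric(1))
  dv[, p_empirical := p]
  dv[, fdr := p.adjust(p_empirical, method = "BH")]
  data.table::setDF(dv)
  dv
}
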