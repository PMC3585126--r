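#' Simulate a full replicated screen
#'
#' Generates a complete screen from a plate layout and per-siRNA effect
#' specifications: for every position, biological replicate and image,
#' per-cell phenotypic parameters are drawn from the scene's generative
#' model, with the effect shifts applied to the penetrant fraction of
#' cells, a multiplicative plate-region edge factor, and multiplicative
#' replicate-, position- and image-level intensity noise. With
#' `tables_only = TRUE` (the fast path used for statistical validation)
#' cell parameter tables are produced directly; otherwise full
#' multi-channel images are rendered per image field.
#'
#' @param layout a layout from [make_plate_layout()].
#' @param effects named list of [effect_spec()] keyed by `sirna_id`;
#'   positions without an entry (all controls) are simulated as null.
#' @param n_replicates number of biological replicates (>= 1).
#' @param scene a [scene_spec()]; `n_cells` is the expected cells per
#'   image, `edge_effect` the per-region intensity factors.
#' @param assay `"fc"` or `"ldl"`.
#' @param images_per_position image fields acquired per well and replicate.
#' @param tables_only if `TRUE`, skip rendering and return cell tables.
#' @param plate_noise_sd,replicate_noise_sd,image_noise_sd standard
#'   deviations of the log-normal multiplicative intensity factors shared
#'   per plate x replicate, per position x replicate, and per image.
#' @param seed master seed; the run is a pure function of inputs and seed.
#' @return list with `cells` (data.frame of per-cell records: position_id,
#'   sirna_id, role, region, replicate, image, total, concentration,
#'   structures, area (FC only, else NA), cell_area, nucleus_area),
#'   `ground_truth` (per-position effect shifts and null flag), `layout`,
#'   `assay`, and (when rendering) `image_sets`.
#' @export
simulate_screen <- function(layout, effects = list(), n_replicates = 3L,
                            scene = scene_spec(n_cells = 150),
                            assay = c("fc", "ldl"),
                            images_per_position = 4L, tables_only = TRUE,
                            plate_noise_sd = 0.08,
                            replicate_noise_sd = 0.05,
                            image_noise_sd = 0.02, seed = 1L) {
  assay <- match.arg(assay)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  missing_fx <- setdiff(names(effects), layout$sirna_id)
  if (length(missing_fx))
    warning("effects for siRNAs absent from layout: ",
            paste(missing_fx, collapse = ", "))

  pre <- if (assay == "fc") "fc" else "ldl"
  shift_of <- function(field, default = 1) {
    vapply(layout$sirna_id, function(s) {
      fx <- effects[[s]]
      if (is.null(fx)) default else fx[[field]]
    }, numeric(1), USE.NAMES = FALSE)
  }
  s_tot <- shift_of(paste0(pre, "_total"))
  s_con <- shift_of(paste0(pre, "_conc"))
  s_str <- shift_of(paste0(pre, "_structures"))
  s_area <- if (assay == "fc") shift_of("fc_area") else rep(1, nrow(layout))
  pen <- shift_of("knockdown_penetrance", default = 1)

  gt <- data.frame(position_id = layout$position_id,
                   sirna_id = layout$sirna_id, role = layout$role,
                   shift_total = s_tot, shift_conc = s_con,
                   shift_structures = s_str, shift_area = s_area,
                   penetrance = pen)
  gt$is_null <- abs(gt$shift_total - 1) < 1e-12 &
    abs(gt$shift_conc - 1) < 1e-12 &
    abs(gt$shift_structures - 1) < 1e-12 & abs(gt$shift_area - 1) < 1e-12

  if (!tables_only)
    return(simulate_screen_rendered(layout, gt, n_replicates, scene, assay,
                                    images_per_position, seed))

  with_seed(seed, {
    npos <- nrow(layout)
    grid <- data.table::CJ(pos = seq_len(npos),
                           replicate = seq_len(n_replicates),
                           image = seq_len(images_per_position))
    data.table::setorder(grid, pos, replicate, image)
    grid[, n_cells := rpois(.N, scene$n_cells)]
    # multiplicative intensity factors
    plate_f <- exp(rnorm(n_replicates, 0, plate_noise_sd))
    posrep_f <- matrix(exp(rnorm(npos * n_replicates, 0,
                                 replicate_noise_sd)), npos, n_replicates)
    grid[, img_f := exp(rnorm(.N, 0, image_noise_sd))]
    grid[, int_f := plate_f[replicate] *
            posrep_f[cbind(pos, replicate)] * img_f *
            scene$edge_effect[layout$region[pos]]]

    cells <- grid[rep(seq_len(.N), n_cells)]
    n <- nrow(cells)
    p <- cells$pos
    penetrant <- runif(n) < pen[p]
    f_str <- ifelse(penetrant, s_str[p], 1)
    f_amp <- ifelse(penetrant, s_con[p] * s_tot[p], 1)
    f_area <- ifelse(penetrant, s_area[p], 1)

    k <- rpois(n, scene$spots_per_cell * f_str)
    amp <- pmax(rnorm(n, scene$spot_intensity[1] * f_amp,
                      scene$spot_intensity[2]), 0.02)
    rbar <- mean(scene$spot_radius)
    A <- rgamma(n, shape = 8, scale = pi * rbar^2 * f_area / 8)
    cell_r <- runif(n, scene$cell_radius[1], scene$cell_radius[2])
    nuc_r <- runif(n, scene$nucleus_radius[1], scene$nucleus_radius[2])

    out <- data.table::data.table(
      position_id = layout$position_id[p],
      sirna_id = layout$sirna_id[p], role = layout$role[p],
      region = layout$region[p], replicate = cells$replicate,
      image = cells$image, assay = assay,
      total = amp * k * A * cells$int_f,
      concentration = ifelse(k > 0, amp * cells$int_f, 0),
      structures = k,
      area = if (assay == "fc") k * A else NA_real_,
      cell_area = pi * cell_r^2, nucleus_area = pi * nuc_r^2)
    out[k == 0, total := 0]
    out[, cell_id := seq_len(.N)]
    list(cells = data.table::setDF(out), ground_truth = gt,
         layout = layout, assay = assay, n_replicates = n_replicates,
         images_per_position = images_per_position, seed = seed)
  })
}

# Rendered path: loops over positions/replicates/images; intended for small
# layouts (segmentation oracles), not full-plate statistics.
simulate_screen_rendered <- function(layout, gt, n_replicates, scene, assay,
                                     images_per_position, seed) {
  image_sets <- list()
  gt_cells <- list()
  idx <- 1L
  for (i in seq_len(nrow(layout))) {
    fx_row <- gt[i, ]
    fx <- effect_spec(fx_row$sirna_id %||% "none")
    for (f in c("total", "conc", "structures"))
      fx[[paste0(assay, "_", f)]] <- fx_row[[paste0("shift_", f)]]
    if (assay == "fc") fx$fc_area <- fx_row$shift_area
    fx$knockdown_penetrance <- fx_row$penetrance
    for (r in seq_len(n_replicates)) {
      for (im in seq_len(images_per_position)) {
        sc <- scene
        sc$region <- layout$region[i]
        sc$seed <- as.integer(child_seed(seed, idx) %% 2147483646 + 1)
        pop <- simulate_cell_population(fx, sc, assay)
        attr(pop, "position_id") <- layout$position_id[i]
        attr(pop, "replicate") <- r
        iset <- with_seed(sc$seed + 1, render_images(pop, sc))
        iset$image <- im
        image_sets[[idx]] <- iset
        g <- iset$ground_truth
        if (nrow(g)) {
          g$position_id <- layout$position_id[i]
          g$replicate <- r; g$image <- im
          gt_cells[[idx]] <- g
        }
        idx <- idx + 1L
      }
    }
  }
  list(image_sets = image_sets, ground_truth = gt,
       ground_truth_cells = do.call(rbind, gt_cells), layout = layout,
       assay = assay, n_replicates = n_replicates,
       images_per_position = images_per_position, seed = seed)
}
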