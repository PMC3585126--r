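#' Per-siRNA ground-truth effect specification
#'
#' Signed multiplicative shifts on the latent drivers of the seven
#' phenotypic parameters (1.0 = no effect). Shifts act on the generative
#' drivers: `*_structures` scales the expected structure count,
#' `*_conc` the per-pixel structure amplitude, `*_total` an additional
#' amplitude multiplier, and `fc_area` the expected structure area.
#' `knockdown_penetrance` is the fraction of cells in which the shifts are
#' expressed.
#'
#' @param sirna_id siRNA identifier.
#' @param ldl_total,ldl_conc,ldl_structures,fc_total,fc_conc,fc_area,fc_structures
#'   multiplicative shifts, all `> 0`.
#' @param knockdown_penetrance fraction in `[0, 1]`.
#' @return list of class `"effect_spec"`.
#' @export
effect_spec <- function(sirna_id, ldl_total = 1, ldl_conc = 1,
                        ldl_structures = 1, fc_total = 1, fc_conc = 1,
                        fc_area = 1, fc_structures = 1,
                        knockdown_penetrance = 1) {
  shifts <- c(ldl_total = ldl_total, ldl_conc = ldl_conc,
              ldl_structures = ldl_structures, fc_total = fc_total,
              fc_conc = fc_conc, fc_area = fc_area,
              fc_structures = fc_structures)
  if (any(shifts <= 0)) stop("effect shifts must be > 0")
  if (knockdown_penetrance < 0 || knockdown_penetrance > 1)
    stop("knockdown_penetrance must be in [0, 1]")
  structure(c(list(sirna_id = sirna_id), as.list(shifts),
              list(knockdown_penetrance = knockdown_penetrance)),
            class = "effect_spec")
}

#' Is an effect specification null (all shifts 1)?
#' @param effect an [effect_spec()].
#' @return logical.
#' @export
is_null_effect <- function(effect) {
  all(abs(unlist(effect[parameter_shift_names()]) - 1) < 1e-12)
}

parameter_shift_names <- function() {
  c("ldl_total", "ldl_conc", "ldl_structures", "fc_total", "fc_conc",
    "fc_area", "fc_structures")
}

#' Synthetic scene specification
#'
#' Geometry, intensity and noise model of one rendered field of view.
#' Intensities are fractions of the 16-bit dynamic range; images are
#' single-plane 16-bit with 0-based, row-major pixel coordinates. Cells are
#' discs with disc nuclei and an annular perinuclear ring; free-cholesterol
#' structures are placed in the ring, LDL endosomal spots anywhere in the
#' cytoplasm.
#'
#' @param width,height image size in pixels.
#' @param n_cells expected number of cells per field.
#' @param cell_radius,nucleus_radius `c(min, max)` radii in pixels.
#' @param spots_per_cell expected structure count per cell (Poisson mean).
#' @param spot_radius `c(min, max)` structure radius in pixels.
#' @param spot_intensity `c(mean, sd)` of the structure amplitude above
#'   background.
#' @param ring_width perinuclear ring width in pixels (FC structures are
#'   placed between the nucleus boundary and this distance from it).
#' @param background flat background level; `gradient_amplitude` adds a
#'   left-to-right linear shading of this amplitude.
#' @param edge_effect multiplicative intensity factor per plate region
#'   (region 1 wells are dimmer at plate edges).
#' @param noise_sd Gaussian read noise (sd, fraction of dynamic range);
#'   `poisson_noise` toggles additional shot noise.
#' @param min_spacing minimum distance between cell centres; default keeps
#'   whole cells disjoint so the rendered field is sub-confluent.
#' @param region plate region the scene belongs to (selects the edge
#'   factor).
#' @param seed integer; fully determines the scene.
#' @return list of class `"scene_spec"`.
#' @export
scene_spec <- function(width = 256L, height = 256L, n_cells = 8L,
                       cell_radius = c(18, 24), nucleus_radius = c(6, 9),
                       spots_per_cell = 6, spot_radius = c(2, 4),
                       spot_intensity = c(0.25, 0.05), ring_width = 15,
                       background = 0.05, gradient_amplitude = 0,
                       edge_effect = c(0.85, 0.95, 1),
                       noise_sd = 0.02, poisson_noise = FALSE,
                       min_spacing = NULL, region = 3L, seed = 1L) {
  if (any(c(cell_radius, nucleus_radius, spot_radius) < 1))
    stop("all radii must be >= 1 px")
  if (max(nucleus_radius) >= min(cell_radius))
    stop("nucleus radius must be below cell radius")
  if (is.null(min_spacing)) min_spacing <- 2 * max(cell_radius) + 2
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_cells = n_cells, cell_radius = cell_radius,
                 nucleus_radius = nucleus_radius,
                 spots_per_cell = spots_per_cell, spot_radius = spot_radius,
                 spot_intensity = spot_intensity, ring_width = ring_width,
                 background = background,
                 gradient_amplitude = gradient_amplitude,
                 edge_effect = edge_effect, noise_sd = noise_sd,
                 poisson_noise = poisson_noise, min_spacing = min_spacing,
                 region = as.integer(region), seed = as.integer(seed)),
            class = "scene_spec")
}

# Rejection-sample k points in [lo, hi]^2 with pairwise distance >= d.
place_centres <- function(k, xlim, ylim, d, max_tries = 2000L) {
  cx <- numeric(0); cy <- numeric(0); tries <- 0L
  while (length(cx) < k && tries < max_tries) {
    x <- runif(1, xlim[1], xlim[2]); y <- runif(1, ylim[1], ylim[2])
    if (!length(cx) || all((cx - x)^2 + (cy - y)^2 >= d^2)) {
      cx <- c(cx, x); cy <- c(cy, y)
    }
    tries <- tries + 1L
  }
  cbind(x = cx, y = cy)
}

#' Simulate one field's cell population
#'
#' Draws per-cell latent parameters from the scene distributions and
#' applies the effect shifts to the penetrant fraction of cells. Returns
#' the per-cell latent table, the individual structures (spots), and the
#' ground truth used by recovery tests.
#'
#' @param effect an [effect_spec()].
#' @param scene a [scene_spec()].
#' @param assay `"fc"` or `"ldl"`; selects which shifts apply and where
#'   structures are placed (perinuclear ring vs whole cytoplasm).
#' @return list with elements `cells` (data.frame: `cell_id`, `cx`, `cy`,
#'   `cell_r`, `nuc_r`, `penetrant`, `n_spots`), `spots` (data.frame:
#'   `cell_id`, `x`, `y`, `r`, `amplitude`) and `ground_truth` (per-cell
#'   true centre, structure count and expected integrated signal).
#' @export
simulate_cell_population <- function(effect, scene, assay = c("fc", "ldl")) {
  assay <- match.arg(assay)
  with_seed(scene$seed, {
    pre <- if (assay == "fc") "fc" else "ldl"
    s_tot <- effect[[paste0(pre, "_total")]]
    s_con <- effect[[paste0(pre, "_conc")]]
    s_str <- effect[[paste0(pre, "_structures")]]
    s_area <- if (assay == "fc") effect$fc_area else 1

    rmax <- max(scene$cell_radius)
    ctr <- place_centres(scene$n_cells,
                         c(rmax + 1, scene$width - rmax - 2),
                         c(rmax + 1, scene$height - rmax - 2),
                         scene$min_spacing)
    n <- nrow(ctr)
    cell_r <- runif(n, scene$cell_radius[1], scene$cell_radius[2])
    nuc_r <- runif(n, scene$nucleus_radius[1], scene$nucleus_radius[2])
    pen <- runif(n) < effect$knockdown_penetrance

    spots <- vector("list", n)
    n_spots <- integer(n)
    for (i in seq_len(n)) {
      f_str <- if (pen[i]) s_str else 1
      f_con <- if (pen[i]) s_con * s_tot else 1
      f_area <- if (pen[i]) s_area else 1
      k <- rpois(1, scene$spots_per_cell * f_str)
      if (k == 0) { spots[[i]] <- NULL; next }
      r <- pmax(1, runif(k, scene$spot_radius[1], scene$spot_radius[2]) *
                  sqrt(f_area))
      amp <- pmax(0.02, rnorm(k, scene$spot_intensity[1] * f_con,
                              scene$spot_intensity[2]))
      # place spots without overlap inside the allowed compartment
      inner <- if (assay == "fc") nuc_r[i] else nuc_r[i]
      outer <- if (assay == "fc")
        min(nuc_r[i] + scene$ring_width, cell_r[i]) else cell_r[i]
      sx <- numeric(0); sy <- numeric(0); sr <- numeric(0); sa <- numeric(0)
      tries <- 0L
      j <- 1L
      while (j <= k && tries < 400L) {
        rad <- runif(1, inner + r[j] + 1, max(inner + r[j] + 1,
                                              outer - r[j] - 1))
        th <- runif(1, 0, 2 * pi)
        x <- ctr[i, 1] + rad * cos(th); y <- ctr[i, 2] + rad * sin(th)
        ok <- !length(sx) || all((sx - x)^2 + (sy - y)^2 >
                                   (sr + r[j] + 1)^2)
        if (ok) {
          sx <- c(sx, x); sy <- c(sy, y); sr <- c(sr, r[j]); sa <- c(sa, amp[j])
          j <- j + 1L
        }
        tries <- tries + 1L
      }
      n_spots[i] <- length(sx)
      if (length(sx))
        spots[[i]] <- data.frame(cell_id = i, x = sx, y = sy, r = sr,
                                 amplitude = sa)
    }
    spots <- if (length(spots)) do.call(rbind, spots) else NULL
    if (is.null(spots))
      spots <- data.frame(cell_id = integer(0), x = numeric(0),
                          y = numeric(0), r = numeric(0),
                          amplitude = numeric(0))
    cells <- data.frame(cell_id = seq_len(n), cx = ctr[, 1], cy = ctr[, 2],
                        cell_r = cell_r, nuc_r = nuc_r, penetrant = pen,
                        n_spots = n_spots)
    expected <- vapply(seq_len(n), function(i) {
      s <- spots[spots$cell_id == i, , drop = FALSE]
      if (!nrow(s)) 0 else sum(s$amplitude * pi * s$r^2)
    }, numeric(1))
    gt <- data.frame(cell_id = cells$cell_id, cx = cells$cx, cy = cells$cy,
                     n_spots = n_spots, expected_integrated = expected)
    list(cells = cells, spots = spots, ground_truth = gt, assay = assay,
         effect = effect, scene = scene)
  })
}
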