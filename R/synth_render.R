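# Disc rasterisation: add `value` to all pixels within radius r of (x, y).
# Coordinates are 0-based; the matrix is indexed [y + 1, x + 1]. Returns the
# updated matrix; the number of pixels touched is stored in attr "npix".
stamp_disc <- function(img, x, y, r, value, mode = c("add", "set")) {
  mode <- match.arg(mode)
  h <- nrow(img); w <- ncol(img)
  x0 <- max(0L, floor(x - r)); x1 <- min(w - 1L, ceiling(x + r))
  y0 <- max(0L, floor(y - r)); y1 <- min(h - 1L, ceiling(y + r))
  if (x0 > x1 || y0 > y1) { attr(img, "npix") <- 0L; return(img) }
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((ys - y)^2, (xs - x)^2, `+`)
  m <- d2 <= r^2
  sub <- img[ys + 1L, xs + 1L, drop = FALSE]
  if (mode == "add") sub[m] <- sub[m] + value else sub[m] <- value
  img[ys + 1L, xs + 1L] <- sub
  attr(img, "npix") <- sum(m)
  img
}

#' Render the multi-channel images of a simulated field
#'
#' Rasterises a simulated cell population into the three screen channels:
#' nuclei as filled discs (nuclear channel), cell bodies as discs
#' (cell-region channel), and structures as discs on a flat background plus
#' optional gradient (signal channel). The per-region edge factor scales
#' all channels multiplicatively; Gaussian read noise and optional Poisson
#' shot noise are added last. Images are numeric matrices in `[0, 1]`
#' intended for 16-bit export.
#'
#' @param population result of [simulate_cell_population()].
#' @param scene a [scene_spec()]; defaults to the scene stored in
#'   `population`.
#' @return list of class `"image_set"` with elements `channels` (named list
#'   `nuclear`, `cell_region`, `signal`), `ground_truth` (per-cell realized
#'   integrated signal above background and structure count),
#'   `position_id`, `replicate`, `assay`, `qc_flag` and `meta` (seed,
#'   region, edge factor, `clipped` flag for cells touching the border).
#' @export
render_images <- function(population, scene = population$scene) {
  cells <- population$cells; spots <- population$spots
  h <- scene$height; w <- scene$width
  edge_f <- scene$edge_effect[scene$region]
  base <- matrix(scene$background, h, w)
  if (scene$gradient_amplitude > 0) {
    grad <- matrix(rep(seq(0, scene$gradient_amplitude, length.out = w),
                       each = h), h, w)
    base <- base + grad
  }
  nuclear <- base; cellch <- base; signal <- base
  clipped <- FALSE
  for (i in seq_len(nrow(cells))) {
    if (cells$cx[i] - cells$cell_r[i] < 0 ||
        cells$cx[i] + cells$cell_r[i] > w - 1 ||
        cells$cy[i] - cells$cell_r[i] < 0 ||
        cells$cy[i] + cells$cell_r[i] > h - 1) clipped <- TRUE
    nuclear <- stamp_disc(nuclear, cells$cx[i], cells$cy[i], cells$nuc_r[i],
                          0.55)
    cellch <- stamp_disc(cellch, cells$cx[i], cells$cy[i], cells$cell_r[i],
                         0.25)
  }
  realized <- numeric(nrow(cells))
  if (nrow(spots)) {
    for (j in seq_len(nrow(spots))) {
      signal <- stamp_disc(signal, spots$x[j], spots$y[j], spots$r[j],
                           spots$amplitude[j])
      realized[spots$cell_id[j]] <- realized[spots$cell_id[j]] +
        spots$amplitude[j] * attr(signal, "npix")
    }
  }
  chans <- lapply(list(nuclear = nuclear, cell_region = cellch,
                       signal = signal), function(ch) {
    ch <- ch * edge_f
    if (scene$poisson_noise) {
      counts <- pmax(ch, 0) * 65535
      ch <- rpois(length(counts), counts) / 65535
      dim(ch) <- dim(counts)
    }
    if (scene$noise_sd > 0)
      ch <- ch + rnorm(length(ch), 0, scene$noise_sd)
    pmin(pmax(ch, 0), 1)
  })
  gt <- population$ground_truth
  gt$realized_integrated <- realized * edge_f
  structure(list(channels = chans, ground_truth = gt,
                 position_id = attr(population, "position_id") %||% "A01",
                 replicate = attr(population, "replicate") %||% 1L,
                 assay = population$assay, qc_flag = "unreviewed",
                 meta = list(seed = scene$seed, region = scene$region,
                             edge_factor = edge_f, clipped = clipped)),
            class = "image_set")
}

#' Write an image set to TIFF files
#'
#' One 16-bit single-plane TIFF per channel, named
#' `<position>_r<rep>_<channel>.tif`.
#'
#' @param image_set an `"image_set"` from [render_images()].
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_image_set <- function(image_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(image_set$channels)) {
    p <- file.path(dir, sprintf("%s_r%d_%s.tif", image_set$position_id,
                                image_set$replicate, ch))
    EBImage::writeImage(EBImage::Image(t(image_set$channels[[ch]])), p,
                        type = "tiff", bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a single-channel TIFF into the package's matrix convention
#'
#' @param path TIFF path.
#' @return numeric matrix in `[0, 1]`, `[y + 1, x + 1]` indexed.
#' @export
read_channel_tiff <- function(path) {
  t(EBImage::imageData(EBImage::readImage(path))[, , drop = TRUE])
}
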