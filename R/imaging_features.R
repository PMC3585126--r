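#' Extract the per-cell phenotypic parameters
#'
#' From the segmentation and detected structures of one image, computes
#' per cell: `total` (summed signal above each structure's local
#' background, floored at 0), `concentration` (mean signal above local
#' background per mask pixel, i.e. `total` divided by the summed mask
#' area), `structures` (mask count), `area` (summed mask area; free
#' cholesterol assay only), plus `cell_area` and `nucleus_area`. Cells
#' without structures get zeros, not missing values.
#'
#' @param cell_labels,nuclei_labels label matrices.
#' @param structures result of [detect_structures()].
#' @param signal_channel intensity matrix.
#' @param assay `"fc"` or `"ldl"` (LDL records carry `area = NA`).
#' @param position_id,replicate,image identifiers copied into the records.
#' @return data.frame of cell records, one row per nucleus.
#' @export
extract_cell_features <- function(cell_labels, nuclei_labels, structures,
                                  signal_channel, assay = c("fc", "ldl"),
                                  position_id = "A01", replicate = 1L,
                                  image = 1L) {
  assay <- match.arg(assay)
  n_cells <- max(cell_labels)
  cell_area <- tabulate(cell_labels[cell_labels > 0], nbins = n_cells)
  nuc_area <- tabulate(nuclei_labels[nuclei_labels > 0], nbins = n_cells)
  tot <- conc <- ar <- numeric(n_cells)
  cnt <- integer(n_cells)
  maskpx <- numeric(n_cells)
  sdf <- structures$structures
  for (j in seq_len(nrow(sdf))) {
    cid <- sdf$cell_id[j]
    if (cid < 1 || cid > n_cells) next
    pix <- structures$pixels[[j]]
    tot[cid] <- tot[cid] +
      sum(pmax(signal_channel[pix] - sdf$local_bg[j], 0))
    maskpx[cid] <- maskpx[cid] + length(pix)
    cnt[cid] <- cnt[cid] + 1L
    ar[cid] <- ar[cid] + length(pix)
  }
  conc <- ifelse(maskpx > 0, tot / maskpx, 0)
  data.frame(position_id = position_id, replicate = replicate,
             image = image, cell_id = seq_len(n_cells), assay = assay,
             total = tot, concentration = conc, structures = cnt,
             area = if (assay == "fc") ar else NA_real_,
             cell_area = cell_area, nucleus_area = nuc_area)
}

#' Quantify one image set end to end
#'
#' Runs nucleus segmentation, cell-region approximation (dilation for FC,
#' propagation on the cell-region channel for LDL), structure detection
#' and feature extraction.
#'
#' @param image_set an `"image_set"` (see [render_images()]).
#' @param assay `"fc"` or `"ldl"`; defaults to the set's assay.
#' @param segment_params,region_params,struct_params parameter lists for
#'   [segment_nuclei()], [approximate_cell_regions()] and
#'   [detect_structures()].
#' @return data.frame of cell records ([extract_cell_features()]).
#' @export
quantify_image_set <- function(image_set, assay = NULL,
                               segment_params = list(),
                               region_params = list(),
                               struct_params = NULL) {
  assay <- assay %||% image_set$assay %||% "fc"
  nuc <- do.call(segment_nuclei,
                 c(list(image_set$channels$nuclear), segment_params))
  mode <- if (assay == "fc") "dilate" else "propagate"
  aux <- if (mode == "propagate") image_set$channels$cell_region else NULL
  cells <- do.call(approximate_cell_regions,
                   c(list(nuc, mode = mode, aux_channel = aux),
                     region_params))
  if (is.null(struct_params))
    struct_params <- structure_params(
      region = if (assay == "fc") "perinuclear_ring" else "whole_cell")
  st <- detect_structures(image_set$channels$signal, cells, nuc,
                          struct_params)
  extract_cell_features(cells, nuc, st, image_set$channels$signal, assay,
                        position_id = image_set$position_id,
                        replicate = image_set$replicate,
                        image = image_set$image %||% 1L)
}

#' Quantify all rendered images of a simulated screen
#'
#' @param screen result of [simulate_screen()] with
#'   `tables_only = FALSE`.
#' @param ... passed to [quantify_image_set()].
#' @return combined cell-record data.frame.
#' @export
quantify_screen_images <- function(screen, ...) {
  recs <- lapply(screen$image_sets, quantify_image_set, ...)
  do.call(rbind, recs)
}
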