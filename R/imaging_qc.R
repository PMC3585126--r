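#' Image QC criteria
#'
#' Automated surrogate for visual quality control: images are excluded
#' when out of focus (low variance of the Laplacian of the nuclear
#' channel), at aberrant cell density, or saturated.
#'
#' @param min_focus minimum variance-of-Laplacian focus score.
#' @param min_cells,max_cells admissible nucleus count per image.
#' @param max_saturation maximum fraction of saturated signal pixels.
#' @return list of class `"qc_criteria"`.
#' @export
qc_criteria <- function(min_focus = 1e-4, min_cells = 1L, max_cells = 5000L,
                        max_saturation = 0.01) {
  structure(list(min_focus = min_focus, min_cells = min_cells,
                 max_cells = max_cells, max_saturation = max_saturation),
            class = "qc_criteria")
}

laplacian_focus <- function(x) {
  k <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  lap <- EBImage::imageData(EBImage::filter2(EBImage::Image(x), k))
  var(as.numeric(lap))
}

#' Quality-control a collection of image sets
#'
#' Flags each image pass/fail with a reason (`focus`, `cell_density`,
#' `saturation`).
#'
#' @param image_sets list of `"image_set"` objects (see [render_images()]).
#' @param criteria a [qc_criteria()].
#' @param segment_params nucleus segmentation parameters used for the
#'   cell-density check.
#' @return list with `image_sets` (qc_flag updated) and `qc` (data.frame:
#'   `position_id`, `replicate`, `image`, `pass`, `reason`, `focus`,
#'   `n_nuclei`, `saturation`) suitable for [summarize_replicates()].
#' @export
qc_images <- function(image_sets, criteria = qc_criteria(),
                      segment_params = list()) {
  if (!length(image_sets)) stop("empty image collection")
  rows <- vector("list", length(image_sets))
  for (i in seq_along(image_sets)) {
    s <- image_sets[[i]]
    foc <- laplacian_focus(s$channels$nuclear)
    nlab <- do.call(segment_nuclei, c(list(s$channels$nuclear),
                                      segment_params))
    n_nuc <- max(nlab)
    sat <- mean(s$channels$signal >= 0.999)
    reason <- if (foc < criteria$min_focus) "focus"
      else if (n_nuc < criteria$min_cells ||
               n_nuc > criteria$max_cells) "cell_density"
      else if (sat > criteria$max_saturation) "saturation"
      else NA_character_
    pass <- is.na(reason)
    image_sets[[i]]$qc_flag <- if (pass) "pass" else "fail"
    rows[[i]] <- data.frame(position_id = s$position_id,
                            replicate = s$replicate,
                            image = s$image %||% 1L, pass = pass,
                            reason = reason, focus = foc, n_nuclei = n_nuc,
                            saturation = sat)
  }
  list(image_sets = image_sets, qc = do.call(rbind, rows))
}
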