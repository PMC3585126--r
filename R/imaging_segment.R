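# drop labelled objects below a minimum pixel area and relabel 1..k
filter_small_labels <- function(labels, min_area) {
  if (max(labels) == 0) return(labels)
  sizes <- tabulate(labels[labels > 0], nbins = max(labels))
  keep <- which(sizes >= min_area)
  map <- integer(max(labels))
  map[keep] <- seq_along(keep)
  out <- labels
  out[out > 0] <- map[out[out > 0]]
  out
}

#' Segment nuclei from the nuclear channel
#'
#' Gaussian smoothing, global (Otsu by default) thresholding, connected
#' component labelling, removal of objects below the minimum area, and an
#' optional distance-transform watershed to split touching nuclei.
#'
#' @param nuclear_channel 2-D numeric matrix in `[0, 1]`.
#' @param smoothing_sigma Gaussian sigma in pixels (0 = no smoothing).
#' @param threshold `"otsu"` or a numeric global threshold.
#' @param min_area minimum nucleus area in px^2.
#' @param split_touching if `TRUE`, apply a seeded watershed on the
#'   distance map to separate touching nuclei.
#' @param watershed_tolerance tolerance passed to [EBImage::watershed()].
#' @param min_contrast minimum intensity range of the smoothed image below
#'   which the field is treated as empty (0 labels).
#' @return integer label matrix (0 = background), one label per nucleus.
#' @export
segment_nuclei <- function(nuclear_channel, smoothing_sigma = 2,
                           threshold = "otsu", min_area = 30L,
                           split_touching = FALSE,
                           watershed_tolerance = 1, min_contrast = 0.1) {
  x <- EBImage::Image(nuclear_channel)
  if (smoothing_sigma > 0) x <- EBImage::gblur(x, sigma = smoothing_sigma)
  # images without real foreground (blank fields) would otherwise be split
  # arbitrarily by a global threshold on noise
  if (diff(range(x)) < min_contrast)
    return(matrix(0L, nrow(nuclear_channel), ncol(nuclear_channel)))
  thr <- if (identical(threshold, "otsu")) EBImage::otsu(x, range = c(0, 1))
    else as.numeric(threshold)
  mask <- x > thr
  if (!any(mask)) return(matrix(0L, nrow(nuclear_channel),
                                ncol(nuclear_channel)))
  labels <- if (split_touching) {
    EBImage::watershed(EBImage::distmap(mask),
                       tolerance = watershed_tolerance)
  } else EBImage::bwlabel(mask)
  out <- matrix(as.integer(EBImage::imageData(labels)),
                nrow(nuclear_channel), ncol(nuclear_channel))
  filter_small_labels(out, min_area)
}

# Euclidean distance of every pixel to the nearest pixel of any labelled
# nucleus (0 inside nuclei).
distance_to_labels <- function(labels) {
  inv <- EBImage::Image(ifelse(labels > 0, 0, 1))
  EBImage::imageData(EBImage::distmap(inv))
}

#' Approximate cell regions from nuclear masks
#'
#' Two modes mirroring the screen's two assays: `"dilate"` expands each
#' nucleus up to `radius` pixels with ties going to the nearest nucleus
#' (used for the free-cholesterol plates); `"propagate"` grows regions
#' from the nuclei over an auxiliary intensity channel within its
#' foreground (used for LDL-uptake arrays). Cell labels preserve nucleus
#' labels, so cell count equals nucleus count.
#'
#' @param nuclei_labels integer label matrix from [segment_nuclei()].
#' @param mode `"dilate"` or `"propagate"`.
#' @param aux_channel intensity matrix guiding propagation (required for
#'   `mode = "propagate"`).
#' @param radius maximum dilation radius in pixels (dilate mode).
#' @param lambda regularization of intensity-guided propagation; large
#'   values approach the purely geometric result.
#' @param fg_threshold foreground threshold on `aux_channel`; default
#'   Otsu.
#' @return integer cell label matrix partitioning the foreground.
#' @export
approximate_cell_regions <- function(nuclei_labels,
                                     mode = c("dilate", "propagate"),
                                     aux_channel = NULL, radius = 25,
                                     lambda = 1e-4, fg_threshold = NULL) {
  mode <- match.arg(mode)
  seeds <- EBImage::Image(nuclei_labels)
  if (max(nuclei_labels) == 0) return(nuclei_labels)
  if (mode == "dilate") {
    d <- distance_to_labels(nuclei_labels)
    mask <- EBImage::Image(ifelse(d <= radius, 1, 0))
    flat <- EBImage::Image(matrix(0, nrow(nuclei_labels),
                                  ncol(nuclei_labels)))
    out <- EBImage::propagate(flat, seeds, mask = mask)
  } else {
    if (is.null(aux_channel))
      stop("mode 'propagate' requires aux_channel")
    x <- EBImage::Image(aux_channel)
    if (is.null(fg_threshold))
      fg_threshold <- EBImage::otsu(x, range = c(0, 1))
    mask <- x > fg_threshold | seeds > 0
    out <- EBImage::propagate(x, seeds, mask = mask, lambda = lambda)
  }
  matrix(as.integer(EBImage::imageData(out)), nrow(nuclei_labels),
         ncol(nuclei_labels))
}
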