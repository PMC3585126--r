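#' Structure detection parameters
#'
#' Parameters of the local adaptive thresholding and the size/shape
#' filters applied to candidate structures. Defaults: 31 px adaptive
#' window, threshold offset 3 robust standard deviations, structure area
#' 4-400 px^2, eccentricity <= 0.95; the free-cholesterol assay restricts
#' detection to a perinuclear ring from the nucleus boundary to +15 px.
#'
#' @param window adaptive window size in pixels (odd, >= 3).
#' @param offset threshold offset in robust-sd units of the window.
#' @param min_area,max_area structure area bounds in px^2.
#' @param max_eccentricity maximum eccentricity (1 = line).
#' @param region `"whole_cell"` or `"perinuclear_ring"`.
#' @param ring `c(inner, outer)` distances in px from the nucleus
#'   boundary delimiting the perinuclear ring.
#' @param min_robust_sd floor on the local robust sd (guards flat,
#'   noise-free windows).
#' @return list of class `"structure_params"`.
#' @export
structure_params <- function(window = 31L, offset = 3, min_area = 4L,
                             max_area = 400L, max_eccentricity = 0.95,
                             region = c("whole_cell", "perinuclear_ring"),
                             ring = c(0, 15), min_robust_sd = 0.002) {
  if (window < 3) stop("adaptive window must be >= 3 px")
  if (window %% 2 == 0) window <- window + 1L
  structure(list(window = as.integer(window), offset = offset,
                 min_area = min_area, max_area = max_area,
                 max_eccentricity = max_eccentricity,
                 region = match.arg(region), ring = ring,
                 min_robust_sd = min_robust_sd),
            class = "structure_params")
}

# local median and local robust sd (1.4826 * median absolute deviation)
# over a square window
local_median_mad <- function(x, window) {
  half <- (window - 1L) %/% 2L
  xi <- EBImage::Image(x)
  m <- EBImage::imageData(EBImage::medianFilter(xi, size = half))
  madv <- EBImage::imageData(
    EBImage::medianFilter(EBImage::Image(pmin(abs(x - m), 1)),
                          size = half)) * 1.4826
  list(median = m, mad = madv)
}

#' Detect intracellular structures by local adaptive thresholding
#'
#' Candidate pixels exceed the local window median by `offset` local
#' robust standard deviations; connected components are filtered by size
#' and shape, clipped to a single cell region, optionally restricted to a
#' perinuclear ring, and each structure is assigned a local background
#' (the median intensity of its window with all structure pixels
#' excluded).
#'
#' @param signal_channel 2-D intensity matrix in `[0, 1]`.
#' @param cell_labels integer cell label matrix
#'   ([approximate_cell_regions()]).
#' @param nuclei_labels nucleus label matrix; required for the perinuclear
#'   restriction.
#' @param params a [structure_params()].
#' @return list: `labels` (structure label matrix), `structures`
#'   (data.frame: `structure_id`, `cell_id`, `area`, `eccentricity`,
#'   `local_bg`, `cx`, `cy`), `pixels` (list of pixel indices per
#'   structure).
#' @export
detect_structures <- function(signal_channel, cell_labels,
                              nuclei_labels = NULL,
                              params = structure_params()) {
  x <- signal_channel
  lm <- local_median_mad(x, params$window)
  thr <- lm$median + params$offset * pmax(lm$mad, params$min_robust_sd)
  mask <- x > thr & cell_labels > 0
  if (params$region == "perinuclear_ring") {
    if (is.null(nuclei_labels))
      stop("perinuclear restriction requires nuclei_labels")
    d <- distance_to_labels(nuclei_labels)
    mask <- mask & nuclei_labels == 0 & d > params$ring[1] &
      d <= params$ring[2]
  }
  empty <- list(labels = matrix(0L, nrow(x), ncol(x)),
                structures = data.frame(structure_id = integer(0),
                                        cell_id = integer(0),
                                        area = integer(0),
                                        eccentricity = numeric(0),
                                        local_bg = numeric(0),
                                        cx = numeric(0), cy = numeric(0)),
                pixels = list())
  if (!any(mask)) return(empty)
  lab <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(mask * 1)))), nrow(x), ncol(x))

  mom <- EBImage::computeFeatures.moment(EBImage::Image(lab),
                                         EBImage::Image(x))
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1,
                                       dimnames = list(NULL, names(mom)))
  pix_by_lab <- split(which(lab > 0), lab[lab > 0])
  keep_id <- integer(0); keep_pix <- list(); cell_of <- integer(0)
  for (id in seq_along(pix_by_lab)) {
    pix <- pix_by_lab[[id]]
    # clip to the majority cell so each structure lies in exactly one cell
    cells <- cell_labels[pix]
    cell <- as.integer(names(which.max(table(cells))))
    pix <- pix[cells == cell]
    a <- length(pix)
    ecc <- mom[id, "m.eccentricity"]
    if (a < params$min_area || a > params$max_area ||
        (is.finite(ecc) && ecc > params$max_eccentricity)) next
    keep_id <- c(keep_id, id)
    keep_pix[[length(keep_pix) + 1L]] <- pix
    cell_of <- c(cell_of, cell)
  }
  if (!length(keep_id)) return(empty)

  out_lab <- matrix(0L, nrow(x), ncol(x))
  for (j in seq_along(keep_pix)) out_lab[keep_pix[[j]]] <- j

  nr <- nrow(x); half <- (params$window - 1L) %/% 2L
  any_mask <- out_lab > 0
  st <- vector("list", length(keep_pix))
  for (j in seq_along(keep_pix)) {
    pix <- keep_pix[[j]]
    rows <- (pix - 1L) %% nr + 1L
    cols <- (pix - 1L) %/% nr + 1L
    cy <- mean(rows); cx <- mean(cols)
    r0 <- max(1L, round(cy) - half); r1 <- min(nr, round(cy) + half)
    c0 <- max(1L, round(cx) - half); c1 <- min(ncol(x), round(cx) + half)
    win <- x[r0:r1, c0:c1]
    winmask <- any_mask[r0:r1, c0:c1]
    bgpix <- win[!winmask]
    bg <- if (length(bgpix)) median(bgpix) else lm$median[round(cy), round(cx)]
    st[[j]] <- data.frame(structure_id = j, cell_id = cell_of[j],
                          area = length(pix),
                          eccentricity = unname(mom[keep_id[j],
                                                    "m.eccentricity"]),
                          local_bg = bg, cx = cx - 1, cy = cy - 1)
  }
  list(labels = out_lab, structures = do.call(rbind, st),
       pixels = keep_pix)
}
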