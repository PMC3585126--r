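#' Plate formats supported by the screen simulator
#'
#' `array_384` (siRNA cell array) and `plate_384` are 16 x 24 grids,
#' `plate_96` is 8 x 12. Rows and columns are 0-based throughout the
#' package.
#'
#' @param format one of `"array_384"`, `"plate_384"`, `"plate_96"`.
#' @return integer vector `c(nrow, ncol)`.
#' @export
plate_dims <- function(format) {
  switch(match.arg(format, c("array_384", "plate_384", "plate_96")),
         array_384 = c(16L, 24L),
         plate_384 = c(16L, 24L),
         plate_96  = c(8L, 12L))
}

#' Plate region of a well
#'
#' Wells at the plate edge are region 1, wells neighbouring an edge well are
#' region 2, and the remainder of the plate is region 3. Regions anchor the
#' plate-effect normalization: deviation values are computed against
#' negative controls of the same region.
#'
#' @param row,col 0-based well coordinates (vectorised).
#' @param dims integer `c(nrow, ncol)` of the plate.
#' @return integer region labels in `{1, 2, 3}`.
#' @export
well_region <- function(row, col, dims) {
  nr <- dims[1]; nc <- dims[2]
  stopifnot(all(row >= 0 & row < nr), all(col >= 0 & col < nc))
  edge  <- row == 0 | row == nr - 1 | col == 0 | col == nc - 1
  ring2 <- row == 1 | row == nr - 2 | col == 1 | col == nc - 2
  ifelse(edge, 1L, ifelse(ring2, 2L, 3L))
}

#' Control-well composition of a screening plate
#'
#' Defaults follow the screening plate design: 16 non-silencing negative
#' controls, mock transfections (3 in the first-pass screen, 8 in the
#' validation screen), 4 INCENP transfection controls, 8 LDLR positive
#' controls for LDL uptake and 8 NPC1 positive controls for free
#' cholesterol.
#'
#' @param n_negative,n_mock,n_positive_ldl,n_positive_fc,n_transfection
#'   number of wells per control role.
#' @return named list of counts, class `"control_spec"`.
#' @export
control_spec <- function(n_negative = 16L, n_mock = 3L, n_positive_ldl = 8L,
                         n_positive_fc = 8L, n_transfection = 4L) {
  if (n_negative < 2L) stop("at least 2 negative-control wells are required")
  structure(list(n_negative = as.integer(n_negative),
                 n_mock = as.integer(n_mock),
                 n_positive_ldl = as.integer(n_positive_ldl),
                 n_positive_fc = as.integer(n_positive_fc),
                 n_transfection = as.integer(n_transfection)),
            class = "control_spec")
}

control_roles <- c("negative_control", "mock", "positive_ldl", "positive_fc",
                   "transfection_control")

#' Generate a screening plate layout
#'
#' Places control wells at seeded pseudo-random positions and fills the
#' remaining positions with candidate siRNAs, assigning each well its
#' plate region (see [well_region()]).
#'
#' @param format plate format, see [plate_dims()].
#' @param candidate_sirnas data.frame with columns `sirna_id` and `gene`
#'   (or a character vector of siRNA ids, genes then `NA`).
#' @param controls a [control_spec()].
#' @param seed integer seed controlling control placement.
#' @param plate_id plate identifier stored in the layout.
#' @return data.frame with columns `plate_id`, `format`, `row`, `col`,
#'   `position_id`, `sirna_id`, `gene`, `role`, `region`; one row per
#'   occupied position.
#' @export
make_plate_layout <- function(format = "plate_384", candidate_sirnas = NULL,
                              controls = control_spec(), seed = 1L,
                              plate_id = "plate1") {
  dims <- plate_dims(format)
  n_pos <- dims[1] * dims[2]
  if (is.character(candidate_sirnas))
    candidate_sirnas <- data.frame(sirna_id = candidate_sirnas,
                                   gene = NA_character_)
  n_cand <- if (is.null(candidate_sirnas)) 0L else nrow(candidate_sirnas)
  n_ctrl <- with(controls, n_negative + n_mock + n_positive_ldl +
                   n_positive_fc + n_transfection)
  if (n_cand + n_ctrl > n_pos)
    stop(sprintf("layout capacity exceeded: %d siRNAs + %d controls > %d positions",
                 n_cand, n_ctrl, n_pos))
  if (!is.null(candidate_sirnas) &&
      anyDuplicated(candidate_sirnas$sirna_id))
    stop("duplicate candidate sirna_id")

  row <- rep(seq_len(dims[1]) - 1L, each = dims[2])
  col <- rep(seq_len(dims[2]) - 1L, times = dims[1])
  position_id <- sprintf("%s%02d", LETTERS[row + 1L], col + 1L)

  roles <- c(rep("negative_control", controls$n_negative),
             rep("mock", controls$n_mock),
             rep("positive_ldl", controls$n_positive_ldl),
             rep("positive_fc", controls$n_positive_fc),
             rep("transfection_control", controls$n_transfection))
  ctrl_sirna <- c(rep("s229174", controls$n_negative),
                  rep("mock", controls$n_mock),
                  rep("s224006", controls$n_positive_ldl),
                  rep("s237198", controls$n_positive_fc),
                  rep("si_INCENP", controls$n_transfection))
  ctrl_gene <- c(rep(NA_character_, controls$n_negative + controls$n_mock),
                 rep("LDLR", controls$n_positive_ldl),
                 rep("NPC1", controls$n_positive_fc),
                 rep("INCENP", controls$n_transfection))

  # negative controls are stratified over the three plate regions (screening
  # plates spread them deliberately so that region normalization is always
  # anchored); remaining controls and candidates are placed at random.
  region_all <- well_region(row, col, dims)
  idx <- with_seed(seed, {
    per_region <- pmax(2L, round(controls$n_negative *
                                   tabulate(region_all, 3) / n_pos))
    while (sum(per_region) > controls$n_negative)
      per_region[which.max(per_region)] <-
        per_region[which.max(per_region)] - 1L
    per_region[3] <- per_region[3] +
      (controls$n_negative - sum(per_region))
    idx_neg <- unlist(lapply(1:3, function(r)
      sample(which(region_all == r), per_region[r])))
    rest <- setdiff(sample.int(n_pos), idx_neg)
    list(neg = idx_neg,
         other_ctrl = rest[seq_len(n_ctrl - controls$n_negative)],
         cand = rest[n_ctrl - controls$n_negative + seq_len(n_cand)])
  })
  idx_ctrl <- c(idx$neg, idx$other_ctrl)
  idx_cand <- idx$cand

  lay <- data.frame(plate_id = plate_id, format = format,
                    row = row, col = col, position_id = position_id,
                    sirna_id = NA_character_, gene = NA_character_,
                    role = NA_character_,
                    region = well_region(row, col, dims),
                    stringsAsFactors = FALSE)
  lay$sirna_id[idx_ctrl] <- ctrl_sirna
  lay$gene[idx_ctrl] <- ctrl_gene
  lay$role[idx_ctrl] <- roles
  if (n_cand > 0L) {
    lay$sirna_id[idx_cand] <- candidate_sirnas$sirna_id
    lay$gene[idx_cand] <- as.character(candidate_sirnas$gene)
    lay$role[idx_cand] <- "candidate"
  }
  lay <- lay[!is.na(lay$role), , drop = FALSE]
  rownames(lay) <- NULL
  stopifnot(!anyDuplicated(lay$position_id))
  lay
}
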