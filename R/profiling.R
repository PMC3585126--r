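fingerprint_parameters <- function() {
  data.frame(assay = c("ldl", "ldl", "ldl", "fc", "fc", "fc", "fc"),
             parameter = c("total", "concentration", "structures",
                           "total", "concentration", "area", "structures"),
             column = c("ldl_total", "ldl_concentration", "ldl_structures",
                        "fc_total", "fc_concentration", "fc_area",
                        "fc_structures"))
}

#' Select a gene's strongest effector siRNAs
#'
#' Ranks the gene's siRNAs by absolute mean deviation on parameter
#' "total", taking for each siRNA the strongest of the two assays; ties
#' break lexicographically by siRNA id.
#'
#' @param gene gene symbol.
#' @param deviations aggregated deviation table (may span assays) with a
#'   `gene` column, or supply `sirna_gene_map`.
#' @param k how many siRNAs to select (default 2).
#' @param sirna_gene_map optional `sirna_id` -> `gene` map.
#' @return character vector of siRNA ids, strongest first; fewer than `k`
#'   with a warning when the gene has fewer scored siRNAs.
#' @export
select_strongest_sirnas <- function(gene, deviations, k = 2L,
                                    sirna_gene_map = NULL) {
  dv <- data.table::as.data.table(deviations)
  if (!is.null(sirna_gene_map))
    dv[, gene := sirna_gene_map$gene[match(sirna_id,
                                           sirna_gene_map$sirna_id)]]
  g <- gene
  dv <- dv[dv$gene == g & dv$parameter == "total" &
             !is.na(dv$mean_deviation)]
  if (!nrow(dv)) stop("gene has no scored siRNAs on parameter 'total'")
  key <- dv[, .(strength = max(abs(mean_deviation))), by = sirna_id]
  data.table::setorder(key, -strength, sirna_id)
  if (nrow(key) < k)
    warning(sprintf("gene %s has %d scored siRNAs (< %d)", g, nrow(key), k))
  head(key$sirna_id, k)
}

#' Build a gene's multiparametric phenotypic fingerprint
#'
#' Matrix of mean deviation values of the gene's two strongest effector
#' siRNAs across the seven phenotypic parameters (LDL total,
#' concentration, structures; FC total, concentration, area, structures),
#' with a per-entry significance flag set by the same thresholds-exceeding
#' rule used for effector calling.
#'
#' @param gene gene symbol.
#' @param deviations aggregated deviation table spanning both assays,
#'   with `gene` (or use `sirna_gene_map`).
#' @param thresholds per-(assay, parameter) threshold table
#'   ([effector_thresholds()]).
#' @param k number of siRNAs (default 2).
#' @param sirna_gene_map optional `sirna_id` -> `gene` map.
#' @return list of class `"fingerprint"`: `gene`, `sirnas`, `matrix`
#'   (siRNA x 7 parameters of mean deviations), `flags` (logical matrix of
#'   threshold exceedance), `directions` (character matrix).
#' @export
build_fingerprint <- function(gene, deviations, thresholds, k = 2L,
                              sirna_gene_map = NULL) {
  dv <- data.table::as.data.table(deviations)
  if (!is.null(sirna_gene_map))
    dv[, gene := sirna_gene_map$gene[match(sirna_id,
                                           sirna_gene_map$sirna_id)]]
  sel <- select_strongest_sirnas(gene, dv, k = k)
  pars <- fingerprint_parameters()
  th <- data.table::as.data.table(thresholds)
  mat <- matrix(NA_real_, length(sel), nrow(pars),
                dimnames = list(sel, pars$column))
  flags <- matrix(FALSE, length(sel), nrow(pars),
                  dimnames = list(sel, pars$column))
  dirs <- matrix("none", length(sel), nrow(pars),
                 dimnames = list(sel, pars$column))
  for (i in seq_along(sel)) {
    for (j in seq_len(nrow(pars))) {
      row <- dv[dv$sirna_id == sel[i] & dv$assay == pars$assay[j] &
                  dv$parameter == pars$parameter[j]]
      if (!nrow(row)) next
      mat[i, j] <- mean(row$mean_deviation)
      trow <- th[th$assay == pars$assay[j] &
                   th$parameter == pars$parameter[j]]
      if (!nrow(trow)) next
      if (mat[i, j] > trow$upper[1]) {
        flags[i, j] <- TRUE; dirs[i, j] <- "increase"
      } else if (mat[i, j] < trow$lower[1]) {
        flags[i, j] <- TRUE; dirs[i, j] <- "decrease"
      }
    }
  }
  structure(list(gene = gene, sirnas = sel, matrix = mat, flags = flags,
                 directions = dirs), class = "fingerprint")
}

#' Classify a fingerprint into a functional group
#'
#' Deterministic sign-pattern rules on the "total" calls of the two
#' strongest siRNAs: significant in both assays with the same sign ->
#' `cocorrelated`; significant on FC only -> `fc_only`; significant in
#' both with opposite signs -> `inverse`; LDL only -> `ldl_only`; no
#' significant "total" entry -> `unclassified`. A direction counts for an
#' assay when at least one of the two siRNAs is flagged on that assay's
#' "total"; conflicting flagged directions within one assay fall back to
#' the direction of the strongest flagged siRNA.
#'
#' @param fingerprint a [build_fingerprint()] result.
#' @return one of `"cocorrelated"`, `"fc_only"`, `"inverse"`,
#'   `"ldl_only"`, `"unclassified"`.
#' @export
classify_functional_group <- function(fingerprint) {
  assay_dir <- function(col) {
    fl <- fingerprint$flags[, col]
    if (!any(fl)) return(0)
    d <- fingerprint$directions[, col][fl]
    d <- ifelse(d == "increase", 1, -1)
    if (length(unique(d)) == 1) d[1] else d[1]  # strongest siRNA is row 1
  }
  ldl <- assay_dir("ldl_total")
  fc <- assay_dir("fc_total")
  if (ldl != 0 && fc != 0) {
    if (ldl == fc) "cocorrelated" else "inverse"
  } else if (fc != 0) "fc_only"
  else if (ldl != 0) "ldl_only"
  else "unclassified"
}

#' Summarize effector genes per GWAS locus
#'
#' Aggregates gene-level hit calls over loci, checking that each gene lies
#' within the stated window of a lead SNP in the annotation.
#'
#' @param gene_calls data.frame from [call_hit_genes()].
#' @param annotation data.frame: `gene`, `locus`, `lead_snp`, `chrom`,
#'   `pos_1based` (lead SNP position), `distance_bp` (gene distance to the
#'   lead SNP).
#' @param window_bp maximum gene-to-lead-SNP distance (closed interval,
#'   default 50000).
#' @return data.frame per locus: `locus`, `lead_snps`, `n_genes_tested`,
#'   `n_effector_genes`, `effector_genes`, `multi_effector`,
#'   `single_prominent_effector`. Genes missing from the annotation are
#'   dropped with a warning; loci without tested genes are excluded.
#' @export
locus_summary <- function(gene_calls, annotation, window_bp = 50000) {
  gc <- data.table::as.data.table(gene_calls)
  an <- data.table::as.data.table(annotation)
  miss <- setdiff(gc$gene, an$gene)
  if (length(miss))
    warning("genes missing from annotation: ", paste(miss, collapse = ", "))
  gc <- merge(gc, an, by = "gene")
  if ("distance_bp" %in% names(gc)) {
    far <- gc$distance_bp > window_bp
    if (any(far)) {
      warning("genes outside the lead-SNP window excluded: ",
              paste(gc$gene[far], collapse = ", "))
      gc <- gc[!far]
    }
  }
  out <- gc[, .(lead_snps = paste(sort(unique(lead_snp)), collapse = ","),
                n_genes_tested = data.table::uniqueN(gene),
                n_effector_genes = data.table::uniqueN(gene[is_hit]),
                effector_genes = paste(sort(unique(gene[is_hit])),
                                       collapse = ",")),
            by = locus]
  out[, multi_effector := n_effector_genes > 1]
  out[, single_prominent_effector := n_effector_genes == 1]
  data.table::setDF(out)
  out
}

#' Export fingerprints as a heatmap matrix
#'
#' Stacks fingerprints into a (gene x siRNA) by parameter matrix ordered
#' by chromosomal position when an annotation is supplied.
#'
#' @param fingerprints list of [build_fingerprint()] results.
#' @param annotation optional annotation with `gene`, `chrom`,
#'   `pos_1based` for chromosomal ordering.
#' @return numeric matrix; rownames `gene:sirna`.
#' @export
fingerprint_matrix <- function(fingerprints, annotation = NULL) {
  if (!is.null(annotation)) {
    ord <- order(match(vapply(fingerprints, `[[`, "", "gene"),
                       annotation$gene[order(annotation$chrom,
                                             annotation$pos_1based)]))
    fingerprints <- fingerprints[ord]
  }
  do.call(rbind, lapply(fingerprints, function(f) {
    m <- f$matrix
    rownames(m) <- paste(f$gene, rownames(m), sep = ":")
    m
  }))
}
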