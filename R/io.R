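#' Read and write the package's CSV tables
#'
#' All tables are UTF-8, comma-separated with a header row. Genomic
#' annotation tables must use 1-based coordinates and carry the columns
#' `gene`, `locus`, `lead_snp`, `chrom`, `pos_1based`, `distance_bp`; a
#' `pos_0based` column is rejected with a convention error.
#'
#' @param path file path.
#' @return data.frame.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_layout <- function(path) {
  lay <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "row", "col", "position_id", "sirna_id", "role",
            "region")
  miss <- setdiff(need, names(lay))
  if (length(miss))
    stop("layout missing columns: ", paste(miss, collapse = ", "))
  dup <- lay$position_id[duplicated(lay$position_id)]
  if (length(dup))
    stop("layout with duplicate position_id: ",
         paste(unique(dup), collapse = ", "))
  lay
}

#' @rdname table_io
#' @param x table to write.
#' @export
write_layout <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_annotation <- function(path) {
  an <- read.csv(path, stringsAsFactors = FALSE)
  if ("pos_0based" %in% names(an))
    stop("annotation uses 0-based coordinates; supply pos_1based")
  need <- c("gene", "locus", "lead_snp", "chrom", "pos_1based")
  miss <- setdiff(need, names(an))
  if (length(miss))
    stop("annotation missing columns: ", paste(miss, collapse = ", "))
  an
}

#' @rdname table_io
#' @export
read_cells <- function(path) {
  cells <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("position_id", "replicate", "image", "total", "concentration",
            "structures")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cell table missing columns: ", paste(miss, collapse = ", "))
  cells
}

#' @rdname table_io
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_table_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)

#' Load and validate a run configuration
#'
#' YAML (or JSON) configuration with top-level sections `paths`, `screen`,
#' `imaging`, `statistics`, `qc`, `seed`. Unknown top-level keys are
#' rejected before any stage runs.
#'
#' @param path YAML/JSON file, or a named list already in memory.
#' @return validated config list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path
    else if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
    else yaml::read_yaml(path)
  allowed <- c("paths", "screen", "imaging", "statistics", "qc", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  scr <- cfg$screen %||% list()
  scr$assay <- scr$assay %||% "fc"
  scr$n_replicates <- as.integer(scr$n_replicates %||% 3L)
  scr$images_per_position <- as.integer(scr$images_per_position %||% 4L)
  scr$format <- scr$format %||% "plate_384"
  scr$n_candidates <- as.integer(scr$n_candidates %||% 100L)
  cfg$screen <- scr
  st <- cfg$statistics %||% list()
  st$error <- st$error %||% "mad"
  st$region_normalize <- st$region_normalize %||% (scr$assay == "fc")
  cfg$statistics <- st
  if (!is.null(cfg$paths$layout) && !file.exists(cfg$paths$layout))
    stop("config error: layout path does not exist: ", cfg$paths$layout)
  structure(cfg, class = "run_config")
}
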