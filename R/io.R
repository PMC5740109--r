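#' Write a probe x sample matrix as TSV
#'
#' Probes become rows with the id in the first column; the header carries the
#' sample ids.
#'
#' @param x Matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the id column (default "probe_id").
#' @export
write_matrix_tsv <- function(x, path, id_col = "probe_id") {
  df <- dplyr::bind_cols(tibble(!!id_col := rownames(x)), as_tibble(x))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a probe x sample TSV back into a matrix
#'
#' @param path TSV written by [write_matrix_tsv()].
#' @param id_col Name of the id column.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path, id_col = "probe_id") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, setdiff(names(df), id_col)])
  rownames(m) <- df[[id_col]]
  m
}

#' Write a study to plain-text files
#'
#' Writes `manifest.tsv`, `beta.tsv`, `control_intensities.tsv`,
#' `samples.csv` and, for synthetic studies, `truth.json` under `dir`.
#'
#' @param study A `meth_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    manifest = file.path(dir, "manifest.tsv"),
    beta = file.path(dir, "beta.tsv"),
    samples = file.path(dir, "samples.csv"))
  readr::write_tsv(study$manifest, paths["manifest"])
  write_matrix_tsv(study$beta, paths["beta"])
  readr::write_csv(study$samples, paths["samples"])
  if (!is.null(study$control_intensities)) {
    paths["control"] <- file.path(dir, "control_intensities.tsv")
    write_matrix_tsv(study$control_intensities, paths["control"])
  }
  if (!is.null(study$truth)) {
    paths["truth"] <- file.path(dir, "truth.json")
    jsonlite::write_json(study$truth, paths["truth"], auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(paths)
}

#' Write DMRs as a BED file
#'
#' Converts the 1-based inclusive region coordinates to BED's 0-based
#' half-open convention at this writer boundary: `bed_start = start - 1`,
#' `bed_end = end`.
#'
#' @param dmr A `dmr_result`.
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmr, path) {
  bed <- tibble(chrom = dmr$chromosome,
                start = dmr$start - 1L,
                end = dmr$end,
                name = dmr$region_id,
                score = round(pmin(1000, -100 * log10(pmax(dmr$q_value,
                                                           1e-10)))),
                strand = ifelse(dmr$direction > 0, "+", "-"))
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
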