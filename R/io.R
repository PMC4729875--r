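# Readers and writers for the pipeline's file formats. Tabular writers
# (TSV, BED) emit '#'-prefixed header lines naming the producing stage and
# seed; readers skip them.

stage_header <- function(stage, seed = NA, config_hash = NULL) {
  c(sprintf("# retrotrace %s stage=%s seed=%s%s",
            as.character(utils::packageVersion("retrotrace")),
            stage, as.character(seed),
            if (is.null(config_hash)) "" else paste0(" config=", config_hash)))
}

#' Write a stage output table
#'
#' Tab-separated with a `#` comment header recording the producing stage and
#' seed. Deterministic: identical tables produce byte-identical files.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param stage Stage name recorded in the header.
#' @param seed Seed recorded in the header.
#' @param config_hash Optional configuration hash for the header.
#' @return `path`, invisibly.
#' @export
write_stage_tsv <- function(df, path, stage = "unknown", seed = NA,
                            config_hash = NULL) {
  writeLines(stage_header(stage, seed, config_hash), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a stage output table
#'
#' @param path Path written by [write_stage_tsv()].
#' @return A tibble.
#' @export
read_stage_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Write a BED file
#'
#' Six-column BED (chrom, start, end, name, score, strand) with a `#`
#' comment header.
#'
#' @inheritParams write_stage_tsv
#' @export
write_bed <- function(df, path, stage = "unknown", seed = NA,
                      config_hash = NULL) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  writeLines(stage_header(stage, seed, config_hash), path)
  readr::write_tsv(df[, cols], path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' @param path BED path (3-6 columns; `#` comments skipped).
#' @return Tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                        show_col_types = FALSE, progress = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score",
                 "strand")[seq_len(ncol(df))]
  df
}

#' Write the toy genome as FASTA
#'
#' @param genome A [simulate_genome()] result.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seq), path)
  invisible(path)
}

#' Read a genome FASTA into a `sim_genome`
#'
#' @param path FASTA path.
#' @param genes Optional gene-model tibble to attach.
#' @return A `sim_genome` (genes empty unless supplied).
#' @export
read_genome_fasta <- function(path, genes = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  structure(list(seq = setNames(as.character(ss), names(ss)),
                 genes = genes %||% tibble(gene_id = character(),
                                           chrom = character(),
                                           start = integer(), end = integer(),
                                           strand = character(),
                                           tss = integer())),
            class = "sim_genome")
}

#' Read or write a pipeline configuration
#'
#' Configurations are plain lists stored as YAML (`.yml`/`.yaml`) or JSON.
#'
#' @param path File path.
#' @return For `read_config()`, the configuration list.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(config, path)
  else jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
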