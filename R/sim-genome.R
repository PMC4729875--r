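# Toy genome generation: random chromosomes plus non-overlapping gene models.

#' Generate a toy genome with gene models
#'
#' Draws random chromosome sequences at the configured GC content and places
#' non-overlapping gene models with random strands. Coordinates are 0-based,
#' half-open; the transcription start site (TSS) is `start` for plus-strand
#' genes and `end - 1` for minus-strand genes.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_genome` with elements `seq` (named character
#'   vector of chromosome sequences) and `genes` (tibble `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `tss`).
#' @export
#' @examples
#' g <- simulate_genome(sim_config(genome_length = 5e4, n_genes = 3))
#' g$genes
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_if(config$seed, {
    chr_len <- floor(config$genome_length / config$n_chromosomes)
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    seqs <- setNames(
      vapply(chroms, function(.) random_dna(chr_len, config$gc_content), character(1)),
      chroms)

    genes <- tibble(gene_id = character(), chrom = character(),
                    start = integer(), end = integer(), strand = character(),
                    tss = integer())
    if (config$n_genes > 0L) {
      placed <- list()
      for (i in seq_len(config$n_genes)) {
        len <- sample_range(config$gene_length_range)
        ok <- FALSE
        for (try in seq_len(1000L)) {
          chrom <- sample(chroms, 1L)
          if (chr_len <= len) next
          start <- sample.int(chr_len - len, 1L) - 1L
          end <- start + len
          prev <- placed[[chrom]]
          if (is.null(prev) || !any(start < prev$end & end > prev$start)) {
            placed[[chrom]] <- bind_rows(prev, tibble(start = start, end = end))
            strand <- sample(c("+", "-"), 1L)
            genes <- bind_rows(genes, tibble(
              gene_id = sprintf("gene%03d", i), chrom = chrom,
              start = start, end = end, strand = strand,
              tss = if (strand == "+") start else end - 1L))
            ok <- TRUE
            break
          }
        }
        if (!ok) abort("gene demand exceeds genome capacity: could not place all genes")
      }
      genes <- arrange(genes, .data$chrom, .data$start)
    }
    structure(list(seq = seqs, genes = genes, gc_content = config$gc_content),
              class = "sim_genome")
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("<sim_genome> %d chromosome(s), %s bases, %d gene(s)\n",
              length(x$seq), format(sum(nchar(x$seq)), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

genome_chrom_lengths <- function(genome) {
  vapply(genome$seq, nchar, integer(1))
}
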