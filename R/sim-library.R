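# Capture-style junction amplicon emission, single-sample libraries and
# multi-sample cohorts.

# Reads for one insertion junction: unique alignment starts jitter uniformly
# within +/- `jitter` of the junction (collision-free, giving the "unique
# amplicon" diversity the >=5 nt separation rule relies on); each unique
# amplicon then gains PCR duplicate copies at the configured rate.
junction_reads <- function(chrom, junction, side, family, elem_offset,
                           insertion_id, sample_id, expected, jitter,
                           read_length, duplicate_rate) {
  n_unique <- min(rpois(1L, expected), 2L * jitter + 1L)
  if (n_unique == 0L) return(NULL)
  offs <- sample(seq(-jitter, jitter), n_unique)
  starts <- junction + offs
  copies <- 1L + rgeom(n_unique, prob = 1 - duplicate_rate)
  idx <- rep(seq_len(n_unique), copies)
  tibble(sample_id = sample_id, chrom = chrom,
         start = starts[idx],
         end = starts[idx] + read_length,
         strand = if (side == "5p") "+" else "-",
         side = side, family = family,
         elem_offset = elem_offset,
         duplicate_group = sprintf("%s_%s_%d", insertion_id, side,
                                   starts[idx]),
         insertion_id = insertion_id)
}

#' Simulate junction amplicon reads for a truth set
#'
#' Emits capture-style 5' and 3' junction amplicons for every truth
#' insertion. The number of unique amplicons per junction is Poisson with
#' mean `depth * vaf` (the insertion's own VAF); alignment starts scatter
#' uniformly within the jitter window; PCR duplicates share a
#' `duplicate_group` id.
#'
#' @param truth Truth tibble from [simulate_truth()].
#' @param config A [sim_config()] (supplies depth, jitter, read length and
#'   duplicate rate).
#' @param sample_id Sample label recorded in the reads.
#' @param seed Integer seed; defaults to `config$seed + 2`.
#' @return Read tibble: `read_id`, `sample_id`, `chrom`, `start`, `end`,
#'   `strand`, `side`, `family`, `elem_offset`, `duplicate_group`,
#'   `insertion_id`.
#' @export
simulate_reads <- function(truth, config, sample_id = "s1",
                           seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  if (any(truth$vaf <= 0 | truth$vaf > 1)) abort("vaf must lie in (0, 1]")
  with_seed_if(seed, {
    out <- purrr::pmap(
      list(truth$chrom, truth$position, truth$tsd_length, truth$family,
           truth$five_prime_start, truth$id, truth$vaf),
      function(chrom, p, tsd_len, family, fps, id, vaf) {
        bind_rows(
          junction_reads(chrom, p, "5p", family, fps, id, sample_id,
                         expected = config$depth * vaf,
                         jitter = config$jitter,
                         read_length = config$read_length,
                         duplicate_rate = config$duplicate_rate),
          junction_reads(chrom, p + tsd_len, "3p", family, fps, id, sample_id,
                         expected = config$depth * vaf,
                         jitter = config$jitter,
                         read_length = config$read_length,
                         duplicate_rate = config$duplicate_rate))
      })
    reads <- bind_rows(out)
    if (nrow(reads) > 0L) {
      reads <- mutate(reads,
                      read_id = sprintf("read%07d", row_number()),
                      .before = 1L)
    }
    reads
  })
}

#' Simulate a complete single-sample library on disk
#'
#' Runs the whole generator (genome, truth set, reads) and writes the
#' standard file set: genome FASTA, gene-model BED, truth table TSV, the
#' known-insertion catalog (BED, germline events only) and the amplicon read
#' table TSV. All tabular writers emit `#`-prefixed header lines naming the
#' producing stage and seed; identical configurations produce byte-identical
#' files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @param sample_id Sample label.
#' @param library A [consensus_library()].
#' @return Invisibly, a list with the in-memory objects (`genome`, `truth`,
#'   `reads`, `catalog`) and a named vector of file `paths`.
#' @export
simulate_library <- function(config, dir, sample_id = "s1",
                             library = consensus_library()) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(config)
  truth <- simulate_truth(genome, config, library = library)
  reads <- simulate_reads(truth, config, sample_id = sample_id)
  catalog <- truth %>%
    filter(.data$germline) %>%
    mutate(end = .data$position + 1L, name = .data$family, score = 0L) %>%
    select("chrom", start = "position", "end", "name", "score", "strand")

  paths <- c(genome = file.path(dir, "genome.fasta"),
             genes = file.path(dir, "genes.bed"),
             truth = file.path(dir, "truth.tsv"),
             catalog = file.path(dir, "catalog.bed"),
             reads = file.path(dir, "reads.tsv"))
  write_genome_fasta(genome, paths[["genome"]])
  write_bed(genome$genes %>%
              mutate(name = .data$gene_id, score = 0L) %>%
              select("chrom", "start", "end", "name", "score", "strand"),
            paths[["genes"]], stage = "simulate", seed = config$seed)
  write_stage_tsv(select(truth, -"insert_seq"), paths[["truth"]],
                  stage = "simulate", seed = config$seed)
  write_bed(catalog, paths[["catalog"]], stage = "simulate", seed = config$seed)
  write_stage_tsv(reads, paths[["reads"]], stage = "simulate", seed = config$seed)
  invisible(list(genome = genome, truth = truth, reads = reads,
                 catalog = catalog, paths = paths))
}

#' Simulate a multi-sample cohort with labelled inheritance classes
#'
#' Plants one truth set and distributes each insertion over the samples of a
#' cohort design according to a sampled inheritance class:
#' * `germline_shared` - present in every sample (donor-independent
#'   polymorphism, the bulk of real non-reference insertions); a
#'   `catalog_fraction` of these is also written to the known-insertion
#'   catalog;
#' * `parental_private` - present in one line's parental sample and all its
#'   derived pluripotent samples;
#' * `pluripotent_private` - a true de novo event: present from one
#'   pluripotent passage of one line onwards (and absent from its parental
#'   sample and every other line).
#'
#' @param config A [sim_config()].
#' @param design A [cohort_design()].
#' @param class_probs Probabilities of the three classes, in the order
#'   above.
#' @param catalog_fraction Fraction of germline-shared insertions present in
#'   the catalog.
#' @param library A [consensus_library()].
#' @param seed Integer seed; defaults to `config$seed + 3`.
#' @return List: `genome`, `truth` (with `class` column), `presence`
#'   (tibble `id` x `sample_id`), `reads` (all samples), `catalog`,
#'   `design`.
#' @export
simulate_cohort <- function(config, design,
                            class_probs = c(germline_shared = 0.6,
                                            parental_private = 0.2,
                                            pluripotent_private = 0.2),
                            catalog_fraction = 0.7,
                            library = consensus_library(),
                            seed = config$seed + 3L) {
  stopifnot(inherits(design, "cohort_design"))
  genome <- simulate_genome(config)
  truth <- simulate_truth(genome, config, library = library)
  with_seed_if(seed, {
    classes <- sample(names(class_probs), nrow(truth), replace = TRUE,
                      prob = class_probs)
    truth$class <- classes
    truth$germline <- classes == "germline_shared"
    truth$vaf <- ifelse(truth$germline, 1, truth$vaf)

    pluri <- design[design$role != "parental", ]
    lines_with_parental <- unique(design$line[design$role == "parental"])
    if (any(classes == "parental_private") && length(lines_with_parental) == 0L) {
      abort("parental_private insertions require at least one parental sample")
    }
    presence <- purrr::map_dfr(seq_len(nrow(truth)), function(i) {
      cls <- classes[i]
      samples <- if (cls == "germline_shared") {
        design$sample_id
      } else if (cls == "parental_private") {
        ln <- sample(lines_with_parental, 1L)
        design$sample_id[design$line == ln]
      } else {
        # a de novo event must arise late enough to be distinguishable: in a
        # line without a parental sample it cannot predate the earliest
        # surveyed passage
        ln <- sample(unique(pluri$line), 1L)
        sub <- pluri[pluri$line == ln, ]
        eligible <- if (ln %in% lines_with_parental) sub$passage
                    else sub$passage[sub$passage > min(sub$passage)]
        if (length(eligible) == 0L) eligible <- max(sub$passage)
        from <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
        sub$sample_id[sub$passage >= from]
      }
      tibble(id = truth$id[i], sample_id = samples)
    })

    in_catalog <- truth$germline & runif(nrow(truth)) < catalog_fraction
    catalog <- truth[in_catalog, ] %>%
      mutate(end = .data$position + 1L, name = .data$family, score = 0L) %>%
      select("chrom", start = "position", "end", "name", "score", "strand")

    reads <- purrr::map_dfr(design$sample_id, function(sid) {
      ids <- presence$id[presence$sample_id == sid]
      simulate_reads(truth[truth$id %in% ids, ], config, sample_id = sid,
                     seed = NULL)
    })
    list(genome = genome, truth = truth, presence = presence, reads = reads,
         catalog = catalog, design = design)
  })
}
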