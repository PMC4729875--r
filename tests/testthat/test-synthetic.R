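# Synthetic-data generator: genome, site selection, planting, read emission.

test_that("genome generation respects configuration and is deterministic", {
  cfg0 <- sim_config(genome_length = 5e4, n_genes = 0, seed = 3)
  g0 <- simulate_genome(cfg0)
  expect_equal(nrow(g0$genes), 0L)
  expect_equal(unname(nchar(g0$seq)), rep(25000L, 2))

  # identical config => byte-identical FASTA
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_genome_fasta(simulate_genome(cfg0), file.path(d1, "g.fasta"))
  write_genome_fasta(simulate_genome(cfg0), file.path(d2, "g.fasta"))
  expect_identical(readLines(file.path(d1, "g.fasta")),
                   readLines(file.path(d2, "g.fasta")))

  # GC content within 3 sd of the binomial expectation
  cfg1 <- sim_config(genome_length = 1e5, n_chromosomes = 1, n_genes = 0,
                     gc_content = 0.5, seed = 4)
  g1 <- simulate_genome(cfg1)
  gc <- sum(strsplit(g1$seq[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5 * 1e5), 3 * sqrt(1e5 * 0.25))

  # genes stay within bounds and TSS follows strand
  expect_true(all(fix_genome$genes$start >= 0))
  expect_true(all(fix_genome$genes$end <= nchar(fix_genome$seq[fix_genome$genes$chrom])))
  expect_equal(fix_genome$genes$tss,
               ifelse(fix_genome$genes$strand == "+",
                      fix_genome$genes$start, fix_genome$genes$end - 1L))
})

test_that("gene demand beyond genome capacity errors", {
  expect_error(sim_config(genome_length = 1e4, n_genes = 50,
                          gene_length_range = c(5e3, 5e3)),
               "capacity")
})

test_that("integration site selection honours the endonuclease motif", {
  # a genome with exactly one motif occurrence must return that site
  base <- strrep("C", 200)
  seq1 <- paste0(substr(base, 1, 100), "TTTTAA", strrep("G", 194))
  g <- structure(list(seq = c(chr1 = seq1),
                      genes = fix_genome$genes[0, ]), class = "sim_genome")
  site <- select_integration_site(g, en_dependent = TRUE, margin = 10, seed = 1)
  expect_equal(site$position, 100 + 4)
  expect_equal(site$motif_context, "TTTTAA")

  # motif on the bottom strand (top reads TTAAAA) is also found
  seq2 <- paste0(substr(base, 1, 100), "TTAAAA", strrep("G", 194))
  g2 <- structure(list(seq = c(chr1 = seq2),
                       genes = fix_genome$genes[0, ]), class = "sim_genome")
  site2 <- select_integration_site(g2, en_dependent = TRUE, margin = 10, seed = 1)
  expect_equal(site2$motif_context, "TTAAAA")

  # exhaustion error when nothing qualifies
  g3 <- structure(list(seq = c(chr1 = strrep("CG", 200)),
                       genes = fix_genome$genes[0, ]), class = "sim_genome")
  expect_error(select_integration_site(g3, en_dependent = TRUE, margin = 10),
               "no endonuclease")
})

test_that("budgeted site selection agrees with an exhaustive 6-mer scan", {
  cfg <- sim_config(genome_length = 1e4, n_chromosomes = 1, n_genes = 0, seed = 9)
  g <- simulate_genome(cfg)
  chars <- strsplit(g$seq[[1]], "")[[1]]
  oracle_mm <- function(p) {
    ctx <- paste(chars[(p - 3):(p + 2)], collapse = "")  # 0-based [p-4, p+2)
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(ctx, "")[[1]]), collapse = ""))
    min(sum(strsplit(ctx, "")[[1]] != strsplit("TTTTAA", "")[[1]]),
        sum(strsplit(rc, "")[[1]] != strsplit("TTTTAA", "")[[1]]))
  }
  for (s in 1:20) {
    site <- select_integration_site(g, en_dependent = TRUE,
                                    mismatch_budget = 1, seed = s)
    expect_lte(oracle_mm(site$position), 1)
  }
  # endonuclease-independent sites carry no mismatch annotation
  site <- select_integration_site(g, en_dependent = FALSE, seed = 2)
  expect_true(is.na(site$mismatches))
})

test_that("planting reproduces the documented haplotype layout", {
  spec <- family_spec("Alu", full_length_fraction = 1,
                      polya_length_range = c(10, 10),
                      untemplated_nt_probability = 0, en_independent_fraction = 0)
  site <- select_integration_site(fix_genome, en_dependent = FALSE, seed = 5)
  res <- plant_insertion(fix_genome, spec, site, library = fix_library,
                         subfamily = "AluYa5", tsd_length = 0, seed = 6)
  cons_len <- nchar(retrotrace:::consensus_of(fix_library, "AluYa5"))
  expect_equal(nchar(res$haplotype),
               nchar(fix_genome$seq[[site$chrom]]) + cons_len + 10)
  expect_equal(res$truth$tsd, "")

  # untemplated G nucleotides sit between the first TSD copy and the element
  spec_g <- family_spec("L1", full_length_fraction = 1,
                        untemplated_nt_probability = 1,
                        en_independent_fraction = 0)
  found_gg <- FALSE
  for (s in 1:20) {
    r <- plant_insertion(fix_genome, spec_g, site, library = fix_library,
                         subfamily = "L1-Ta", tsd_length = 6, seed = s)
    if (r$truth$untemplated_5p == "GG") {
      found_gg <- TRUE
      cons <- retrotrace:::consensus_of(fix_library, "L1-Ta")
      cassette <- if (site$strand == "+") r$truth$insert_seq
                  else retrotrace:::revcomp(r$truth$insert_seq)
      expect_true(grepl(paste0(r$truth$tsd, cassette,
                               r$truth$tsd), r$haplotype, fixed = TRUE))
      expect_true(startsWith(r$truth$insert_seq,
                             paste0("GG", substr(cons, 1, 20))))
      break
    }
  }
  expect_true(found_gg)
})

test_that("endonuclease-independent truncated events still carry a TSD", {
  spec <- family_spec("L1", full_length_fraction = 1, en_independent_fraction = 1,
                      untemplated_nt_probability = 0)
  spec$force_three_prime_truncation <- TRUE
  site <- select_integration_site(fix_genome, en_dependent = FALSE, seed = 8)
  r <- plant_insertion(fix_genome, spec, site, library = fix_library,
                       subfamily = "L1-Ta", tsd_length = 8, seed = 9)
  expect_false(r$truth$en_dependent)
  expect_equal(r$truth$tsd_length, 8L)
  expect_true(r$truth$three_prime_truncated)
})

test_that("amplicon counts per junction follow the configured depth", {
  cfg <- sim_config(genome_length = 4e5, n_genes = 0, depth = 20, vaf = 1,
                    duplicate_rate = 0, germline_fraction = 0, seed = 13,
                    families = list(family_spec("Alu", n = 100)))
  g <- simulate_genome(cfg)
  tr <- simulate_truth(g, cfg)
  rd <- simulate_reads(tr, cfg)
  per_junction <- dplyr::count(rd, insertion_id, side)
  # Poisson(20) mean over 200 junctions: tolerance 4 standard errors
  expect_lt(abs(mean(per_junction$n) - 20), 4 * sqrt(20 / nrow(per_junction)))
  # no duplicates configured => every duplicate group is a singleton
  expect_true(all(dplyr::count(rd, duplicate_group)$n == 1))
})

test_that("read emission is deterministic and validates VAF", {
  r1 <- simulate_reads(fix_truth, fix_config, seed = 77)
  r2 <- simulate_reads(fix_truth, fix_config, seed = 77)
  expect_identical(r1, r2)
  bad <- fix_truth
  bad$vaf[1] <- 0
  expect_error(simulate_reads(bad, fix_config), "vaf")
})

test_that("truth and catalog partition the insertion set", {
  dir <- withr::local_tempdir()
  sim <- simulate_library(sim_config(genome_length = 2e5, n_genes = 3, seed = 5,
                                     families = list(family_spec("Alu", n = 20))),
                          dir)
  truth <- read_stage_tsv(sim$paths[["truth"]])
  catalog <- read_bed(sim$paths[["catalog"]])
  germline_ids <- truth$id[truth$germline]
  expect_equal(nrow(catalog), length(germline_ids))
  expect_equal(sort(truth$id), sort(unique(truth$id)))
  # every catalog position is a germline truth position, never a de novo one
  expect_true(all(catalog$start %in% truth$position[truth$germline]))
  expect_false(any(catalog$start %in% truth$position[!truth$germline]))
})
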