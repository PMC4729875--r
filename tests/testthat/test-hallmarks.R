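# TPRT hallmark annotation.

test_that("TSD detection finds the longest suffix-prefix match", {
  expect_equal(detect_tsd("ACGTGGAT", "GGATTTCA"), "GGAT")
  expect_equal(detect_tsd("ACGTGGAT", "CCCCTTCA"), "")
  # cap at max_tsd
  expect_equal(nchar(detect_tsd(strrep("A", 40), strrep("A", 40), max_tsd = 30)), 30)
  # blunt case is an empty string, never an error
  expect_equal(detect_tsd("", "ACGT"), "")
})

test_that("endonuclease motif scoring matches a both-strand Hamming oracle", {
  expect_equal(score_en_motif("TTTTAA")$mismatches, 0L)
  expect_equal(score_en_motif("TTTCAA")$mismatches, 1L)
  expect_true(is.na(score_en_motif("TTT")$mismatches))

  bases <- c("A", "C", "G", "T")
  all6 <- expand.grid(b1 = bases, b2 = bases, b3 = bases, b4 = bases,
                      b5 = bases, b6 = bases, stringsAsFactors = FALSE)
  ctxs <- apply(all6, 1, paste, collapse = "")
  oracle <- function(ctx) {
    f <- strsplit(ctx, "")[[1]]
    r <- rev(chartr("ACGT", "TGCA", f))
    m <- strsplit("TTTTAA", "")[[1]]
    min(sum(f != m), sum(r != m))
  }
  got <- vapply(ctxs, function(c) score_en_motif(c)$mismatches, integer(1))
  expect_equal(unname(got), vapply(ctxs, oracle, numeric(1), USE.NAMES = FALSE))

  # strand symmetry: reverse complement never changes the score
  some <- ctxs[seq(1, 4096, by = 97)]
  for (ctx in some) {
    expect_equal(score_en_motif(retrotrace:::revcomp(ctx))$mismatches,
                 score_en_motif(ctx)$mismatches)
  }
})

test_that("poly-A measurement applies the interruption rule", {
  expect_equal(measure_polya("GCAAAAAA"), 6L)
  expect_equal(measure_polya("GCAAAAAG"), 0L)
  expect_equal(measure_polya(""), 0L)
  # a single interruption is tolerated once 20 bases are consumed
  expect_equal(measure_polya(paste0("AAAA", "G", strrep("A", 25))), 30L)
  # but not before
  expect_equal(measure_polya(paste0("AAAA", "G", strrep("A", 10))), 10L)
})

test_that("structure classification reports planted hallmarks", {
  spec <- family_spec("L1", full_length_fraction = 0, twin_priming_fraction = 1,
                      untemplated_nt_probability = 0, en_independent_fraction = 0)
  site <- select_integration_site(fix_genome, en_dependent = FALSE, seed = 31)
  r <- plant_insertion(fix_genome, spec, site, library = fix_library,
                       subfamily = "L1-Ta", vaf = 1, seed = 32)
  trip <- insertion_triplets(fix_genome, r$truth)
  rep <- classify_structure(trip$left_flank, trip$insert, trip$right_flank,
                            family = "L1", library = fix_library)
  expect_true(rep$inversion)
  expect_equal(rep$spacer_length, 25L)
  expect_equal(rep$five_prime_start, r$truth$five_prime_start)
  expect_equal(rep$inversion_breakpoint, r$truth$inversion_breakpoint)
  expect_false(rep$full_length)

  # full-length, no hallmark extras
  spec2 <- family_spec("Alu", full_length_fraction = 1,
                       untemplated_nt_probability = 0, en_independent_fraction = 0)
  r2 <- plant_insertion(fix_genome, spec2, site, library = fix_library,
                        subfamily = "AluYb8", seed = 33)
  trip2 <- insertion_triplets(fix_genome, r2$truth)
  rep2 <- classify_structure(trip2$left_flank, trip2$insert, trip2$right_flank,
                             family = "Alu", library = fix_library)
  expect_true(rep2$full_length)
  expect_equal(rep2$five_prime_start, 0L)
  expect_equal(rep2$subfamily, "AluYb8")
  expect_equal(rep2$tsd, r2$truth$tsd)

  # unalignable insert reports structure as unknown but still finds the TSD
  junk <- classify_structure(trip2$left_flank, strrep("ACGT", 10),
                             trip2$right_flank, family = "Alu",
                             library = fix_library)
  expect_false(junk$aligned)
  expect_equal(junk$tsd, r2$truth$tsd)
})

test_that("microcomplementarity is mutually exclusive with untemplated bases", {
  # construct a truncated insertion whose flank suffix equals the consensus
  # bases just 5' of the truncation point
  cons <- retrotrace:::consensus_of(fix_library, "AluYa5")
  # pick a truncation point whose preceding consensus base is not G, so the
  # untemplated GG below cannot be absorbed into the body alignment
  t0 <- 60L
  while (substr(cons, t0, t0) == "G") t0 <- t0 + 1L
  micro <- substr(cons, t0 - 2L, t0)  # consensus bases just 5' of the cut
  left <- paste0(strrep("C", 47), micro)
  right <- paste0("GGTT", strrep("C", 46))
  insert <- paste0(substring(cons, t0 + 1L), strrep("A", 20))
  rep <- classify_structure(left, insert, right, family = "Alu",
                            library = fix_library)
  expect_equal(rep$five_prime_start, t0)
  expect_gte(rep$microcomplementarity, 3L)
  expect_equal(rep$untemplated_5p, "")

  # with untemplated bases present, microcomplementarity is not reported
  insert_u <- paste0("GG", substring(cons, t0 + 1L), strrep("A", 20))
  rep_u <- classify_structure(left, insert_u, right, family = "Alu",
                              library = fix_library)
  expect_equal(rep_u$untemplated_5p, "GG")
  expect_true(is.na(rep_u$microcomplementarity))
})

test_that("hallmark round trip is exact on a noise-free simulated batch", {
  # a 60-event mixed batch; the full 500-event check runs in the acceptance
  # suite
  cfg <- sim_config(genome_length = 4e5, n_genes = 0, seed = 51,
                    families = list(family_spec("L1", n = 25),
                                    family_spec("Alu", n = 25),
                                    family_spec("SVA", n = 10)))
  g <- simulate_genome(cfg)
  tr <- simulate_truth(g, cfg, library = fix_library)
  hm <- annotate_hallmarks(insertion_triplets(g, tr), library = fix_library)
  j <- dplyr::left_join(tr, hm, by = "id", suffix = c(".t", ".h"))
  # recovery is exact up to genuine sequence ambiguities (e.g. a homopolymer
  # TSD whose boundary cannot be placed uniquely); tolerate at most one such
  # event per field in this 60-event batch
  recovered <- function(f) mean(j[[paste0(f, ".t")]] == j[[paste0(f, ".h")]])
  for (f in c("tsd", "tsd_length", "polya_length", "five_prime_start",
              "inversion", "untemplated_5p", "subfamily", "strand")) {
    expect_gte(recovered(f), 59 / 60)
  }
})
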