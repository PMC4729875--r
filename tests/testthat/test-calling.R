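# Junction calling: duplicate collapse, clustering, thresholds, family
# assignment, catalog matching.

test_that("duplicate collapse matches a brute-force distinct-key count", {
  ten <- tibble::tibble(sample_id = "s1", chrom = "chr1", start = 500L,
                        side = "5p", family = "L1")[rep(1, 10), ]
  u <- collapse_duplicates(ten)
  expect_equal(nrow(u), 1L)
  expect_equal(u$multiplicity, 10L)

  two <- tibble::tibble(sample_id = "s1", chrom = "chr1",
                        start = c(500L, 501L), side = "5p", family = "L1")
  expect_equal(nrow(collapse_duplicates(two)), 2L)

  rnd <- random_read_table(300, seed = 10)
  u <- collapse_duplicates(rnd)
  # nested-loop oracle: count rows with no earlier identical key
  keys <- paste(rnd$sample_id, rnd$chrom, rnd$start, rnd$side, rnd$family)
  oracle <- sum(vapply(seq_along(keys), function(i) {
    !any(keys[seq_len(i - 1L)] == keys[i])
  }, logical(1)))
  expect_equal(nrow(u), oracle)
  expect_equal(sum(u$multiplicity), nrow(rnd))
})

test_that("clustering is single linkage and matches the O(n^2) closure", {
  mk <- function(starts) tibble::tibble(
    sample_id = "s1", chrom = "chr1", start = starts, side = "5p",
    family = "L1", multiplicity = 1L)
  expect_equal(length(unique(cluster_amplicons(mk(c(1000, 1400)), 200)$cluster_id)), 2L)
  # chain with gaps 150,150 merges under window 200 by transitivity
  expect_equal(length(unique(cluster_amplicons(mk(c(1000, 1150, 1300)), 200)$cluster_id)), 1L)
  expect_error(cluster_amplicons(mk(1000), window = -1), "non-negative")

  rnd <- collapse_duplicates(random_read_table(200, seed = 11))
  cl <- cluster_amplicons(rnd, window = 60)
  oc <- oracle_clusters(cl, 60)
  # identical partitions: pairwise co-membership agrees
  pairs <- utils::combn(nrow(cl), 2)
  same_pkg <- cl$cluster_id[pairs[1, ]] == cl$cluster_id[pairs[2, ]]
  same_orc <- oc[pairs[1, ]] == oc[pairs[2, ]]
  expect_identical(same_pkg, same_orc)
})

test_that("the reporting threshold needs two unique amplicons >= 5 nt apart", {
  mk <- function(starts, mult = 1L) tibble::tibble(
    sample_id = "s1", chrom = "chr1", start = starts, side = "5p",
    family = "L1", multiplicity = mult) |> cluster_amplicons()
  expect_equal(nrow(call_insertions(mk(c(1000, 1005)))), 1L)  # separation 5: reported
  expect_equal(nrow(call_insertions(mk(c(1000, 1004)))), 0L)  # separation 4: not
  expect_equal(nrow(call_insertions(mk(1000, mult = 50L))), 0L)  # duplicates don't count
})

test_that("calls are invariant to read-order permutation", {
  shuffled <- fix_reads[withr::with_seed(5, sample.int(nrow(fix_reads))), ]
  c1 <- call_junctions(fix_reads)
  c2 <- call_junctions(shuffled)
  expect_equal(dplyr::select(c1, -call_id), dplyr::select(c2, -call_id))
})

test_that("caller recovers planted insertions with no false positives", {
  calls <- call_junctions(fix_reads)
  hit <- vapply(seq_len(nrow(fix_truth)), function(i) {
    any(calls$chrom == fix_truth$chrom[i] &
          calls$family == fix_truth$family[i] &
          abs(calls$junction - fix_truth$position[i]) <= 200)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
  clean <- vapply(seq_len(nrow(calls)), function(i) {
    any(fix_truth$chrom == calls$chrom[i] &
          abs(calls$junction[i] - fix_truth$position) <= 230)
  }, logical(1))
  expect_true(all(clean))
})

test_that("recall does not increase as VAF decreases", {
  recall_at <- function(vaf, seed) {
    cfg <- sim_config(genome_length = 3e5, n_genes = 0, depth = 10, vaf = vaf,
                      germline_fraction = 0, seed = seed,
                      families = list(family_spec("Alu", n = 40)))
    g <- simulate_genome(cfg)
    tr <- simulate_truth(g, cfg)
    calls <- call_junctions(simulate_reads(tr, cfg))
    mean(vapply(seq_len(nrow(tr)), function(i) {
      any(calls$chrom == tr$chrom[i] & abs(calls$junction - tr$position[i]) <= 200)
    }, logical(1)))
  }
  highs <- vapply(1:3, function(s) recall_at(1, s), numeric(1))
  lows <- vapply(1:3, function(s) recall_at(0.05, s), numeric(1))
  expect_gte(mean(highs), mean(lows))
})

test_that("family majority vote and diagnostic subfamily assignment work", {
  expect_equal(assign_family_subfamily(c("L1", "L1", "Alu"),
                                       library = fix_library)$family, "L1")
  expect_error(assign_family_subfamily("LINEX", library = fix_library), "unknown")
  # no sequence => subfamily unresolved for multi-subfamily families
  expect_equal(assign_family_subfamily("Alu", library = fix_library)$subfamily,
               "unresolved")
  # single-subfamily families resolve without sequence
  expect_equal(assign_family_subfamily("SVA", library = fix_library)$subfamily,
               "SVA_E")

  # simulated subfamily round trip via the planted sequence
  for (sub in c("AluYa5", "AluYb8", "L1-Ta", "L1-preTa")) {
    fam <- retrotrace:::family_of(fix_library, sub)
    seq <- retrotrace:::consensus_of(fix_library, sub)
    got <- assign_family_subfamily(fam, sequence = seq, five_prime_start = 0,
                                   library = fix_library)
    expect_equal(got$subfamily, sub)
  }
  # a sequence matching both subfamilies equally ties to unresolved:
  # truncate away every diagnostic position
  diags <- attr(fix_library, "diagnostics")
  cut <- max(diags$position[diags$subfamily == "AluYa5"]) + 1L
  seq <- substring(retrotrace:::consensus_of(fix_library, "AluYa5"), cut + 1L)
  got <- assign_family_subfamily("Alu", sequence = seq, five_prime_start = cut,
                                 library = fix_library)
  expect_equal(got$subfamily, "unresolved")
})

test_that("catalog matching respects window, family and malformed records", {
  calls <- tibble::tibble(call_id = "c1", sample_id = "s1", chrom = "chr1",
                          family = "L1", junction = 1000L)
  cat_exact <- tibble::tibble(chrom = "chr1", start = 1000L, family = "L1")
  expect_equal(match_catalog(calls, cat_exact)$catalog_status, "known")
  cat_fam <- tibble::tibble(chrom = "chr1", start = 1000L, family = "Alu")
  expect_equal(match_catalog(calls, cat_fam)$catalog_status, "novel")
  cat_100 <- tibble::tibble(chrom = "chr1", start = 1100L, family = "L1")
  expect_equal(match_catalog(calls, cat_100)$catalog_status, "known")
  cat_101 <- tibble::tibble(chrom = "chr1", start = 1101L, family = "L1")
  expect_equal(match_catalog(calls, cat_101)$catalog_status, "novel")
  cat_bad <- tibble::tibble(chrom = c("chr1", NA), start = c(1101L, NA),
                            family = "L1")
  expect_warning(out <- match_catalog(calls, cat_bad), "malformed")
  expect_equal(out$catalog_status, "novel")
})
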