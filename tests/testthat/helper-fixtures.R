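# Shared fixtures, built once per test run. Sizes are kept small: genomes of
# a few hundred kilobases and tens of insertions exercise every code path.

fix_library <- consensus_library()

fix_config <- sim_config(
  genome_length = 3e5, n_genes = 8, seed = 42,
  families = list(family_spec("L1", n = 15), family_spec("Alu", n = 15)))

fix_genome <- simulate_genome(fix_config)
fix_truth <- simulate_truth(fix_genome, fix_config, library = fix_library)
fix_reads <- simulate_reads(fix_truth, fix_config)

# a cohort with two hiPSC lines (parental + two passages each) and one hESC
# line (two passages)
fix_design <- cohort_design(tibble::tibble(
  sample_id = c("fibA", "ipsA_p20", "ipsA_p40",
                "fibB", "ipsB_p20", "ipsB_p40",
                "esc_p10", "esc_p30"),
  line = c("A", "A", "A", "B", "B", "B", "E", "E"),
  role = c("parental", "hiPSC", "hiPSC",
           "parental", "hiPSC", "hiPSC", "hESC", "hESC"),
  passage = c(0, 20, 40, 0, 20, 40, 10, 30)))

# two tiny gene models used by the positional-bias tests
genes2 <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                         start = c(0L, 1000L), end = c(100L, 1200L),
                         strand = c("+", "-"))

# deterministic random read table for oracle comparisons
random_read_table <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    sample_id = "s1",
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample.int(3000L, n, replace = TRUE),
    side = sample(c("5p", "3p"), n, replace = TRUE),
    family = sample(c("L1", "Alu"), n, replace = TRUE)))
}

# brute-force single-linkage transitive closure over starts (O(n^2))
oracle_clusters <- function(df, window) {
  n <- nrow(df)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (comp[i] != comp[j] &&
          df$chrom[i] == df$chrom[j] && df$family[i] == df$family[j] &&
          df$sample_id[i] == df$sample_id[j] &&
          abs(df$start[i] - df$start[j]) <= window) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}
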