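# Planting retrotransposon insertions with TPRT hallmarks.
#
# Coordinate convention: 0-based, half-open; the insertion point `position`
# is the index of the first base of the 3' flank. The modified haplotype is
#   genome[0, position + tsd_length) | cassette | genome[position, ...)
# so the target site duplication appears once at the end of the left flank
# and once at the start of the right flank. The cassette (element
# orientation) is
#   [untemplated nts][inverted 5' segment + spacer][body from five_prime_start][poly-A]
# and is reverse-complemented when the element integrates on the minus
# strand.
#
# Junctions are emitted unambiguously by construction: truncation points,
# spacer termini and untemplated bases are resampled so that no junction base
# could equally be attributed to the neighbouring segment. This makes exact
# structural recovery a well-posed round trip (see the methods vignette).

EN_MOTIF <- "TTTTAA"  # L1 endonuclease target, written 5'-TTTT/AA-3'

# Scan a genome for endonuclease-motif sites on both strands.
# Returns 0-based insertion points p with the stored 6-mer context
# genome[p-4, p+2); the cleavage position sits between context positions 4
# and 5 on the strand that reads TTTT/AA.
scan_en_sites <- function(genome, mismatch_budget = 0L, margin = 250L) {
  bottom <- revcomp(EN_MOTIF)  # top-strand spelling of a bottom-strand motif
  out <- lapply(names(genome$seq), function(chrom) {
    x <- strsplit(genome$seq[[chrom]], "")[[1]]
    n <- length(x)
    if (n < 6L) return(NULL)
    idx <- seq_len(n - 5L)
    mm_top <- integer(n - 5L)
    mm_bot <- integer(n - 5L)
    for (j in 1:6) {
      mm_top <- mm_top + (x[idx + j - 1L] != substr(EN_MOTIF, j, j))
      mm_bot <- mm_bot + (x[idx + j - 1L] != substr(bottom, j, j))
    }
    pos <- idx + 3L  # 0-based insertion point = context position 4/5 boundary
    keep_top <- mm_top <= mismatch_budget
    keep_bot <- mm_bot <= mismatch_budget
    res <- bind_rows(
      tibble(chrom = chrom, position = pos[keep_top], strand = "+",
             mismatches = mm_top[keep_top]),
      tibble(chrom = chrom, position = pos[keep_bot], strand = "-",
             mismatches = mm_bot[keep_bot]))
    res <- res[res$position >= margin & res$position <= n - margin, , drop = FALSE]
    res
  })
  sites <- bind_rows(out)
  if (nrow(sites) > 0L) {
    sites <- sites %>%
      arrange(.data$chrom, .data$position, .data$mismatches) %>%
      distinct(.data$chrom, .data$position, .keep_all = TRUE)
    sites$context <- mapply(function(ch, p) substr0(genome$seq[[ch]], p - 4L, p + 2L),
                            sites$chrom, sites$position, USE.NAMES = FALSE)
  } else {
    sites$context <- character()
  }
  as_tibble(sites)
}

#' Select an integration site
#'
#' Picks a genomic site for an insertion. Endonuclease-dependent events land
#' at positions whose 6-mer cleavage context matches the L1 endonuclease
#' target motif 5'-TTTT/AA-3' within `mismatch_budget` mismatches on either
#' strand; endonuclease-independent events (integration at preexisting DNA
#' lesions) are placed uniformly at random.
#'
#' @param genome A [simulate_genome()] result.
#' @param en_dependent Should the site match the endonuclease motif?
#' @param mismatch_budget Maximum Hamming distance to the motif for
#'   endonuclease-dependent sites.
#' @param margin Minimum distance (bases) from chromosome ends.
#' @param sites Optional precomputed [scan_en_sites()] table, to avoid
#'   rescanning when placing many insertions.
#' @param seed Optional integer seed.
#'
#' @return A one-row tibble: `chrom`, `position` (0-based insertion point),
#'   `strand`, `motif_context` (the 6-mer `genome[p-4, p+2)`), `mismatches`.
#' @export
select_integration_site <- function(genome, en_dependent = TRUE,
                                    mismatch_budget = 0L, margin = 250L,
                                    sites = NULL, seed = NULL) {
  stopifnot(inherits(genome, "sim_genome"))
  with_seed_if(seed, {
    if (en_dependent) {
      if (is.null(sites)) sites <- scan_en_sites(genome, mismatch_budget, margin)
      sites <- sites[sites$mismatches <= mismatch_budget, , drop = FALSE]
      if (nrow(sites) == 0L) {
        abort("no endonuclease-motif site within the mismatch budget in this genome")
      }
      row <- sites[sample.int(nrow(sites), 1L), ]
      tibble(chrom = row$chrom, position = row$position, strand = row$strand,
             motif_context = row$context, mismatches = row$mismatches)
    } else {
      lens <- genome_chrom_lengths(genome)
      if (any(lens < 2L * margin)) abort("genome too short for the requested margin")
      chrom <- sample(names(lens), 1L, prob = lens)
      p <- sample.int(lens[[chrom]] - 2L * margin, 1L) + margin - 1L
      tibble(chrom = chrom, position = p,
             strand = sample(c("+", "-"), 1L),
             motif_context = substr0(genome$seq[[chrom]], p - 4L, p + 2L),
             mismatches = NA_integer_)
    }
  })
}

# Build the inserted cassette (element orientation) for one insertion and
# resolve all junction-ambiguity constraints. Returns the structural fields
# of the truth record.
build_cassette <- function(spec, library, subfamily = NULL) {
  fam <- spec$name
  if (is.null(subfamily)) {
    subfamily <- sample(subfamilies_of(library, fam), 1L)
  }
  cons <- consensus_of(library, subfamily)
  L <- nchar(cons)
  base_at <- function(i0) substr(cons, i0 + 1L, i0 + 1L)  # 0-based accessor

  full_length <- runif(1) < spec$full_length_fraction
  inversion <- FALSE
  untemplated <- ""
  if (runif(1) < spec$untemplated_nt_probability) {
    untemplated <- strrep("G", sample(1:2, 1L))
  }

  t0 <- 0L
  if (!full_length) {
    inversion <- runif(1) < spec$twin_priming_fraction
    # keep at least 100 bases of element body so alignment is unambiguous
    repeat {
      t0 <- sample(seq(30L, L - 150L), 1L)
      # a 5' junction base must not extend the body alignment leftwards
      prev <- base_at(t0 - 1L)
      if (nzchar(untemplated) && !inversion) {
        if (substr(untemplated, nchar(untemplated), nchar(untemplated)) != prev) break
      } else break
    }
  }

  breakpoint <- NA_integer_
  spacer <- ""
  if (inversion) {
    inv_len <- sample(seq(30L, min(200L, L - t0 - 120L)), 1L)
    breakpoint <- t0 + inv_len
    # spacer of unknown origin between the inverted segment and the body;
    # two terminal bases on each side must mismatch the adjacent consensus
    # continuation, or a local alignment could cross the junction (one
    # mismatch followed by matches still scores positively)
    S <- spec$spacer_length
    repeat {
      spacer <- random_dna(S, gc = 0.5)
      ok_start <- substr(spacer, 1L, 1L) != revcomp(base_at(t0 - 1L)) &&
        substr(spacer, 2L, 2L) != revcomp(base_at(t0 - 2L))
      ok_end <- substr(spacer, S, S) != base_at(breakpoint - 1L) &&
        substr(spacer, S - 1L, S - 1L) != base_at(breakpoint - 2L)
      if (ok_start && ok_end) break
    }
    # untemplated bases must not extend the inverted alignment
    if (nzchar(untemplated) &&
        substr(untemplated, nchar(untemplated), nchar(untemplated)) ==
        revcomp(base_at(breakpoint))) {
      untemplated <- ""
    }
  }

  # endonuclease-independent events may be 3' truncated (within the poly-A
  # signal region near the element terminus)
  e0 <- L
  three_prime_truncated <- FALSE
  if (!is.null(spec$force_three_prime_truncation) && spec$force_three_prime_truncation) {
    repeat {
      e0 <- L - sample(10L:60L, 1L)
      if (!grepl("A", substr0(cons, e0 - 2L, e0))) break
    }
    three_prime_truncated <- TRUE
  }

  polya_length <- sample_range(spec$polya_length_range)
  body_start <- if (inversion) breakpoint else t0
  cassette <- paste0(
    untemplated,
    if (inversion) paste0(revcomp(substr0(cons, t0, breakpoint)), spacer) else "",
    substr0(cons, body_start, e0),
    strrep("A", polya_length))

  list(subfamily = subfamily, five_prime_start = t0, three_prime_end = e0,
       three_prime_truncated = three_prime_truncated,
       inversion = inversion, inversion_breakpoint = breakpoint,
       spacer_length = if (inversion) spec$spacer_length else NA_integer_,
       polya_length = polya_length, untemplated_5p = untemplated,
       full_length = t0 <= 3L && !inversion, insert_seq = cassette)
}

#' Plant one insertion into the genome
#'
#' Builds the truth record for one retrotransposon insertion at a chosen site
#' and returns the modified haplotype of that chromosome. The haplotype is
#' `left flank + TSD + cassette + TSD + right flank`, where the cassette
#' carries the planted TPRT hallmarks (optional untemplated 5' nucleotides,
#' optional twin-priming inversion plus spacer, element body from the
#' truncation offset, poly-A tail), reverse-complemented on minus-strand
#' integrations.
#'
#' @param genome A [simulate_genome()] result.
#' @param spec A [family_spec()].
#' @param site A one-row tibble from [select_integration_site()].
#' @param library A [consensus_library()].
#' @param subfamily Optional subfamily override (default: sampled).
#' @param tsd_length Optional TSD length override (default: sampled from the
#'   spec range; pass 0 for a blunt joint).
#' @param vaf Variant allele fraction recorded in the truth record.
#' @param seed Optional integer seed.
#'
#' @return List with `truth` (one-row tibble) and `haplotype` (the modified
#'   chromosome sequence).
#' @export
plant_insertion <- function(genome, spec, site, library = consensus_library(),
                            subfamily = NULL, tsd_length = NULL, vaf = 1,
                            seed = NULL) {
  stopifnot(inherits(genome, "sim_genome"), inherits(spec, "family_spec"))
  with_seed_if(seed, {
    chrom_seq <- genome$seq[[site$chrom]]
    if (is.null(chrom_seq)) abort(sprintf("chromosome '%s' not in genome", site$chrom))
    p <- site$position
    if (p < 0L || p > nchar(chrom_seq)) abort("site outside chromosome bounds")
    if (is.null(tsd_length)) tsd_length <- sample_range(spec$tsd_length_range)
    tsd <- substr0(chrom_seq, p, p + tsd_length)

    parts <- build_cassette(spec, library, subfamily = subfamily)
    if (parts$five_prime_start >= nchar(consensus_of(library, parts$subfamily))) {
      abort("truncation offset beyond consensus length")
    }
    cassette <- if (site$strand == "+") parts$insert_seq else revcomp(parts$insert_seq)
    haplotype <- paste0(substr0(chrom_seq, 0L, p + tsd_length),
                        cassette,
                        substr0(chrom_seq, p, nchar(chrom_seq)))
    en_dep <- !is.na(site$mismatches)
    truth <- tibble(
      id = NA_character_, family = spec$name, subfamily = parts$subfamily,
      chrom = site$chrom, position = p, strand = site$strand,
      tsd = tsd, tsd_length = tsd_length,
      en_dependent = en_dep, en_motif_context = site$motif_context,
      five_prime_start = parts$five_prime_start,
      three_prime_end = parts$three_prime_end,
      three_prime_truncated = parts$three_prime_truncated,
      inversion = parts$inversion,
      inversion_breakpoint = parts$inversion_breakpoint,
      spacer_length = parts$spacer_length,
      polya_length = parts$polya_length,
      untemplated_5p = parts$untemplated_5p,
      full_length = parts$full_length,
      vaf = vaf, insert_seq = parts$insert_seq)
    list(truth = truth, haplotype = haplotype)
  })
}

#' Simulate a set of truth insertions
#'
#' Plants all configured insertions into the genome: per family, the
#' configured number of events with endonuclease-dependent sites at motif
#' matches and endonuclease-independent sites placed uniformly (the latter
#' may additionally be 3' truncated within the poly-A signal region).
#' Insertion points are kept at least `min_spacing` bases apart so that
#' junction clusters of distinct events never merge. A `germline_fraction`
#' of events is labelled germline (these go to the known-insertion catalog
#' and get VAF 1); the rest are de novo at the configured VAF.
#'
#' @param genome A [simulate_genome()] result.
#' @param config A [sim_config()].
#' @param library A [consensus_library()].
#' @param min_spacing Minimum distance (bases) between insertion points.
#' @param seed Integer seed; defaults to `config$seed + 1`.
#'
#' @return Truth tibble, one row per insertion (see [plant_insertion()]),
#'   with columns `id` and `germline` filled in.
#' @export
simulate_truth <- function(genome, config, library = consensus_library(),
                           min_spacing = 500L, seed = config$seed + 1L) {
  stopifnot(inherits(genome, "sim_genome"), inherits(config, "sim_config"))
  with_seed_if(seed, {
    en_sites <- scan_en_sites(genome, mismatch_budget = 0L)
    used <- tibble(chrom = character(), position = integer())
    far_enough <- function(chrom, pos) {
      hits <- used$chrom == chrom & abs(used$position - pos) < min_spacing
      !any(hits)
    }
    rows <- list()
    k <- 0L
    for (spec in config$families) {
      for (i in seq_len(spec$n)) {
        k <- k + 1L
        en_dep <- runif(1) >= spec$en_independent_fraction
        site <- NULL
        for (try in seq_len(200L)) {
          cand <- if (en_dep) {
            if (nrow(en_sites) == 0L) abort("no endonuclease-motif sites available")
            en_sites[sample.int(nrow(en_sites), 1L), ] %>%
              rename(motif_context = "context") %>%
              select("chrom", "position", "strand", "motif_context", "mismatches")
          } else {
            select_integration_site(genome, en_dependent = FALSE)
          }
          if (far_enough(cand$chrom, cand$position)) { site <- cand; break }
        }
        if (is.null(site)) abort("could not place insertions with the requested spacing")
        used <- bind_rows(used, tibble(chrom = site$chrom, position = site$position))
        spec_i <- spec
        if (!en_dep) {
          site$mismatches <- NA_integer_
          spec_i$force_three_prime_truncation <- runif(1) < 0.5
        }
        planted <- plant_insertion(genome, spec_i, site, library = library,
                                   vaf = config$vaf)
        planted$truth$id <- sprintf("ins%04d", k)
        rows[[k]] <- planted$truth
      }
    }
    truth <- bind_rows(rows)
    truth$germline <- runif(nrow(truth)) < config$germline_fraction
    truth$vaf[truth$germline] <- 1
    truth
  })
}

#' Extract flank/insert/flank triplets for planted insertions
#'
#' Reconstructs, for each truth insertion, the left genomic flank (ending
#' with the first TSD copy), the inserted sequence as it appears in the
#' haplotype (genomic orientation), and the right genomic flank (starting
#' with the second TSD copy). This is the input the hallmark annotator takes.
#'
#' @param genome A [simulate_genome()] result.
#' @param truth Truth tibble from [simulate_truth()].
#' @param flank Flank length in bases.
#' @return Tibble: `id`, `family`, `left_flank`, `insert`, `right_flank`.
#' @export
insertion_triplets <- function(genome, truth, flank = 150L) {
  purrr::pmap_dfr(
    list(truth$id, truth$family, truth$chrom, truth$position,
         truth$tsd_length, truth$strand, truth$insert_seq),
    function(id, family, chrom, p, tsd_len, strand, insert_seq) {
      s <- genome$seq[[chrom]]
      left <- substr0(s, max(0L, p + tsd_len - flank), p + tsd_len)
      right <- substr0(s, p, min(nchar(s), p + flank))
      tibble(id = id, family = family, left_flank = left,
             insert = if (strand == "+") insert_seq else revcomp(insert_seq),
             right_flank = right)
    })
}
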