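# TPRT hallmark annotation of resolved insertion sequences.
#
# Given the left genomic flank, the inserted sequence (genomic orientation)
# and the right genomic flank, the annotator reports the canonical hallmarks
# of L1-mediated target-primed reverse transcription: target site
# duplication, endonuclease motif at the cleavage site, poly-A tail length,
# 5' truncation offset, twin-priming inversion with spacer,
# microcomplementarity and untemplated 5' nucleotides.

#' Detect a target site duplication
#'
#' The TSD is the longest exact suffix of the left flank that equals a prefix
#' of the right flank, capped at `max_tsd`. A blunt insertion (no duplication)
#' returns the empty string.
#'
#' @param left_flank,right_flank Genomic flanks; the left flank must end at
#'   the insertion (its suffix is the first TSD copy), the right flank must
#'   start with the second copy.
#' @param max_tsd Longest TSD considered (bases).
#' @return The TSD sequence (possibly `""`).
#' @export
#' @examples
#' detect_tsd("ACGTGGAT", "GGATTTCA")  # "GGAT"
detect_tsd <- function(left_flank, right_flank, max_tsd = 30L) {
  k <- longest_suffix_prefix(left_flank, right_flank, max_tsd)
  if (k == 0L) "" else substr(right_flank, 1L, k)
}

#' Score a cleavage context against the L1 endonuclease motif
#'
#' Computes the minimum Hamming distance of a 6-mer cleavage context to the
#' L1 endonuclease target motif 5'-TTTT/AA-3', reading the context on both
#' strands. The verdict `en_dependent` is distance `<= budget`.
#'
#' @param context 6 bases of genomic context centred on the cleavage site
#'   (slash between positions 4 and 5).
#' @param budget Mismatch tolerance for the endonuclease-dependent verdict.
#' @return One-row tibble: `context`, `mismatches`, `strand` (which reading
#'   attains the minimum; `"+"` wins ties), `en_dependent`. A context shorter
#'   than 6 bases yields `NA` fields (unknown verdict).
#' @export
#' @examples
#' score_en_motif("TTTTAA")  # 0 mismatches
#' score_en_motif("TTTCAA")  # 1 mismatch
score_en_motif <- function(context, budget = 2L) {
  if (is.na(context) || nchar(context) < 6L) {
    return(tibble(context = context, mismatches = NA_integer_,
                  strand = NA_character_, en_dependent = NA))
  }
  context <- substr(context, 1L, 6L)
  mm_f <- hamming(context, EN_MOTIF)
  mm_r <- hamming(revcomp(context), EN_MOTIF)
  strand <- if (mm_f <= mm_r) "+" else "-"
  mm <- min(mm_f, mm_r)
  tibble(context = context, mismatches = mm, strand = strand,
         en_dependent = mm <= budget)
}

#' Measure the poly-A tail of an inserted sequence
#'
#' Length of the maximal 3'-terminal adenosine run, permitting at most one
#' non-A interruption per `per` consumed bases. An interruption must be a
#' single non-A base flanked by further A (two consecutive non-A bases end
#' the tail). The reported length runs from the 3' terminus to the most
#' distal A inside the tolerated region.
#'
#' @param insert Inserted sequence, element (sense) orientation.
#' @param per Bases of tail required per tolerated interruption.
#' @return Integer tail length (0 when the terminal base is not A).
#' @export
#' @examples
#' measure_polya("GCAAAAAA")  # 6
measure_polya <- function(insert, per = 20L) {
  if (!nzchar(insert)) return(0L)
  chars <- rev(strsplit(insert, "")[[1]])
  n <- length(chars)
  last_a <- 0L
  interruptions <- 0L
  for (i in seq_len(n)) {
    if (chars[i] == "A") {
      last_a <- i
    } else if ((interruptions + 1L) * per <= i - 1L &&
               i < n && chars[i + 1L] == "A") {
      interruptions <- interruptions + 1L
    } else {
      break
    }
  }
  last_a
}

# Local alignment wrapper with the package's fixed scoring scheme
# (match 2, mismatch -3, gap open 5, gap extend 2). Returns NULL when no
# positive-scoring alignment exists.
align_local <- function(pattern, subject) {
  if (!nzchar(pattern) || !nzchar(subject)) return(NULL)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(pattern, subject, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 5, gapExtension = 2)
  sc <- Biostrings::score(al)
  if (sc <= 0) return(NULL)
  list(score = sc,
       pstart = Biostrings::start(Biostrings::pattern(al)),
       pend = Biostrings::end(Biostrings::pattern(al)),
       sstart = Biostrings::start(Biostrings::subject(al)),
       send = Biostrings::end(Biostrings::subject(al)))
}

#' Classify the structure of one insertion
#'
#' Full hallmark annotation of a single resolved insertion: orientation and
#' subfamily by local alignment to the consensus library, then TSD,
#' endonuclease motif, poly-A tail, 5' truncation offset, twin-priming
#' inversion (antisense 5' segment, with spacer length), 3' truncation,
#' microcomplementarity (1-5 bases of identity between the flank suffix and
#' the consensus immediately 5' of the truncation point, reported only when
#' no untemplated bases are present) and untemplated 5' nucleotides.
#'
#' @param left_flank,right_flank Genomic flanks (see [detect_tsd()]).
#' @param insert Inserted sequence in genomic orientation.
#' @param family Element family, or `NA` to search all families.
#' @param library A [consensus_library()].
#' @param max_tsd,en_budget,polya_per See the individual hallmark functions.
#' @param full_length_tol Truncation offsets up to this many consensus bases
#'   still count as full length (absorbs untemplated additions).
#' @param min_inversion Minimum prefix length (bases) before an antisense
#'   alignment is attempted.
#' @param min_score Minimum local alignment score to accept a match.
#'
#' @return One-row tibble (`hallmark report`): `family`, `subfamily`,
#'   `strand`, `aligned`, `tsd`, `tsd_length`, `en_context`, `en_mismatches`,
#'   `en_dependent`, `polya_length`, `five_prime_start`,
#'   `three_prime_truncated`, `inversion`, `inversion_breakpoint`,
#'   `spacer_length`, `microcomplementarity`, `untemplated_5p`,
#'   `full_length`.
#' @export
classify_structure <- function(left_flank, insert, right_flank,
                               family = NA_character_,
                               library = consensus_library(),
                               max_tsd = 30L, en_budget = 2L, polya_per = 20L,
                               full_length_tol = 3L, min_inversion = 15L,
                               min_score = 30) {
  tsd <- detect_tsd(left_flank, right_flank, max_tsd = max_tsd)
  tsd_len <- nchar(tsd)

  # endonuclease context: 4 bases 5' of the cleavage point + first 2 bases of
  # the duplicated target site, read on the unbroken genomic strand
  left_sans_tsd <- substr(left_flank, 1L, nchar(left_flank) - tsd_len)
  context <- if (nchar(left_sans_tsd) >= 4L && nchar(right_flank) >= 2L) {
    paste0(substr(left_sans_tsd, nchar(left_sans_tsd) - 3L, nchar(left_sans_tsd)),
           substr(right_flank, 1L, 2L))
  } else NA_character_
  en <- score_en_motif(context, budget = en_budget)

  candidates <- if (is.na(family)) library else library[library$family == family, ]
  if (nrow(candidates) == 0L) abort(sprintf("unknown family '%s'", family))

  best <- NULL
  for (i in seq_len(nrow(candidates))) {
    cons <- candidates$sequence[[i]]
    for (ori in c("+", "-")) {
      pat <- if (ori == "+") insert else revcomp(insert)
      al <- align_local(pat, cons)
      if (!is.null(al) && (is.null(best) || al$score > best$al$score)) {
        best <- list(al = al, subfamily = candidates$subfamily[[i]],
                     family = candidates$family[[i]], strand = ori)
      }
    }
  }

  blank <- tibble(family = family, subfamily = NA_character_,
                  strand = NA_character_, aligned = FALSE,
                  tsd = tsd, tsd_length = tsd_len,
                  en_context = en$context, en_mismatches = en$mismatches,
                  en_dependent = en$en_dependent,
                  polya_length = NA_integer_, five_prime_start = NA_integer_,
                  three_prime_truncated = NA, inversion = NA,
                  inversion_breakpoint = NA_integer_,
                  spacer_length = NA_integer_,
                  microcomplementarity = NA_integer_,
                  untemplated_5p = NA_character_, full_length = NA)
  if (is.null(best) || best$al$score < min_score) return(blank)

  strand <- best$strand
  ins_or <- if (strand == "+") insert else revcomp(insert)
  left_or <- if (strand == "+") left_flank else revcomp(right_flank)
  cons <- consensus_of(library, best$subfamily)
  L <- nchar(cons)
  al <- best$al

  polya_length <- measure_polya(ins_or, per = polya_per)
  three_prime_truncated <- al$send < L - 3L

  five_prime_start <- al$sstart - 1L  # 0-based consensus offset
  inversion <- FALSE
  inversion_breakpoint <- NA_integer_
  spacer_length <- NA_integer_
  untemplated <- ""

  prefix <- substr(ins_or, 1L, al$pstart - 1L)
  if (nchar(prefix) >= min_inversion) {
    inv_al <- align_local(prefix, revcomp(cons))
    if (!is.null(inv_al) && inv_al$score >= min_score) {
      inversion <- TRUE
      inversion_breakpoint <- five_prime_start
      # antisense subject range back to consensus coordinates (0-based)
      five_prime_start <- L - inv_al$send
      spacer_length <- nchar(prefix) - inv_al$pend
      untemplated <- substr(prefix, 1L, inv_al$pstart - 1L)
    } else {
      untemplated <- prefix
    }
  } else {
    untemplated <- prefix
  }

  micro <- 0L
  if (!nzchar(untemplated) && five_prime_start > 0L && nzchar(left_or)) {
    for (k in seq_len(min(5L, five_prime_start, nchar(left_or)))) {
      if (substr(left_or, nchar(left_or) - k + 1L, nchar(left_or)) ==
          substr0(cons, five_prime_start - k, five_prime_start)) micro <- k
    }
  }

  tibble(family = best$family, subfamily = best$subfamily, strand = strand,
         aligned = TRUE, tsd = tsd, tsd_length = tsd_len,
         en_context = en$context, en_mismatches = en$mismatches,
         en_dependent = en$en_dependent,
         polya_length = polya_length, five_prime_start = five_prime_start,
         three_prime_truncated = three_prime_truncated,
         inversion = inversion, inversion_breakpoint = inversion_breakpoint,
         spacer_length = spacer_length,
         microcomplementarity = if (nzchar(untemplated)) NA_integer_ else micro,
         untemplated_5p = untemplated,
         full_length = five_prime_start <= full_length_tol && !inversion)
}

#' Annotate hallmarks for a table of insertion triplets
#'
#' Applies [classify_structure()] to each row of a triplet table (as produced
#' by [insertion_triplets()] or read from a TSV of left flank / insert /
#' right flank columns).
#'
#' @param triplets Tibble with columns `left_flank`, `insert`, `right_flank`,
#'   and optionally `id` and `family`.
#' @param library A [consensus_library()].
#' @param ... Passed to [classify_structure()].
#' @return Tibble with one hallmark-report row per input row, carrying `id`.
#' @export
annotate_hallmarks <- function(triplets, library = consensus_library(), ...) {
  ids <- if ("id" %in% names(triplets)) triplets$id
         else sprintf("ins%04d", seq_len(nrow(triplets)))
  fams <- if ("family" %in% names(triplets)) triplets$family
          else rep(NA_character_, nrow(triplets))
  purrr::map_dfr(seq_len(nrow(triplets)), function(i) {
    rep <- classify_structure(triplets$left_flank[[i]], triplets$insert[[i]],
                              triplets$right_flank[[i]], family = fams[[i]],
                              library = library, ...)
    dplyr::bind_cols(tibble(id = ids[[i]]), rep)
  })
}
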