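# Junction-read insertion calling: duplicate collapse, single-linkage
# clustering, the two-unique-amplicon / >=5 nt separation reporting rule,
# family and subfamily assignment, and known-catalog matching.

#' Collapse PCR duplicates to unique amplicons
#'
#' Two reads are duplicates when they share the same alignment start, junction
#' side, family and sample; each distinct combination becomes one unique
#' amplicon with a multiplicity equal to the collapsed read count.
#'
#' @param reads Amplicon read tibble with columns `sample_id`, `chrom`,
#'   `start`, `side`, `family` (extra columns are dropped).
#' @return Tibble of unique amplicons: `sample_id`, `chrom`, `start`, `side`,
#'   `family`, `multiplicity`.
#' @export
collapse_duplicates <- function(reads) {
  reads %>%
    group_by(.data$sample_id, .data$chrom, .data$start, .data$side, .data$family) %>%
    summarise(multiplicity = dplyr::n(), .groups = "drop") %>%
    arrange(.data$sample_id, .data$chrom, .data$start)
}

#' Cluster unique amplicons by proximity
#'
#' Single-linkage clustering along each chromosome: consecutive unique
#' amplicons of the same sample, chromosome and family whose starts are
#' within `window` bases join one cluster; chains merge transitively.
#'
#' @param uniques Output of [collapse_duplicates()].
#' @param window Clustering window in bases (non-negative).
#' @return `uniques` with an added `cluster_id` column.
#' @export
cluster_amplicons <- function(uniques, window = 200L) {
  if (window < 0L) abort("`window` must be non-negative")
  uniques %>%
    arrange(.data$sample_id, .data$family, .data$chrom, .data$start) %>%
    group_by(.data$sample_id, .data$family, .data$chrom) %>%
    mutate(.new = c(TRUE, diff(.data$start) > window)) %>%
    ungroup() %>%
    mutate(cluster_id = cumsum(.data$.new)) %>%
    select(-".new")
}

#' Emit insertion calls from amplicon clusters
#'
#' A cluster becomes a call when it holds at least `min_unique` unique
#' amplicons whose maximum pairwise start separation is at least `min_sep`
#' bases (the reporting threshold; duplicates never count). The junction
#' coordinate per side is the start of the maximum-multiplicity member, ties
#' broken toward the 5'-most coordinate. Calls may be single-sided.
#'
#' @param clustered Output of [cluster_amplicons()].
#' @param min_unique Minimum unique amplicons per call.
#' @param min_sep Minimum maximum-pairwise start separation (bases).
#' @return Call tibble: `call_id`, `sample_id`, `chrom`, `family`,
#'   `junction_5p`, `junction_3p`, `junction` (5' side if present, else 3'),
#'   `n_unique_amplicons`, `max_separation`, `sides`.
#' @export
call_insertions <- function(clustered, min_unique = 2L, min_sep = 5L) {
  side_mode <- function(start, multiplicity) {
    if (length(start) == 0L) return(NA_integer_)
    o <- order(-multiplicity, start)
    start[o[1L]]
  }
  calls <- clustered %>%
    group_by(.data$sample_id, .data$family, .data$chrom, .data$cluster_id) %>%
    summarise(
      n_unique_amplicons = dplyr::n(),
      max_separation = max(.data$start) - min(.data$start),
      junction_5p = side_mode(.data$start[.data$side == "5p"],
                              .data$multiplicity[.data$side == "5p"]),
      junction_3p = side_mode(.data$start[.data$side == "3p"],
                              .data$multiplicity[.data$side == "3p"]),
      sides = paste(sort(unique(.data$side)), collapse = ","),
      .groups = "drop") %>%
    filter(.data$n_unique_amplicons >= min_unique,
           .data$max_separation >= min_sep) %>%
    mutate(junction = dplyr::coalesce(.data$junction_5p, .data$junction_3p),
           call_id = sprintf("call%05d", row_number())) %>%
    select("call_id", "sample_id", "chrom", "family", "junction_5p",
           "junction_3p", "junction", "n_unique_amplicons", "max_separation",
           "sides")
  calls
}

#' Call insertions from raw amplicon reads
#'
#' Convenience wrapper chaining [collapse_duplicates()],
#' [cluster_amplicons()] and [call_insertions()].
#'
#' @inheritParams collapse_duplicates
#' @inheritParams cluster_amplicons
#' @inheritParams call_insertions
#' @return See [call_insertions()].
#' @export
#' @examples
#' reads <- tibble::tibble(sample_id = "s1", chrom = "chr1",
#'                         start = c(1000L, 1010L), side = "5p", family = "L1")
#' call_junctions(reads)
call_junctions <- function(reads, window = 200L, min_unique = 2L, min_sep = 5L) {
  reads %>%
    collapse_duplicates() %>%
    cluster_amplicons(window = window) %>%
    call_insertions(min_unique = min_unique, min_sep = min_sep)
}

#' Assign family and subfamily to a call
#'
#' The family is the majority vote over member amplicon families (ties
#' toward the lexicographically first). The subfamily is decided from the
#' resolved insertion sequence: the candidate subfamily consensus matching
#' the most diagnostic positions wins; ties (or a missing sequence) give
#' `"unresolved"`.
#'
#' @param member_families Character vector of member amplicon families.
#' @param sequence Optional resolved insertion sequence (element
#'   orientation).
#' @param five_prime_start 0-based consensus offset of the sequence start
#'   (from the hallmark report); diagnostic positions upstream of it cannot
#'   be read.
#' @param library A [consensus_library()].
#' @return One-row tibble: `family`, `subfamily`.
#' @export
assign_family_subfamily <- function(member_families, sequence = NULL,
                                    five_prime_start = 0L,
                                    library = consensus_library()) {
  known <- unique(library$family)
  if (!all(member_families %in% known)) {
    abort(sprintf("unknown family label(s): %s",
                  paste(setdiff(member_families, known), collapse = ", ")))
  }
  tab <- sort(table(member_families), decreasing = TRUE)
  fam <- names(tab)[tab == max(tab)]
  fam <- sort(fam)[1L]

  subs <- subfamilies_of(library, fam)
  diags <- attr(library, "diagnostics")
  if (length(subs) == 1L) {
    return(tibble(family = fam, subfamily = subs))
  }
  if (is.null(sequence) || !nzchar(sequence) || is.null(diags)) {
    return(tibble(family = fam, subfamily = "unresolved"))
  }
  scores <- vapply(subs, function(sub) {
    d <- diags[diags$subfamily == sub, ]
    if (nrow(d) == 0L) return(0L)
    hits <- 0L
    for (j in seq_len(nrow(d))) {
      i <- d$position[j] - five_prime_start  # 0-based index into sequence
      if (i >= 0L && i < nchar(sequence) &&
          substr(sequence, i + 1L, i + 1L) == d$base[j]) hits <- hits + 1L
    }
    hits
  }, integer(1))
  top <- subs[scores == max(scores)]
  tibble(family = fam,
         subfamily = if (length(top) == 1L && max(scores) > 0L) top else "unresolved")
}

#' Match calls against a known-insertion catalog
#'
#' A call is `"known"` when a catalog entry of the same family lies within
#' `match_window` bases of its junction coordinate, else `"novel"`.
#' Malformed catalog records (missing chromosome/position or non-numeric
#' position) are skipped with a warning reporting the skipped count.
#'
#' @param calls Call tibble (needs `chrom`, `junction`, `family`).
#' @param catalog Catalog tibble with columns `chrom`, `start`, `family`
#'   (BED-style; `start` is the insertion point).
#' @param match_window Half-width of the matching window in bases.
#' @return `calls` with an added `catalog_status` column.
#' @export
match_catalog <- function(calls, catalog, match_window = 100L) {
  bad <- is.na(catalog$chrom) | is.na(catalog$start) |
    !is.finite(suppressWarnings(as.numeric(catalog$start)))
  if (any(bad)) {
    warn(sprintf("skipping %d malformed catalog record(s)", sum(bad)))
    catalog <- catalog[!bad, , drop = FALSE]
  }
  known <- vapply(seq_len(nrow(calls)), function(i) {
    hit <- catalog$chrom == calls$chrom[i] &
      catalog$family == calls$family[i] &
      abs(as.numeric(catalog$start) - calls$junction[i]) <= match_window
    any(hit)
  }, logical(1))
  mutate(calls, catalog_status = ifelse(known, "known", "novel"))
}
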