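# The de novo filter cascade: a call in a pluripotent sample is de novo only
# if it is absent from (i) known-insertion catalogs, (ii) the parental cell
# line, (iii) an earlier passage of the same hESC line and (iv) every other
# pluripotent line.

#' Describe a cohort of samples and their lineage
#'
#' @param samples Tibble (or data frame) with columns `sample_id`, `line`,
#'   `role` (one of `"parental"`, `"hiPSC"`, `"hESC"`) and `passage`
#'   (integer; use 0 for parental samples). Parental and derived samples of
#'   one line share the `line` label; at most one parental sample per line.
#' @return The validated tibble with class `cohort_design`.
#' @export
#' @examples
#' cohort_design(tibble::tibble(
#'   sample_id = c("fib1", "ips1_p20", "ips1_p40"),
#'   line = "line1", role = c("parental", "hiPSC", "hiPSC"),
#'   passage = c(0, 20, 40)))
cohort_design <- function(samples) {
  samples <- as_tibble(samples)
  need <- c("sample_id", "line", "role", "passage")
  if (!all(need %in% names(samples))) {
    abort(sprintf("cohort design needs columns: %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id in design")
  if (!all(samples$role %in% c("parental", "hiPSC", "hESC"))) {
    abort("role must be one of parental, hiPSC, hESC")
  }
  n_par <- samples %>% filter(.data$role == "parental") %>%
    dplyr::count(.data$line) %>% pull(.data$n)
  if (any(n_par > 1L)) abort("a line may have at most one parental sample")
  structure(samples, class = c("cohort_design", class(samples)))
}

#' Do two calls match across samples?
#'
#' Two calls match when they share the element family and their junction
#' coordinates lie within `match_window` bases.
#'
#' @param call_a,call_b One-row call tibbles (need `chrom`, `junction`,
#'   `family`).
#' @param match_window Half-width of the coordinate window (bases).
#' @return Logical.
#' @export
cross_sample_match <- function(call_a, call_b, match_window = 100L) {
  call_a$chrom == call_b$chrom &&
    call_a$family == call_b$family &&
    abs(call_a$junction - call_b$junction) <= match_window
}

# vectorized: for each row of `calls`, is there any matching row in `other`?
matched_in <- function(calls, other, match_window = 100L) {
  if (nrow(other) == 0L) return(rep(FALSE, nrow(calls)))
  vapply(seq_len(nrow(calls)), function(i) {
    any(other$chrom == calls$chrom[i] &
          other$family == calls$family[i] &
          abs(other$junction - calls$junction[i]) <= match_window)
  }, logical(1))
}

#' Apply the de novo filter cascade
#'
#' Labels every call from a pluripotent sample as de novo or not. A call
#' fails:
#' * `catalog` - a same-family catalog entry lies within the match window;
#' * `parental` - the call is found in the parental sample of its line;
#' * `earlier_passage` - the sample is an hESC passage and the call is found
#'   in an earlier passage of the same line (presence only in the later
#'   passage is compatible with de novo);
#' * `recurrent_across_lines` - the call is found in a different line
#'   (passages of one line count as one line).
#'
#' A call is de novo exactly when it fails no filter. Calls from parental
#' samples are not evaluated.
#'
#' @param calls Call tibble covering the whole cohort (needs `call_id`,
#'   `sample_id`, `chrom`, `junction`, `family`).
#' @param catalog Known-insertion catalog (see [match_catalog()]); may have
#'   zero rows.
#' @param design A [cohort_design()] covering every sample in `calls`.
#' @param match_window Coordinate tolerance (bases) shared by all presence
#'   checks.
#' @return Verdict tibble: `call_id`, `sample_id`, `de_novo`,
#'   `failed_catalog`, `failed_parental`, `failed_earlier_passage`,
#'   `failed_recurrent`, `failed` (comma-separated labels).
#' @export
annotate_de_novo <- function(calls, catalog, design, match_window = 100L) {
  stopifnot(inherits(design, "cohort_design"))
  missing <- setdiff(unique(calls$sample_id), design$sample_id)
  if (length(missing) > 0L) {
    abort(sprintf("sample(s) absent from cohort design: %s",
                  paste(missing, collapse = ", ")))
  }
  calls <- left_join(calls, select(design, "sample_id", "line", "role", "passage"),
                     by = "sample_id")
  pluri <- filter(calls, .data$role != "parental")
  if (nrow(pluri) == 0L) {
    return(tibble(call_id = character(), sample_id = character(),
                  de_novo = logical(), failed_catalog = logical(),
                  failed_parental = logical(),
                  failed_earlier_passage = logical(),
                  failed_recurrent = logical(), failed = character()))
  }

  cat_tbl <- if (is.null(catalog) || nrow(catalog) == 0L) {
    tibble(chrom = character(), start = numeric(), family = character())
  } else {
    ct <- as_tibble(catalog)
    if (!"family" %in% names(ct) && "name" %in% names(ct)) ct$family <- ct$name
    select(ct, "chrom", "start", "family")
  }
  f_catalog <- if (nrow(cat_tbl) == 0L) rep(FALSE, nrow(pluri)) else {
    match_catalog(pluri, cat_tbl, match_window = match_window)$catalog_status == "known"
  }

  f_parental <- vapply(seq_len(nrow(pluri)), function(i) {
    par_samples <- design$sample_id[design$line == pluri$line[i] &
                                      design$role == "parental"]
    if (length(par_samples) == 0L) return(FALSE)
    other <- filter(calls, .data$sample_id %in% par_samples)
    matched_in(pluri[i, ], other, match_window)
  }, logical(1))

  f_earlier <- vapply(seq_len(nrow(pluri)), function(i) {
    if (pluri$role[i] != "hESC") return(FALSE)
    earlier <- design$sample_id[design$line == pluri$line[i] &
                                  design$role != "parental" &
                                  design$passage < pluri$passage[i]]
    if (length(earlier) == 0L) return(FALSE)
    other <- filter(calls, .data$sample_id %in% earlier)
    matched_in(pluri[i, ], other, match_window)
  }, logical(1))

  f_recurrent <- vapply(seq_len(nrow(pluri)), function(i) {
    other <- filter(calls, .data$role != "parental",
                    .data$line != pluri$line[i])
    matched_in(pluri[i, ], other, match_window)
  }, logical(1))

  failed_labels <- purrr::pmap_chr(
    list(f_catalog, f_parental, f_earlier, f_recurrent),
    function(a, b, c, d) {
      paste(c("catalog", "parental", "earlier_passage",
              "recurrent_across_lines")[c(a, b, c, d)], collapse = ",")
    })
  tibble(call_id = pluri$call_id, sample_id = pluri$sample_id,
         de_novo = !(f_catalog | f_parental | f_earlier | f_recurrent),
         failed_catalog = f_catalog, failed_parental = f_parental,
         failed_earlier_passage = f_earlier, failed_recurrent = f_recurrent,
         failed = failed_labels)
}
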