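# Library-subsampling sensitivity modelling, weighted false-negative
# arithmetic and the sensitivity-corrected retrotransposition-rate
# estimator.

#' Germline concordance between lineage-linked samples
#'
#' For each family, the fraction of calls in the early sample (parental line
#' or early passage) that are recovered in the matched late sample. This is
#' the baseline detection rate of the assay; its complement is the baseline
#' false-negative rate.
#'
#' @param calls_early,calls_late Call tibbles (need `chrom`, `junction`,
#'   `family`).
#' @param match_window Coordinate tolerance (bases).
#' @return Tibble: `family`, `n_early`, `n_matched`, `detection` (fraction;
#'   `NA` for families with no early calls).
#' @export
germline_concordance <- function(calls_early, calls_late, match_window = 100L) {
  fams <- sort(unique(c(calls_early$family, calls_late$family)))
  purrr::map_dfr(fams, function(f) {
    early <- filter(calls_early, .data$family == f)
    late <- filter(calls_late, .data$family == f)
    n <- nrow(early)
    m <- if (n == 0L) 0L else sum(matched_in(early, late, match_window))
    tibble(family = f, n_early = n, n_matched = m,
           detection = if (n == 0L) NA_real_ else m / n)
  })
}

#' Subsampling detection curve
#'
#' Emulates sequencing a library at reduced depth: at each sampling depth
#' `s` on the grid, reads are retained independently with probability `s`
#' and an insertion counts as detected when at least `min_unique` of its
#' unique amplicons survive. Each replicate draws one uniform variate per
#' unique amplicon (the smallest retention threshold over its duplicate
#' copies), so the whole grid is evaluated from a single coupled draw with
#' the exact per-depth Bernoulli marginals.
#'
#' @param reads Read tibble carrying `insertion_id` (the simulator's, or a
#'   call id assigned upstream), `start`, `side`, `family` and
#'   `duplicate_group`.
#' @param insertions Tibble of the full-library insertions to track (needs
#'   `id` and `family`); typically the germline truth or call set.
#' @param grid Sampling-depth grid, fractions in (0, 1].
#' @param reps Number of sampling replicates per depth.
#' @param min_unique Unique-read threshold for detection.
#' @param seed Optional integer seed.
#' @return A tibble of class `detection_curve`: `depth`, `family`, `rep`,
#'   `detected`, `total`, `fraction`.
#' @export
subsample_detection <- function(reads, insertions,
                                grid = seq(0.01, 1, by = 0.01),
                                reps = 10L, min_unique = 2L, seed = NULL) {
  if (reps < 1L) abort("`reps` must be at least 1")
  if (any(grid < 0 | grid > 1)) abort("grid depths must lie in [0, 1]")
  reads <- filter(reads, .data$insertion_id %in% insertions$id)
  with_seed_if(seed, {
    # per unique amplicon and replicate: the smallest u over duplicate
    # copies; the unique survives depth s iff u <= s
    uniq <- reads %>%
      group_by(.data$insertion_id, .data$side, .data$start) %>%
      summarise(copies = dplyr::n(), .groups = "drop")
    out <- purrr::map_dfr(seq_len(reps), function(r) {
      u <- stats::rbeta(nrow(uniq), 1, uniq$copies)  # min of `copies` uniforms
      thr <- uniq %>%
        mutate(u = u) %>%
        group_by(.data$insertion_id) %>%
        summarise(u_k = sort(.data$u)[min(min_unique, dplyr::n())],
                  n_uniq = dplyr::n(), .groups = "drop") %>%
        mutate(u_k = ifelse(.data$n_uniq < min_unique, Inf, .data$u_k))
      purrr::map_dfr(grid, function(s) {
        det <- insertions %>%
          left_join(thr, by = c(id = "insertion_id")) %>%
          mutate(detected = !is.na(.data$u_k) & .data$u_k <= s) %>%
          group_by(.data$family) %>%
          summarise(detected = sum(.data$detected), total = dplyr::n(),
                    .groups = "drop")
        mutate(det, depth = s, rep = r)
      })
    })
    curve <- out %>%
      mutate(fraction = .data$detected / .data$total) %>%
      select("depth", "family", "rep", "detected", "total", "fraction") %>%
      arrange(.data$depth, .data$family, .data$rep)
    class(curve) <- c("detection_curve", class(curve))
    attr(curve, "reps") <- reps
    attr(curve, "min_unique") <- min_unique
    curve
  })
}

#' Summarise a detection curve
#'
#' Mean detection fraction and replicate spread per depth and family.
#'
#' @param x A [subsample_detection()] result.
#' @param ... Unused.
#' @return Tibble: `depth`, `family`, `mean_fraction`, `sd_fraction`.
#' @export
tidy.detection_curve <- function(x, ...) {
  as_tibble(x) %>%
    group_by(.data$depth, .data$family) %>%
    summarise(mean_fraction = mean(.data$fraction),
              sd_fraction = stats::sd(.data$fraction), .groups = "drop")
}

#' Overall false-negative rate from per-family detection
#'
#' The overall false-negative rate is one minus the weighted mean of the
#' per-family detection fractions, weighted by the average per-sample
#' insertion count of each family:
#' `FN = 1 - sum(w_f * d_f) / sum(w_f)`.
#'
#' @param detection Named numeric vector of per-family detection fractions
#'   in `[0, 1]`.
#' @param weights Named numeric vector of family weights (average insertion
#'   counts per sample); names must cover `names(detection)`.
#' @return Overall false-negative rate as a fraction.
#' @export
#' @examples
#' weighted_fn(c(L1 = 0.885, Alu = 0.928, SVA = 0.883, LTR = 0.898))
weighted_fn <- function(detection, weights = family_weights_default) {
  if (is.null(names(detection))) names(detection) <- names(weights)
  fams <- names(detection)
  if (!all(fams %in% names(weights))) abort("weights missing for some families")
  w <- weights[fams]
  if (sum(w) <= 0) abort("total weight must be positive")
  if (any(detection < 0 | detection > 1)) abort("detection fractions must lie in [0, 1]")
  1 - sum(w * detection) / sum(w)
}

#' VAF-adjusted overall false-negative rate
#'
#' Composes the depth-specific per-family detection fractions (library
#' sampling depth `v` models an insertion at variant allele fraction `v`)
#' with the baseline false-negative rate multiplicatively:
#' `FN(v) = 1 - [sum(w_f d_f(v)) / sum(w_f)] * (1 - FN_baseline)`.
#'
#' @param detection_v Named per-family detection fractions at sampling
#'   depth `v`.
#' @param weights Family weights (see [weighted_fn()]).
#' @param fn_baseline Baseline overall false-negative rate (fraction), as
#'   returned by [weighted_fn()] on the full-depth detection fractions.
#' @return Overall false-negative rate at VAF `v`, as a fraction.
#' @export
#' @examples
#' base <- weighted_fn(c(L1 = 0.885, Alu = 0.928, SVA = 0.883, LTR = 0.898))
#' fn_at_vaf(c(L1 = 0.714, Alu = 0.762, SVA = 0.684, LTR = 0.873),
#'           fn_baseline = base)
fn_at_vaf <- function(detection_v, weights = family_weights_default,
                      fn_baseline = 0) {
  if (any(detection_v < 0 | detection_v > 1)) {
    abort("detection fractions must lie in [0, 1]")
  }
  d_bar <- 1 - weighted_fn(detection_v, weights)
  1 - d_bar * (1 - fn_baseline)
}

#' False-positive rate from a validation rate
#'
#' The assay's false-positive rate is the complement of the PCR validation
#' rate of its calls.
#'
#' @param validation_rate Fraction of calls confirmed by validation PCR.
#' @return False-positive rate as a fraction.
#' @export
false_positive_rate <- function(validation_rate) {
  assert_fraction(validation_rate, "validation_rate")
  1 - validation_rate
}

#' Per-insertion detection probability curves
#'
#' For each tracked insertion, the probability (over subsampling replicates)
#' that it would still be detected at each sampling depth. Feeds
#' [estimate_insertion_rate()].
#'
#' @inheritParams subsample_detection
#' @return Tibble: `id`, `depth`, `p` (detection probability estimate).
#' @export
insertion_detection_curves <- function(reads, insertions,
                                       grid = seq(0.05, 1, by = 0.05),
                                       reps = 10L, min_unique = 2L,
                                       seed = NULL) {
  if (reps < 1L) abort("`reps` must be at least 1")
  reads <- filter(reads, .data$insertion_id %in% insertions$id)
  with_seed_if(seed, {
    uniq <- reads %>%
      group_by(.data$insertion_id, .data$side, .data$start) %>%
      summarise(copies = dplyr::n(), .groups = "drop")
    thr <- purrr::map_dfr(seq_len(reps), function(r) {
      u <- stats::rbeta(nrow(uniq), 1, uniq$copies)
      uniq %>%
        mutate(u = u) %>%
        group_by(.data$insertion_id) %>%
        summarise(u_k = if (dplyr::n() < min_unique) Inf
                  else sort(.data$u)[min_unique],
                  .groups = "drop") %>%
        mutate(rep = r)
    })
    purrr::map_dfr(insertions$id, function(ins) {
      uk <- thr$u_k[thr$insertion_id == ins]
      if (length(uk) == 0L) uk <- rep(Inf, reps)
      tibble(id = ins, depth = grid,
             p = vapply(grid, function(s) mean(uk <= s), numeric(1)))
    })
  })
}

#' Sensitivity-corrected de novo insertion rate
#'
#' Corrects the observed de novo insertion count of a cell line for
#' detection sensitivity. Each observed insertion `i` contributes
#' `1 / p_bar_i`, where `p_bar_i` is its mean detection probability over the
#' sampling-depth (equivalently VAF) grid from `vaf_floor` to 100%,
#' multiplied by the baseline detection rate `1 - fn_baseline`. Insertions
#' carried by fewer than `vaf_floor` of cells are outside the model and are
#' not represented. The per-cell extrapolation multiplies the corrected
#' per-line count by the mean VAF of the observed insertions (an insertion
#' at VAF `v` is carried by a fraction `v` of cells); it is model-dependent
#' and labelled as such in the output.
#'
#' @param observed Tibble of observed de novo insertions with columns `id`
#'   and `vaf`.
#' @param curves Per-insertion detection curves from
#'   [insertion_detection_curves()].
#' @param vaf_floor Smallest VAF considered (fraction).
#' @param fn_baseline Baseline overall false-negative rate (fraction).
#' @return Object of class `rate_estimate`: a list with `observed_n`,
#'   `corrected_per_line`, `per_cell`, `mean_vaf`, `vaf_floor`,
#'   `fn_baseline`, `excluded` and `per_insertion` (tibble `id`, `vaf`,
#'   `p_bar`, `weight`).
#' @export
estimate_insertion_rate <- function(observed, curves, vaf_floor = 0.05,
                                    fn_baseline = 0) {
  assert_fraction(vaf_floor, "vaf_floor")
  per_ins <- curves %>%
    filter(.data$depth >= vaf_floor) %>%
    group_by(.data$id) %>%
    summarise(p_bar = mean(.data$p) * (1 - fn_baseline), .groups = "drop")
  obs <- left_join(observed, per_ins, by = "id")
  excluded <- obs$id[is.na(obs$p_bar) | obs$p_bar <= 0]
  if (length(excluded) > 0L) {
    warn(sprintf("excluding %d insertion(s) with zero detection probability: %s",
                 length(excluded), paste(excluded, collapse = ", ")))
  }
  obs <- filter(obs, !.data$id %in% excluded)
  corrected <- sum(1 / obs$p_bar)
  mean_vaf <- if (nrow(obs) > 0L) mean(obs$vaf) else NA_real_
  structure(list(observed_n = nrow(observed),
                 corrected_per_line = corrected,
                 per_cell = corrected * mean_vaf,
                 mean_vaf = mean_vaf, vaf_floor = vaf_floor,
                 fn_baseline = fn_baseline, excluded = excluded,
                 per_insertion = mutate(obs, weight = 1 / .data$p_bar)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(paste0("<rate_estimate> %d observed de novo insertion(s)\n",
                     "  corrected per line (VAF >= %.0f%%): %.2f\n",
                     "  per cell (VAF-weighted model):      %.2f\n"),
              x$observed_n, 100 * x$vaf_floor, x$corrected_per_line,
              x$per_cell))
  invisible(x)
}

#' @rdname estimate_insertion_rate
#' @param x A `rate_estimate`.
#' @param ... Unused.
#' @export
glance.rate_estimate <- function(x, ...) {
  tibble(observed_n = x$observed_n,
         corrected_per_line = x$corrected_per_line,
         per_cell = x$per_cell, mean_vaf = x$mean_vaf,
         vaf_floor = x$vaf_floor, fn_baseline = x$fn_baseline,
         n_excluded = length(x$excluded))
}

#' @rdname estimate_insertion_rate
#' @export
tidy.rate_estimate <- function(x, ...) x$per_insertion
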