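# Positional bias of intragenic insertions: percentile-of-gene-length
# statistic (measured from the TSS) and its permutation test.

#' Percentile of gene length for intragenic insertions
#'
#' Position of each insertion within its host gene as a percentage of gene
#' length measured from the transcription start site: 0 at the TSS, 100 at
#' the 3' end. Plus-strand genes: `100 * (pos - start) / (end - start)`;
#' minus-strand genes: `100 * (end - 1 - pos) / (end - start)`. An insertion
#' overlapping several genes contributes its minimum (most 5') percentile,
#' and a message reports how often that rule fired.
#'
#' @param insertions Tibble with columns `chrom` and `pos` (0-based), plus
#'   an optional `id`.
#' @param genes Gene-model tibble with `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based, half-open).
#' @param intergenic How to treat insertions outside every gene: `"error"`
#'   (default) or `"drop"`.
#' @return Tibble: `id`, `gene_id`, `percentile` (in `[0, 100]`).
#' @export
#' @examples
#' genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 0L,
#'                         end = 100L, strand = "+")
#' gene_percentile(tibble::tibble(chrom = "chr1", pos = 50L), genes)
gene_percentile <- function(insertions, genes, intergenic = c("error", "drop")) {
  intergenic <- match.arg(intergenic)
  ids <- if ("id" %in% names(insertions)) insertions$id
         else sprintf("ins%03d", seq_len(nrow(insertions)))
  multi <- 0L
  out <- purrr::map_dfr(seq_len(nrow(insertions)), function(i) {
    pos <- insertions$pos[i]
    hit <- genes[genes$chrom == insertions$chrom[i] &
                   genes$start <= pos & pos < genes$end, , drop = FALSE]
    if (nrow(hit) == 0L) {
      if (intergenic == "error") {
        abort(sprintf("insertion %s at %s:%d lies outside every gene",
                      ids[i], insertions$chrom[i], pos))
      }
      return(NULL)
    }
    pct <- ifelse(hit$strand == "+",
                  100 * (pos - hit$start) / (hit$end - hit$start),
                  100 * (hit$end - 1 - pos) / (hit$end - hit$start))
    pct <- pmin(pmax(pct, 0), 100)
    if (nrow(hit) > 1L) multi <<- multi + 1L
    j <- which.min(pct)
    tibble(id = ids[i], gene_id = hit$gene_id[j], percentile = pct[j])
  })
  if (multi > 0L) {
    inform(sprintf("%d insertion(s) overlapped multiple genes; minimum percentile used",
                   multi))
  }
  out
}

# Vectorized null draw: n positions uniform over the intragenic genome
# (gene chosen proportionally to its length, position uniform within the
# gene), returned as percentiles from the TSS.
sample_null_percentiles <- function(n, genes, per_gene = FALSE) {
  len <- genes$end - genes$start
  gi <- if (per_gene) {
    sample.int(nrow(genes), n, replace = TRUE)
  } else {
    sample.int(nrow(genes), n, replace = TRUE, prob = len)
  }
  off <- floor(runif(n) * len[gi])  # 0-based offset within gene
  ifelse(genes$strand[gi] == "+",
         100 * off / len[gi],
         100 * (len[gi] - 1 - off) / len[gi])
}

#' Empirical permutation p-value
#'
#' The exceedance rule used by [permutation_test()]: with `k` permutations
#' at or beyond the observed statistic out of `n_perm`, the empirical
#' p-value is `k / n_perm`.
#'
#' @param k Exceedance count.
#' @param n_perm Number of permutations.
#' @return The empirical p-value.
#' @export
#' @examples
#' perm_pvalue(6, 1000)
perm_pvalue <- function(k, n_perm) {
  if (n_perm < 1) abort("`n_perm` must be at least 1")
  if (k < 0 || k > n_perm) abort("`k` must lie in [0, n_perm]")
  k / n_perm
}

#' Permutation test for 5' positional bias within genes
#'
#' Tests whether intragenic insertions sit closer to transcription start
#' sites than random expectation. Each permutation draws the same number of
#' positions uniformly over the intragenic genome (gene sampled with
#' probability proportional to its length, position uniform within the
#' gene; set `null = "per_gene"` to weight genes equally instead), computes
#' the mean percentile from the TSS, and counts an exceedance when the
#' permuted mean is less than or equal to the observed mean. The p-value is
#' the exceedance fraction `k / N`.
#'
#' @param insertions Tibble of intragenic insertions (`chrom`, `pos`), or a
#'   numeric vector of precomputed percentiles.
#' @param genes Gene models (see [gene_percentile()]).
#' @param n_perm Number of permutations.
#' @param null Null model for gene choice: `"length_weighted"` (uniform over
#'   intragenic bases) or `"per_gene"` (uniform over genes).
#' @param seed Optional integer seed.
#' @param keep_null Maximum number of permuted means retained for plotting.
#' @return Object of class `permutation_result`: list with `observed_mean`,
#'   `n`, `n_perm`, `k` (exceedances), `p_value`, `percentiles` and
#'   `null_means` (possibly subsampled).
#' @export
permutation_test <- function(insertions, genes, n_perm = 1e6,
                             null = c("length_weighted", "per_gene"),
                             seed = NULL, keep_null = 1e5) {
  null <- match.arg(null)
  if (n_perm < 1) abort("`n_perm` must be at least 1")
  if (nrow(genes) == 0L) abort("gene annotation is empty")
  pct <- if (is.numeric(insertions)) {
    insertions
  } else {
    gene_percentile(insertions, genes)$percentile
  }
  n <- length(pct)
  if (n < 1L) abort("need at least one intragenic insertion")
  observed <- mean(pct)
  with_seed_if(seed, {
    # draw in blocks to bound memory at ~1e7 values
    block <- max(1L, floor(1e7 / n))
    k <- 0
    kept <- numeric(0)
    done <- 0
    while (done < n_perm) {
      b <- min(block, n_perm - done)
      draws <- sample_null_percentiles(n * b, genes, per_gene = null == "per_gene")
      means <- colMeans(matrix(draws, nrow = n))
      k <- k + sum(means <= observed)
      if (length(kept) < keep_null) {
        kept <- c(kept, utils::head(means, keep_null - length(kept)))
      }
      done <- done + b
    }
    structure(list(observed_mean = observed, n = n, n_perm = n_perm,
                   k = k, p_value = perm_pvalue(k, n_perm), percentiles = pct,
                   null_means = kept, null = null),
              class = "permutation_result")
  })
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("<permutation_result> n = %d intragenic insertion(s)\n",
                     "  observed mean percentile: %.1f\n",
                     "  permutations: %s, exceedances: %s, p = %.4g\n"),
              x$n, x$observed_mean,
              format(x$n_perm, big.mark = ","),
              format(x$k, big.mark = ","), x$p_value))
  invisible(x)
}

#' @rdname permutation_test
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @export
glance.permutation_result <- function(x, ...) {
  tibble(observed_mean = x$observed_mean, n = x$n, n_perm = x$n_perm,
         k = x$k, p_value = x$p_value, null = x$null)
}

#' @rdname permutation_test
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(percentile = x$percentiles)
}
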