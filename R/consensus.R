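# Synthetic retrotransposon consensus library.
#
# Real consensus sequences (L1.3, AluY, SVA, LTR5_Hs) are thousands of bases
# and carry subfamily-diagnostic substitutions. For an offline, self-contained
# toolkit we build *synthetic* stand-ins: one random backbone per family, with
# diagnostic bases forced at fixed positions to distinguish subfamilies
# (L1-Ta vs L1-preTa, AluYa5 vs AluYb8). Lengths are scaled down from the real
# elements so that alignments stay fast; the structural logic downstream
# (truncation offsets, inversions, poly-A tails) is length-agnostic.

# Diagnostic base sets per subfamily; positions are drawn deterministically
# inside consensus_library().
SUBFAMILY_TABLE <- list(
  L1  = list(subfamilies = c("L1-Ta", "L1-preTa"), n_diag = 6L),
  Alu = list(subfamilies = c("AluYa5", "AluYb8"),  n_diag = 6L),
  SVA = list(subfamilies = "SVA_E",                n_diag = 0L),
  LTR = list(subfamilies = "LTR5",                 n_diag = 0L)
)

#' Build the synthetic retrotransposon consensus library
#'
#' Generates deterministic synthetic consensus sequences for the four probed
#' retrotransposon families (L1, Alu, SVA, LTR) and their active subfamilies
#' (L1-Ta, L1-preTa, AluYa5, AluYb8, SVA_E). Subfamilies of one family share a
#' backbone and differ only at diagnostic positions, which is what the
#' subfamily classifier keys on. Sequences end in a non-A trinucleotide so the
#' appended poly-A tail of a planted insertion has a well-defined start.
#'
#' @param lengths Named integer vector of consensus lengths per family.
#'   Defaults are scaled-down relative to the real elements (L1 ~6 kb,
#'   Alu ~300 b, SVA ~1.5 kb, LTR ~1 kb) to keep alignment fast.
#' @param seed Integer seed fixing the library; the same seed always yields
#'   byte-identical sequences.
#'
#' @return A tibble of class `consensus_library` with columns `family`,
#'   `subfamily`, `length` and `sequence`, and an attribute `diagnostics`
#'   (tibble of `subfamily`, `position` (0-based), `base`).
#' @export
#' @examples
#' lib <- consensus_library()
#' lib$subfamily
consensus_library <- function(lengths = c(L1 = 1500L, Alu = 300L, SVA = 700L, LTR = 400L),
                              seed = 7001L) {
  stopifnot(all(names(SUBFAMILY_TABLE) %in% names(lengths)))
  with_seed_if(seed, {
    rows <- list()
    diags <- list()
    for (fam in names(SUBFAMILY_TABLE)) {
      len <- as.integer(lengths[[fam]])
      backbone <- strsplit(random_dna(len, gc = 0.45), "")[[1]]
      # guarantee a non-A 3' terminus so planted poly-A tails are delimited
      backbone[(len - 2L):len] <- c("G", "C", "G")
      info <- SUBFAMILY_TABLE[[fam]]
      if (info$n_diag > 0L) {
        pos <- sort(sample(seq(10L, len - 20L), info$n_diag))
        for (i in seq_along(info$subfamilies)) {
          sub <- info$subfamilies[i]
          seq_chars <- backbone
          # each subfamily gets its own base at every diagnostic position
          bases <- vapply(pos, function(p) {
            setdiff(DNA_BASES, backbone[p])[i]
          }, character(1))
          seq_chars[pos] <- bases
          rows[[sub]] <- tibble(family = fam, subfamily = sub, length = len,
                                sequence = paste(seq_chars, collapse = ""))
          diags[[sub]] <- tibble(subfamily = sub, position = pos - 1L, base = bases)
        }
      } else {
        sub <- info$subfamilies
        rows[[sub]] <- tibble(family = fam, subfamily = sub, length = len,
                              sequence = paste(backbone, collapse = ""))
      }
    }
    lib <- bind_rows(rows)
    attr(lib, "diagnostics") <- bind_rows(diags)
    class(lib) <- c("consensus_library", class(lib))
    lib
  })
}

consensus_of <- function(library, subfamily) {
  row <- library[library$subfamily == subfamily, ]
  if (nrow(row) == 0L) abort(sprintf("unknown subfamily '%s'", subfamily))
  row$sequence[[1]]
}

family_of <- function(library, subfamily) {
  row <- library[library$subfamily == subfamily, ]
  if (nrow(row) == 0L) abort(sprintf("unknown subfamily '%s'", subfamily))
  row$family[[1]]
}

subfamilies_of <- function(library, family) {
  library$subfamily[library$family == family]
}
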