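# Simulation configuration: the knobs that define a synthetic study.

#' Per-family insertion simulation settings
#'
#' Describes how insertions of one retrotransposon family are planted:
#' how many, how often they are full length, twin-primed or endonuclease
#' independent, and the ranges for target site duplications and poly-A tails.
#'
#' @param name Family name; one of `"L1"`, `"Alu"`, `"SVA"`, `"LTR"`.
#' @param n Number of insertions of this family to plant.
#' @param full_length_fraction Fraction of insertions with no 5' truncation.
#'   De novo L1 insertions in pluripotent cells are unusually often full
#'   length (about half), unlike the heavily truncated genomic L1 complement.
#' @param twin_priming_fraction Of the 5'-truncated insertions, the fraction
#'   that additionally carry a twin-priming inversion.
#' @param en_independent_fraction Fraction of insertions integrated without an
#'   L1 endonuclease motif at the target site (typically at preexisting DNA
#'   lesions); these sites are drawn uniformly rather than at motif matches.
#' @param tsd_length_range Range (bases) of target site duplication lengths.
#' @param polya_length_range Range (bases) of poly-A tail lengths.
#' @param untemplated_nt_probability Probability that an insertion carries
#'   one or two untemplated G nucleotides at its 5' junction.
#' @param spacer_length Length (bases) of the random-sequence fragment placed
#'   between the inverted 5' segment and the element body in twin-priming
#'   events.
#'
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(name,
                        n = 10L,
                        full_length_fraction = if (name == "L1") 0.55 else 1,
                        twin_priming_fraction = if (name == "L1") 0.5 else 0,
                        en_independent_fraction = 0.1,
                        tsd_length_range = c(4L, 20L),
                        polya_length_range = c(10L, 60L),
                        untemplated_nt_probability = if (name == "L1") 0.2 else 0,
                        spacer_length = 25L) {
  stopifnot(name %in% names(SUBFAMILY_TABLE))
  assert_fraction(full_length_fraction, "full_length_fraction")
  assert_fraction(twin_priming_fraction, "twin_priming_fraction")
  assert_fraction(en_independent_fraction, "en_independent_fraction")
  assert_fraction(untemplated_nt_probability, "untemplated_nt_probability")
  assert_range(tsd_length_range, "tsd_length_range")
  assert_range(polya_length_range, "polya_length_range")
  structure(list(name = name, n = as.integer(n),
                 full_length_fraction = full_length_fraction,
                 twin_priming_fraction = twin_priming_fraction,
                 en_independent_fraction = en_independent_fraction,
                 tsd_length_range = as.integer(tsd_length_range),
                 polya_length_range = as.integer(polya_length_range),
                 untemplated_nt_probability = untemplated_nt_probability,
                 spacer_length = as.integer(spacer_length)),
            class = "family_spec")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator: the toy genome, the
#' per-family insertion specs, and the capture-library emulation parameters.
#' A fixed seed makes all downstream outputs byte-identical.
#'
#' @param genome_length Total genome length in bases, split evenly across
#'   chromosomes.
#' @param n_chromosomes Number of chromosomes.
#' @param n_genes Number of non-overlapping gene models to annotate.
#' @param gene_length_range Range (bases) of gene lengths.
#' @param gc_content Genome GC fraction.
#' @param families List of [family_spec()] objects.
#' @param vaf Default variant allele fraction of planted insertions, the
#'   fraction of cells carrying the insertion; in `(0, 1]`.
#' @param depth Expected junction-spanning amplicons per junction per
#'   haplotype at `vaf = 1`.
#' @param duplicate_rate Fraction of emitted reads that are PCR duplicates of
#'   another read.
#' @param germline_fraction Fraction of planted insertions labelled as
#'   germline (written to the known-insertion catalog) rather than de novo.
#' @param jitter Half-width (bases) of the uniform window over which amplicon
#'   alignment starts scatter around a junction.
#' @param read_length Amplicon length in bases.
#' @param seed Integer seed; fixes every random choice of the generator.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 2e5, n_genes = 5,
#'                   families = list(family_spec("L1", n = 5)))
sim_config <- function(genome_length = 1e6,
                       n_chromosomes = 2L,
                       n_genes = 30L,
                       gene_length_range = c(5e3, 3e4),
                       gc_content = 0.41,
                       families = list(
                         family_spec("L1", n = 21L),
                         family_spec("Alu", n = 60L),
                         family_spec("SVA", n = 5L),
                         family_spec("LTR", n = 2L)
                       ),
                       vaf = 1,
                       depth = 20,
                       duplicate_rate = 0.15,
                       germline_fraction = 0.8,
                       jitter = 30L,
                       read_length = 150L,
                       seed = 1L) {
  assert_fraction(gc_content, "gc_content")
  assert_fraction(vaf, "vaf", allow_zero = FALSE)
  assert_fraction(duplicate_rate, "duplicate_rate")
  assert_fraction(germline_fraction, "germline_fraction")
  assert_range(gene_length_range, "gene_length_range")
  if (depth <= 0) abort("`depth` must be positive")
  stopifnot(vapply(families, inherits, logical(1), "family_spec"))
  if (n_genes > 0 &&
      n_genes * mean(gene_length_range) > 0.9 * genome_length) {
    abort("gene demand exceeds genome capacity: reduce `n_genes` or gene lengths")
  }
  structure(list(genome_length = as.numeric(genome_length),
                 n_chromosomes = as.integer(n_chromosomes),
                 n_genes = as.integer(n_genes),
                 gene_length_range = as.numeric(gene_length_range),
                 gc_content = gc_content,
                 families = families,
                 vaf = vaf, depth = depth,
                 duplicate_rate = duplicate_rate,
                 germline_fraction = germline_fraction,
                 jitter = as.integer(jitter),
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}
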