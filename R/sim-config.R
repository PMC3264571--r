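#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' Defaults describe a small pooled mRNA-seq study: three breed pools
#' sequenced as 75-bp paired reads of ~150-bp fragments, fixed substitutions
#' between breeds (half of them inside coding sequence), within-breed
#' polymorphic sites with minor-allele fractions straddling the 10 % caller
#' threshold, and base qualities straddling Q20.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene integer range `c(min, max)` of exons per gene.
#' @param exon_len,intron_len integer ranges (bp).
#' @param utr5_len integer range (bp) of the 5' UTR carved from each
#'   transcript before the ATG.
#' @param n_breeds number of breed pools.
#' @param n_fixed_diffs total fixed between-breed substitutions to spike;
#'   each alters exactly one breed's haplotype.
#' @param frac_coding_diffs fraction of fixed differences placed inside CDS.
#' @param n_within_snps within-breed polymorphic sites per breed.
#' @param minor_allele_fracs minor-allele fractions cycled over the
#'   within-breed sites; values must lie in (0, 0.5].
#' @param two_isoform_frac fraction of genes given a second isoform that
#'   shares the TSS and skips one internal exon.
#' @param usage_base baseline isoform-usage vector for two-isoform genes.
#' @param usage_shift alternative usage vector applied in the last breed to
#'   the first `n_usage_shift` two-isoform genes.
#' @param n_usage_shift number of genes with a between-breed usage shift.
#' @param expr_profile optional numeric matrix (genes x breeds) of relative
#'   expression multipliers; default all 1.
#' @param depth mean fragment coverage per transcribed base.
#' @param read_len,frag_len read and fragment lengths (bp);
#'   `read_len <= frag_len` is required and `frag_len <= 2*read_len` keeps
#'   fragment coverage gap-free.
#' @param error_rate per-base sequencing error probability.
#' @param qual_high,qual_low Phred qualities; one must be >= 20 and the
#'   other < 20 so the Q20 filter separates them.
#' @param intergenic_gap bp between consecutive gene loci.
#' @param n_unannotated_far,n_unannotated_near counts of unannotated
#'   transcribed intervals placed >= 1000 bp and < 1000 bp from genes, to
#'   exercise the intergenic rule.
#' @param seed integer RNG seed (< 2^31 - 16; the generator derives
#'   per-stage seeds by small offsets).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20L,
                       exons_per_gene = c(2L, 5L),
                       exon_len = c(90L, 240L),
                       intron_len = c(60L, 200L),
                       utr5_len = c(12L, 36L),
                       n_breeds = 3L,
                       n_fixed_diffs = 30L,
                       frac_coding_diffs = 0.5,
                       n_within_snps = 30L,
                       minor_allele_fracs = c(0.05, 0.08, 0.15, 0.20, 0.30, 0.50),
                       two_isoform_frac = 0.5,
                       usage_base = c(0.9, 0.1),
                       usage_shift = c(0.4, 0.6),
                       n_usage_shift = 0L,
                       expr_profile = NULL,
                       depth = 50,
                       read_len = 75L,
                       frag_len = 150L,
                       error_rate = 0,
                       qual_high = 30L,
                       qual_low = 15L,
                       intergenic_gap = 2000L,
                       n_unannotated_far = 0L,
                       n_unannotated_near = 0L,
                       seed = 1L) {
  rng <- function(x, nm) {
    if (length(x) == 1L) x <- c(x, x)
    if (length(x) != 2L || x[2] < x[1] || x[1] < 1)
      stop("configuration error: invalid range for ", nm)
    as.integer(x)
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    exons_per_gene = rng(exons_per_gene, "exons_per_gene"),
    exon_len = rng(exon_len, "exon_len"),
    intron_len = rng(intron_len, "intron_len"),
    utr5_len = rng(utr5_len, "utr5_len"),
    n_breeds = as.integer(n_breeds),
    breeds = paste0("breed", seq_len(n_breeds)),
    n_fixed_diffs = as.integer(n_fixed_diffs),
    frac_coding_diffs = frac_coding_diffs,
    n_within_snps = as.integer(n_within_snps),
    minor_allele_fracs = minor_allele_fracs,
    two_isoform_frac = two_isoform_frac,
    usage_base = usage_base / sum(usage_base),
    usage_shift = usage_shift / sum(usage_shift),
    n_usage_shift = as.integer(n_usage_shift),
    expr_profile = expr_profile,
    depth = depth,
    read_len = as.integer(read_len),
    frag_len = as.integer(frag_len),
    error_rate = error_rate,
    qual_high = as.integer(qual_high),
    qual_low = as.integer(qual_low),
    intergenic_gap = as.integer(intergenic_gap),
    n_unannotated_far = as.integer(n_unannotated_far),
    n_unannotated_near = as.integer(n_unannotated_near),
    seed = as.integer(seed))

  if (cfg$n_genes < 1L) stop("configuration error: n_genes must be >= 1")
  if (cfg$n_breeds < 1L) stop("configuration error: n_breeds must be >= 1")
  if (cfg$frac_coding_diffs < 0 || cfg$frac_coding_diffs > 1)
    stop("configuration error: frac_coding_diffs must be in [0, 1]")
  if (any(cfg$minor_allele_fracs <= 0 | cfg$minor_allele_fracs > 0.5))
    stop("configuration error: minor_allele_fracs must lie in (0, 0.5]")
  if (cfg$depth <= 0) stop("configuration error: depth must be > 0")
  if (cfg$read_len > cfg$frag_len)
    stop("configuration error: read_len must be <= frag_len")
  if (cfg$error_rate < 0 || cfg$error_rate > 1)
    stop("configuration error: error_rate must be in [0, 1]")
  if (!xor(cfg$qual_high >= 20L, cfg$qual_low >= 20L) && cfg$qual_high != cfg$qual_low)
    stop("configuration error: one quality must be >= 20, the other < 20")
  if (cfg$qual_high < 20L || cfg$qual_low >= 20L)
    stop("configuration error: need qual_high >= 20 and qual_low < 20")
  if (abs(sum(cfg$usage_base) - 1) > 1e-9 || abs(sum(cfg$usage_shift) - 1) > 1e-9)
    stop("configuration error: usage vectors must sum to 1")
  if (cfg$seed >= 2^31 - 16 || cfg$seed < 0)
    stop("configuration error: seed out of range")
  if (!is.null(expr_profile)) {
    expr_profile <- as.matrix(expr_profile)
    if (nrow(expr_profile) != cfg$n_genes || ncol(expr_profile) != cfg$n_breeds)
      stop("configuration error: expr_profile must be n_genes x n_breeds")
    cfg$expr_profile <- expr_profile
  }
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,", x$n_breeds, "breeds,",
      x$n_fixed_diffs, "fixed diffs,", x$n_within_snps,
      "within-SNPs/breed, depth", x$depth, "x, seed", x$seed, "\n")
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()].
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$expr_profile))
    vals$expr_profile <- matrix(unlist(vals$expr_profile),
                                nrow = vals$n_genes, byrow = TRUE)
  do.call(sim_config, vals)
}
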