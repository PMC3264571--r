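# Count-level synthetic screens for statistical calibration and power.

#' Simulate a differential-expression screen at count level
#'
#' Draws per-gene Poisson fragment counts for two libraries; a fraction of
#' genes carries a true fold change.  The baseline per-gene mean is
#' `depth * gene_len / frag_len` fragments, the scale implied by uniform
#' fragment coverage.
#'
#' @param n_genes number of genes.
#' @param frac_shifted fraction of genes with a true shift.
#' @param fold true fold change of shifted genes (library B over A).
#' @param depth mean fragment coverage.
#' @param gene_len transcript length in bp.
#' @param frag_len fragment length in bp.
#' @param lib_size library size used as offset for both libraries.
#' @param seed RNG seed.
#' @return list: `count_a`, `count_b`, `shifted` (logical), `lib_size`.
#' @export
simulate_de_screen <- function(n_genes = 200L, frac_shifted = 0.5,
                               fold = 4, depth = 30, gene_len = 600L,
                               frag_len = 150L, lib_size = 1e6, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  mu <- depth * gene_len / frag_len
  shifted <- seq_len(n_genes) <= round(frac_shifted * n_genes)
  count_a <- stats::rpois(n_genes, mu)
  count_b <- stats::rpois(n_genes, mu * ifelse(shifted, fold, 1))
  list(count_a = count_a, count_b = count_b, shifted = shifted,
       lib_size = lib_size)
}

#' Simulate a differential isoform-usage screen at count level
#'
#' Draws multinomial isoform counts for two breeds per gene; a fraction of
#' genes uses `usage_b` in the second breed, the rest share `usage_a`.
#'
#' @param n_genes number of genes.
#' @param frac_shifted fraction with a true usage shift.
#' @param usage_a,usage_b isoform-usage probability vectors.
#' @param n_frag fragments per gene per breed.
#' @param seed RNG seed.
#' @return list: `counts` (named list of 2-row matrices, for
#'   [diff_splicing_screen()]), `shifted` (logical).
#' @export
simulate_usage_screen <- function(n_genes = 100L, frac_shifted = 0.5,
                                  usage_a = c(0.9, 0.1),
                                  usage_b = c(0.4, 0.6),
                                  n_frag = 200L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  shifted <- seq_len(n_genes) <= round(frac_shifted * n_genes)
  counts <- lapply(seq_len(n_genes), function(i) {
    ua <- usage_a
    ub <- if (shifted[i]) usage_b else usage_a
    rbind(as.vector(stats::rmultinom(1, n_frag, ua)),
          as.vector(stats::rmultinom(1, n_frag, ub)))
  })
  names(counts) <- sprintf("gene%04d", seq_len(n_genes))
  list(counts = counts, shifted = shifted)
}
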