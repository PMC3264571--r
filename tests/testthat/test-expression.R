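# two-isoform gene: tA = exons [0,100)+[200,300)+[400,500),
# tB skips the middle exon
two_iso_ann <- pair_annotation(rbind(c(0, 100), c(200, 300), c(400, 500)),
                               rbind(c(0, 100), c(400, 500)),
                               contig = "chr1")

test_that("fragment compatibility follows exon containment and junction match", {
  sam <- write_test_sam(list(
    c("shared", "0", "1", "50M", strrep("A", 50), strrep("?", 50)),
    c("junc_skip", "0", "81", "20M300N20M", strrep("A", 40), strrep("?", 40)),
    c("junc_incl", "0", "81", "20M100N20M", strrep("A", 40), strrep("?", 40)),
    c("intronic", "0", "131", "40M", strrep("A", 40), strrep("?", 40))))
  cc <- count_compatible_fragments(sam, two_iso_ann)
  cls <- stats::setNames(cc$classes$count, cc$classes$isoforms)
  expect_equal(unname(cls[["tA|tB"]]), 1L)   # fully inside the shared exon
  expect_equal(unname(cls[["tB"]]), 1L)      # uses the skipping junction
  expect_equal(unname(cls[["tA"]]), 1L)      # uses the inclusion junction
  expect_equal(cc$n_unassigned, 1L)          # overlaps an intron of both
  expect_equal(cc$library_size, 4L)
})

test_that("EM abundance matches closed forms and conserves counts", {
  # unambiguous two-isoform counts 5 vs 15 with equal lengths
  compat <- list(classes = data.table::data.table(
    gene = "g", isoforms = c("tA", "tB"), count = c(5L, 15L)),
    library_size = 1e6)
  eq_ann <- pair_annotation(rbind(c(0, 1000)), rbind(c(2000, 3000)))
  ab <- em_isoform_abundance(compat, eq_ann)
  expect_equal(ab$count, c(5, 15))
  expect_equal(ab$count / sum(ab$count), c(0.25, 0.75))

  # symmetric ambiguous classes ({A},4), ({B},4), ({A,B},8) -> (8, 8)
  compat2 <- list(classes = data.table::data.table(
    gene = "g", isoforms = c("tA", "tB", "tA|tB"), count = c(4L, 4L, 8L)),
    library_size = 16)
  ab2 <- em_isoform_abundance(compat2, eq_ann)
  expect_equal(ab2$count, c(8, 8), tolerance = 1e-6)

  # count conservation on an asymmetric case
  compat3 <- list(classes = data.table::data.table(
    gene = "g", isoforms = c("tA", "tB", "tA|tB"), count = c(10L, 2L, 7L)),
    library_size = 19)
  ab3 <- em_isoform_abundance(compat3, eq_ann)
  expect_equal(sum(ab3$count), 19, tolerance = 1e-6)

  # single isoform, 10 fragments, l = 2000, N = 1e6 -> FPKM 5
  ann1 <- tx_annotation(
    data.frame(transcript_id = "t", gene_id = "g", contig = "c", strand = "+"),
    data.frame(transcript_id = "t", start = 0L, end = 2000L))
  ab4 <- em_isoform_abundance(list(classes = data.table::data.table(
    gene = "g", isoforms = "t", count = 10L), library_size = 1e6), ann1)
  expect_equal(ab4$fpkm, 5)

  # zero fragments: all-zero abundances, no division error
  ab5 <- em_isoform_abundance(list(classes = data.table::data.table(
    gene = character(), isoforms = character(), count = integer()),
    library_size = 1e6), eq_ann)
  expect_equal(ab5$fpkm, c(0, 0))
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(42)
  for (rep in 1:20) {
    K <- sample(2:4, 1)
    txs <- paste0("t", seq_len(K))
    n_cls <- sample(2:5, 1)
    sets <- lapply(seq_len(n_cls), function(i)
      sort(sample(txs, sample.int(K, 1))))
    A <- matrix(FALSE, n_cls, K, dimnames = list(NULL, txs))
    for (i in seq_len(n_cls)) A[i, sets[[i]]] <- TRUE
    ncl <- sample(1:50, n_cls, replace = TRUE)
    alpha <- rep(1 / K, K)
    ll_prev <- -Inf
    for (it in 1:50) {
      denom <- as.vector(A %*% alpha)
      ll <- sum(ncl * log(denom))
      expect_gte(ll, ll_prev - 1e-9)
      ll_prev <- ll
      W <- A * rep(alpha, each = n_cls) / denom
      alpha <- colSums(W * ncl) / sum(ncl)
    }
  }
})

test_that("FPKM is invariant to doubling every count and the library size", {
  eq_ann <- pair_annotation(rbind(c(0, 1000)), rbind(c(2000, 3000)))
  mk <- function(f) em_isoform_abundance(list(
    classes = data.table::data.table(gene = "g", isoforms = c("tA", "tB"),
                                     count = c(30L, 50L) * f),
    library_size = 1e5 * f), eq_ann)
  expect_equal(mk(1L)$fpkm, mk(2L)$fpkm)
})

test_that("upper-quartile normalization matches the interpolated order statistic", {
  expect_equal(unname(upper_quartile_normalize(cbind(a = c(1, 2, 3, 4)))$
                        scale_factors), 3.25)
  m <- cbind(a = c(10, 20, 30, 40), b = c(10, 20, 30, 40))
  expect_equal(upper_quartile_normalize(m)$normalized, m)
  # a doubled column normalizes back onto the other
  m2 <- cbind(a = c(10, 20, 30, 40), b = 2 * c(10, 20, 30, 40))
  nn <- upper_quartile_normalize(m2)$normalized
  expect_equal(nn[, "a"], nn[, "b"], ignore_attr = TRUE)
  # zeroes are excluded from the quantile; all-zero columns error
  expect_equal(unname(upper_quartile_normalize(
    cbind(a = c(0, 0, 1, 2, 3, 4)))$scale_factors), 3.25)
  expect_error(upper_quartile_normalize(cbind(a = c(1, 2), b = c(0, 0))),
               "all-zero")
})

test_that("the Poisson LRT matches hand computation and handles zeros", {
  r <- de_test(100, 100, 1e6, 1e6)
  expect_equal(r$log2fc, 0); expect_equal(r$p, 1)
  r <- de_test(100, 200, 1e6, 1e6)
  stat <- 2 * (100 * log(100 / 150) + 200 * log(200 / 150))
  expect_equal(stat, 33.97981, tolerance = 1e-5)
  expect_equal(r$p, stats::pchisq(stat, 1, lower.tail = FALSE))
  r <- de_test(0, 0, 1e6, 1e6)
  expect_equal(r$p, 1); expect_equal(r$log2fc, 0)
  # 0 vs 50 is significant after FDR inside a null background
  set.seed(1)
  a <- c(0, rpois(99, 100)); b <- c(50, rpois(99, 100))
  r <- de_test(a, b, 1e6, 1e6)
  expect_true(r$significant[1])
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(c(0.005, 0.04, 0.5)), c(0.015, 0.06, 0.5))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  p <- c(0.01, 0.02, 0.3, 0.6)
  expect_true(all(bh_fdr(p) >= p))
})

test_that("breed-specific detection requires exactly one detected breed", {
  fpkm <- rbind(g1 = c(5, 0, 0), g2 = c(5, 5, 5), g3 = c(0, 0, 0.2))
  colnames(fpkm) <- c("b1", "b2", "b3")
  r <- detect_breed_specific(fpkm, 0)
  expect_equal(r$specific$b1, "g1")
  expect_equal(r$specific$b3, "g3")
  expect_setequal(r$detected$b1, c("g1", "g2"))
  r2 <- detect_breed_specific(fpkm, 0.5)
  expect_equal(r2$specific$b3, character(0))
})
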