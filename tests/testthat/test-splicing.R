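test_that("single-TSS selection requires strict TSS equality and >= 2 isoforms", {
  # shared TSS
  ann <- pair_annotation(rbind(c(0, 100), c(200, 300)),
                         rbind(c(0, 100), c(250, 300)))
  expect_equal(single_tss_multi_isoform(ann)$genes, "g")
  # TSS differing by 1 bp
  ann2 <- pair_annotation(rbind(c(0, 100), c(200, 300)),
                          rbind(c(1, 100), c(200, 300)))
  expect_equal(single_tss_multi_isoform(ann2)$genes, character(0))
  # single isoform
  ann3 <- tx_annotation(
    data.frame(transcript_id = "t1", gene_id = "g", contig = "c", strand = "+"),
    data.frame(transcript_id = "t1", start = 0L, end = 100L))
  expect_equal(single_tss_multi_isoform(ann3)$genes, character(0))
  # on the minus strand the TSS is the rightmost exon end
  ann4 <- pair_annotation(rbind(c(0, 100), c(200, 300)),
                          rbind(c(10, 100), c(200, 300)), strand = "-")
  expect_equal(single_tss_multi_isoform(ann4)$genes, "g")
})

test_that("the six event categories classify on hand-built cases", {
  ev <- function(exA, exB, strand = "+")
    classify_events(pair_annotation(exA, exB, strand), genes = "g")
  r <- ev(rbind(c(0, 100), c(200, 300), c(400, 500)),
          rbind(c(0, 100), c(400, 500)))
  expect_equal(r$category, "exon_skipping")
  expect_equal(r$coords, "201-300")
  r <- ev(rbind(c(0, 100), c(200, 300)), rbind(c(0, 120), c(200, 300)))
  expect_equal(r$category, "alt_5ss")
  r <- ev(rbind(c(0, 100), c(200, 300)), rbind(c(0, 120), c(200, 300)), "-")
  expect_equal(r$category, "alt_3ss")
  r <- ev(rbind(c(0, 100), c(200, 300)), rbind(c(0, 300)))
  expect_equal(r$category, "intron_retention")
  expect_equal(r$coords, "101-200")
  r <- ev(rbind(c(0, 100), c(200, 300), c(600, 700)),
          rbind(c(0, 100), c(400, 500), c(600, 700)))
  expect_equal(r$category, "mutually_exclusive")
  r <- ev(rbind(c(0, 100), c(200, 300)), rbind(c(0, 100), c(400, 500)))
  expect_equal(r$category, "alt_last_exon")
})

test_that("classification agrees with construction labels on random genes", {
  set.seed(20)
  n_checked <- 0L
  for (i in 1:500) {
    g <- random_labeled_gene()
    ev <- classify_events(pair_annotation(g$exA, g$exB, g$strand), genes = "g")
    expect_equal(nrow(ev), 1L,
                 label = sprintf("case %d (%s, %s): one event", i,
                                 g$expected, g$strand))
    expect_equal(ev$category, g$expected,
                 label = sprintf("case %d strand %s", i, g$strand))
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 500L)
})

test_that("reflecting coordinates and flipping strand swaps alt 5'/3' roles", {
  set.seed(21)
  M <- 100000L
  for (i in 1:60) {
    g <- random_labeled_gene()
    ev1 <- classify_events(pair_annotation(g$exA, g$exB, g$strand),
                           genes = "g")$category
    refl <- function(ex) {
      r <- cbind(M - ex[, 2], M - ex[, 1])
      r[order(r[, 1]), , drop = FALSE]
    }
    flip <- unname(c("+" = "-", "-" = "+")[g$strand])
    ev2 <- classify_events(pair_annotation(refl(g$exA), refl(g$exB), flip),
                           genes = "g")$category
    expect_equal(ev2, ev1)
    # reflection without the strand flip swaps the alternative splice sites
    ev3 <- classify_events(pair_annotation(refl(g$exA), refl(g$exB), g$strand),
                           genes = "g")$category
    swap <- c(alt_5ss = "alt_3ss", alt_3ss = "alt_5ss")
    if (ev1 %in% names(swap)) expect_equal(ev3, unname(swap[ev1]))
  }
})

test_that("events are deduplicated across isoform pairs", {
  # three isoforms where tB and tC both support the same skipping event
  tx <- data.frame(transcript_id = c("tA", "tB", "tC"), gene_id = "g",
                   contig = "c", strand = "+")
  ex <- rbind(
    data.frame(transcript_id = "tA", start = c(0, 200, 400), end = c(100, 300, 500)),
    data.frame(transcript_id = "tB", start = c(0, 400), end = c(100, 500)),
    data.frame(transcript_id = "tC", start = c(0, 400), end = c(100, 520)))
  ev <- classify_events(tx_annotation(tx, ex), genes = "g")
  expect_equal(sum(ev$category == "exon_skipping"), 1L)
})

test_that("sqrt JSD matches closed forms and is a bounded metric", {
  expect_equal(sqrt_jsd(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(sqrt_jsd(c(1, 0), c(0, 1)), 1)
  h <- -(0.75 * log2(0.75) + 0.25 * log2(0.25))
  expect_equal(sqrt_jsd(c(0.75, 0.25), c(0.25, 0.75)), sqrt(1 - h),
               tolerance = 1e-6)
  expect_equal(sqrt(1 - h), 0.43442, tolerance = 1e-5)
  expect_error(sqrt_jsd(c(1, 0), c(1, 0, 0)), "dimension")
  set.seed(5)
  for (i in 1:1000) {
    k <- sample(2:5, 1)
    rnd <- function() { x <- stats::rgamma(k, 1); x / sum(x) }
    p <- rnd(); q <- rnd(); r <- rnd()
    dpq <- sqrt_jsd(p, q); dqr <- sqrt_jsd(q, r); dpr <- sqrt_jsd(p, r)
    expect_equal(dpq, sqrt_jsd(q, p))
    expect_true(dpq >= 0 && dpq <= 1)
    expect_lte(dpr, dpq + dqr + 1e-12)
  }
  expect_equal(sqrt_jsd(c(0.3, 0.7), c(0.3, 0.7)), 0)
})

test_that("the bootstrap usage test is exact on identity and extreme cases", {
  r <- diff_splicing_test(c(50, 50), c(50, 50), n_boot = 500, seed = 1)
  expect_equal(r$statistic, 0); expect_equal(r$p, 1)
  r <- diff_splicing_test(c(100, 0), c(0, 100), n_boot = 999, seed = 1)
  expect_equal(r$statistic, 1)
  expect_lte(r$p, 2 / 1000)
  expect_error(diff_splicing_test(c(0, 0), c(10, 10)), "untestable")
})

test_that("a usage shift of the observed magnitude is detected in a screen", {
  sc <- simulate_usage_screen(n_genes = 100, frac_shifted = 0.1,
                              usage_a = c(0.9, 0.1), usage_b = c(0.4, 0.6),
                              n_frag = 200, seed = 3)
  r <- diff_splicing_screen(sc$counts, n_boot = 2000, seed = 100)
  expect_true(all(r$q[sc$shifted] < 0.05))
  # untestable genes are flagged and excluded from the FDR
  sc$counts[["gene0100"]] <- rbind(c(0, 0), c(10, 10))
  r2 <- diff_splicing_screen(sc$counts, n_boot = 200, seed = 100)
  expect_true(r2$untestable[100])
  expect_true(is.na(r2$q[100]))
})
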