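th <- calling_thresholds()

test_that("a single high-quality read tallies one count per aligned base", {
  sam <- write_test_sam(list(c("r1", "0", "101", "10M",
                               strrep("A", 10), strrep("?", 10))))  # Q30
  counts <- build_pileup(sam)
  expect_equal(nrow(counts), 10L)
  expect_equal(counts$pos, 100:109)
  expect_true(all(counts$depth == 1L))
  expect_true(all(counts$n_A_f == 1L))
  expect_true(all(counts$q_A_f == counts$n_A_f))
})

test_that("spliced alignments contribute nothing inside skipped introns", {
  sam <- write_test_sam(list(c("r1", "0", "101", "5M100N5M",
                               strrep("C", 10), strrep("?", 10))))
  counts <- build_pileup(sam)
  expect_setequal(counts$pos, c(100:104, 205:209))
})

test_that("overlapping mates count once per fragment, keeping the better call", {
  sam <- write_test_sam(list(
    c("f1", "99", "101", "10M", strrep("A", 10), paste0(strrep("?", 10))),
    c("f1", "147", "106", "10M", strrep("A", 10), strrep("5", 10))))  # Q20
  counts <- build_pileup(sam)
  expect_true(all(counts$depth == 1L))
  # in the overlap the Q30 forward call wins
  ov <- counts[counts$pos %in% 105:109, ]
  expect_true(all(ov$n_A_f == 1L & ov$n_A_r == 0L))
  tl <- counts[counts$pos %in% 110:114, ]
  expect_true(all(tl$n_A_r == 1L))
})

test_that("secondary, duplicate, unmapped and multimapped records are excluded", {
  sam <- write_test_sam(list(
    c("r1", "0", "101", "5M", "AAAAA", "?????"),
    c("r2", "256", "101", "5M", "AAAAA", "?????"),        # secondary
    c("r3", "1024", "101", "5M", "AAAAA", "?????"),       # duplicate
    c("r4", "4", "101", "5M", "AAAAA", "?????"),          # unmapped
    c("r5", "0", "101", "5M", "AAAAA", "?????", "3")))    # NH:i:3
  counts <- build_pileup(sam)
  expect_true(all(counts$depth == 1L))
})

test_that("malformed records are skipped with a warning, not an error", {
  sam <- write_test_sam(list(
    c("r1", "0", "101", "5M", "AAAAA", "?????"),
    c("bad", "0", "201", "9M", "AAAAA", "?????")))
  expect_warning(counts <- build_pileup(sam), "malformed")
  expect_equal(nrow(counts), 5L)
})

test_that("site classification follows the coverage and polymorphism filters", {
  mk <- function(af = 0, ar = 0, cf = 0, cr = 0, af_lo = 0, cf_lo = 0) {
    counts <- matrix(0L, 4, 2, dimnames = list(c("A", "C", "G", "T"),
                                               c("f", "r")))
    q <- counts
    counts["A", ] <- c(af + af_lo, ar); counts["C", ] <- c(cf + cf_lo, cr)
    q["A", ] <- c(af, ar); q["C", ] <- c(cf, cr)
    call_site(counts, q, th)
  }
  # unanimous depth 10: monomorphic
  r <- mk(af = 5, ar = 5)
  expect_equal(r$status, "monomorphic"); expect_equal(r$consensus, "A")
  # depth 9: uncallable
  expect_equal(mk(af = 5, ar = 4)$status, "uncallable")
  # 18 A / 2 C with C on both strands: minor fraction exactly 10% -> polymorphic
  expect_equal(mk(af = 9, ar = 9, cf = 1, cr = 1)$status, "polymorphic")
  # both C reads on the forward strand: criterion 2 fails -> ambiguous
  expect_equal(mk(af = 9, ar = 9, cf = 2)$status, "ambiguous")
  # zero depth is uncallable, never an error
  expect_equal(mk()$status, "uncallable")
})

test_that("top-two dominance below 90% is ambiguous", {
  counts <- matrix(0L, 4, 2, dimnames = list(c("A", "C", "G", "T"), c("f", "r")))
  counts["A", ] <- c(5L, 5L); counts["C", ] <- c(3L, 2L); counts["G", ] <- c(2L, 3L)
  expect_equal(call_site(counts, counts, th)$status, "ambiguous")
})

test_that("every surveyed site receives exactly one status and summaries add up", {
  cells <- weak_compositions(8L, 5L)
  tab <- counts_table_from_cells(cells)
  res <- call_all(tab, th)
  expect_true(all(res$calls$status %in%
                    c("uncallable", "monomorphic", "polymorphic", "ambiguous")))
  expect_equal(res$summary$n_surveyed, sum(tab$depth >= th$min_coverage))
  expect_true(all(is.na(res$calls$consensus) !=
                    (res$calls$status == "monomorphic")))
  expect_true(all((res$calls$depth < th$min_coverage) ==
                    (res$calls$status == "uncallable")))
})

test_that("raising the coverage floor never makes an uncallable site callable", {
  cells <- weak_compositions(8L, 4L)
  tab <- counts_table_from_cells(cells)
  lo <- call_all(tab, calling_thresholds(min_coverage = 5))$calls$status
  hi <- call_all(tab, calling_thresholds(min_coverage = 8))$calls$status
  expect_true(all(!(lo == "uncallable" & hi != "uncallable")))
  # lowering the minor-allele bound never turns polymorphic into monomorphic
  strict <- call_all(tab, calling_thresholds(min_coverage = 5,
                                             minor_frac = 0.2))$calls$status
  lax <- call_all(tab, calling_thresholds(min_coverage = 5,
                                          minor_frac = 0.05))$calls$status
  expect_true(all(!(strict == "polymorphic" & lax == "monomorphic")))
})

test_that("the printed SNP percentage matches hand arithmetic", {
  # published-scale counts: 32,547 of 22,100,344 surveyed is 0.147%
  expect_equal(breedtx::round_half_up(100 * 32547 / 22100344, 3), 0.147)
  expect_equal(breedtx::round_half_up(100 * 39370 / 19967581, 3), 0.197)
})
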