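mk_calls <- function(...) {
  # rows: list(breed, pos, status, consensus)
  rows <- list(...)
  data.table::data.table(
    breed = vapply(rows, `[[`, "", 1L),
    contig = "c",
    pos = vapply(rows, function(r) as.integer(r[[2]]), integer(1)),
    status = vapply(rows, `[[`, "", 3L),
    consensus = vapply(rows, function(r)
      if (length(r) >= 4) as.character(r[[4]]) else NA_character_,
      character(1)),
    depth = 50L, top1 = "A", top2 = "C", n_top1 = 50L, n_top2 = 0L)
}

test_that("identical consensus in all breeds emits no difference", {
  calls <- mk_calls(list("b1", 5, "monomorphic", "A"),
                    list("b2", 5, "monomorphic", "A"),
                    list("b3", 5, "monomorphic", "A"))
  r <- cross_breed_differences(calls)
  expect_equal(r$n_determinable, 1L)
  expect_equal(nrow(r$differences), 0L)
})

test_that("an A/G/A site yields exactly the two discordant pairs", {
  calls <- mk_calls(list("b1", 5, "monomorphic", "A"),
                    list("b2", 5, "monomorphic", "G"),
                    list("b3", 5, "monomorphic", "A"))
  r <- cross_breed_differences(calls)
  expect_equal(nrow(r$differences), 1L)
  expect_setequal(strsplit(r$differences$differing_pairs, ";")[[1]],
                  c("b1|b2", "b2|b3"))
  expect_equal(r$pair_counts$n[r$pair_counts$pair == "b1|b3"], 0L)
})

test_that("a site polymorphic in any breed is excluded from the determinable set", {
  calls <- mk_calls(list("b1", 5, "polymorphic", NA),
                    list("b2", 5, "monomorphic", "G"),
                    list("b3", 5, "monomorphic", "G"),
                    list("b1", 9, "monomorphic", "T"),
                    list("b2", 9, "monomorphic", "T"),
                    list("b3", 9, "monomorphic", "T"))
  r <- cross_breed_differences(calls)
  expect_equal(r$n_determinable, 1L)
  expect_equal(nrow(r$differences), 0L)
})

test_that("breed-label permutation leaves pairwise counts invariant", {
  calls <- mk_calls(list("b1", 1, "monomorphic", "A"),
                    list("b2", 1, "monomorphic", "G"),
                    list("b3", 1, "monomorphic", "C"),
                    list("b1", 2, "monomorphic", "T"),
                    list("b2", 2, "monomorphic", "T"),
                    list("b3", 2, "monomorphic", "A"))
  r1 <- cross_breed_differences(calls)
  swapped <- data.table::copy(calls)
  swapped[, breed := c(b1 = "b2", b2 = "b1", b3 = "b3")[breed]]
  r2 <- cross_breed_differences(swapped)
  expect_equal(r1$n_determinable, r2$n_determinable)
  expect_equal(sort(r1$pair_counts$n), sort(r2$pair_counts$n))
})

test_that("effect annotation translates codons on both strands", {
  # + strand gene: CDS ATG GAA AAA TGG TAA at positions 10..24
  ref <- paste0(strrep("T", 10), "ATGGAAAAATGGTAA", strrep("T", 10))
  ann <- tx_annotation(
    data.frame(transcript_id = "t1", gene_id = "g1", contig = "c", strand = "+"),
    data.frame(transcript_id = "t1", start = 5L, end = 30L),
    cds = data.frame(transcript_id = "t1", start = 10L, end = 25L))
  mk_diff <- function(pos, b1, b2) data.table::data.table(
    contig = "c", pos = as.integer(pos), consensus_b1 = b1, consensus_b2 = b2,
    differing_pairs = "b1|b2")
  r <- annotate_effect(mk_diff(15, "A", "G"), ann,
                       stats::setNames(ref, "c"))       # GAA -> GAG
  expect_equal(r$effect, "synonymous")
  expect_equal(r$codon_ref, "GAA"); expect_equal(r$codon_alt, "GAG")
  r <- annotate_effect(mk_diff(16, "A", "G"), ann,
                       stats::setNames(ref, "c"))       # AAA -> GAA
  expect_equal(r$effect, "nonsynonymous")
  expect_equal(r$aa_ref, "K"); expect_equal(r$aa_alt, "E")
  r <- annotate_effect(mk_diff(21, "G", "A"), ann,
                       stats::setNames(ref, "c"))       # TGG -> TGA
  expect_equal(r$effect, "stop_gained")
  # UTR position: exonic-noncoding, effect none
  r <- annotate_effect(mk_diff(7, "T", "C"), ann, stats::setNames(ref, "c"))
  expect_equal(r$region, "exonic-noncoding"); expect_equal(r$effect, "none")

  # - strand gene: same CDS read off the reverse strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref)))
  L <- nchar(ref)
  ann2 <- tx_annotation(
    data.frame(transcript_id = "t1", gene_id = "g1", contig = "c", strand = "-"),
    data.frame(transcript_id = "t1", start = L - 30L, end = L - 5L),
    cds = data.frame(transcript_id = "t1", start = L - 25L, end = L - 10L))
  # genomic position of the TGG codon's G->A change: transcript pos 21
  gpos <- L - 1L - 21L
  refb <- substr(rc, gpos + 1L, gpos + 1L)
  r <- annotate_effect(mk_diff(gpos, refb, breedtx:::comp_base("A")), ann2,
                       stats::setNames(rc, "c"))
  expect_equal(r$effect, "stop_gained")
  expect_equal(r$codon_ref, "TGG"); expect_equal(r$codon_alt, "TGA")
})

test_that("positions outside the reference raise a coordinate error", {
  ann <- tx_annotation(
    data.frame(transcript_id = "t1", gene_id = "g1", contig = "c", strand = "+"),
    data.frame(transcript_id = "t1", start = 0L, end = 10L))
  d <- data.table::data.table(contig = "c", pos = 500L,
                              consensus_b1 = "A", consensus_b2 = "C",
                              differing_pairs = "b1|b2")
  expect_error(annotate_effect(d, ann, stats::setNames(strrep("A", 20), "c")),
               "coordinate error")
})

test_that("the CDS coverage filter includes genes at exactly the 50% boundary", {
  ann <- tx_annotation(
    data.frame(transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"),
               contig = "c", strand = "+"),
    data.frame(transcript_id = c("t1", "t2"), start = c(0L, 1000L),
               end = c(300L, 1300L)),
    cds = data.frame(transcript_id = c("t1", "t2"), start = c(0L, 1000L),
                     end = c(300L, 1300L)))
  counts <- function(n_cov, offset = 0L) data.table::data.table(
    breed = "b", contig = "c", pos = offset + seq_len(n_cov) - 1L, depth = 12L)
  expect_equal(genes_with_cds_coverage(ann, counts(150L)), "g1")    # 150/300
  expect_equal(genes_with_cds_coverage(ann, counts(149L)), character(0))
  both <- data.table::rbindlist(list(counts(150L), counts(300L, 1000L)))
  expect_setequal(genes_with_cds_coverage(ann, both), c("g1", "g2"))
})

test_that("the intergenic flag is inclusive at 1000 bp and false on overlap", {
  ann <- tx_annotation(
    data.frame(transcript_id = "t1", gene_id = "g1", contig = "c", strand = "+"),
    data.frame(transcript_id = "t1", start = 5000L, end = 6000L))
  iv <- function(s, e) data.frame(contig = "c", start = s, end = e)
  expect_false(flag_intergenic(iv(3000, 4001), ann))   # 999 bp away
  expect_true(flag_intergenic(iv(3000, 4000), ann))    # exactly 1000 bp
  expect_false(flag_intergenic(iv(5500, 5600), ann))   # overlap
  empty <- tx_annotation(
    data.frame(transcript_id = character(), gene_id = character(),
               contig = character(), strand = character()),
    data.frame(transcript_id = character(), start = integer(),
               end = integer()))
  expect_true(flag_intergenic(iv(0, 10), empty))
})
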