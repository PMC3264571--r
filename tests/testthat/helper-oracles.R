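# Independent oracles used by the test suite.  These are deliberately
# written from first principles (textbook codon table, literal filter
# criteria, construction-labelled gene edits) and share no code with the
# package internals they check.

# standard genetic code, textbook layout (T/C/A/G by position)
ORACLE_AA <- local({
  b1 <- strsplit(paste0(strrep("T", 16), strrep("C", 16),
                        strrep("A", 16), strrep("G", 16)), "")[[1]]
  b2 <- strsplit(strrep(paste0(strrep("T", 4), strrep("C", 4),
                               strrep("A", 4), strrep("G", 4)), 4), "")[[1]]
  b3 <- strsplit(strrep("TCAG", 16), "")[[1]]
  aa <- strsplit(paste0("FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
                        "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, paste0(b1, b2, b3))
})

oracle_effect <- function(ref_codon, alt_codon) {
  a1 <- ORACLE_AA[[ref_codon]]; a2 <- ORACLE_AA[[alt_codon]]
  if (a2 == "*" && a1 != "*") "stop_gained"
  else if (a1 == "*" && a2 != "*") "stop_lost"
  else if (a1 == a2) "synonymous" else "nonsynonymous"
}

# brute-force site caller: counts as a [base, strand, qualpass] array,
# the three filter criteria written out literally with integer arithmetic
oracle_call_site <- function(arr, min_coverage = 10L, minor_frac = 0.10,
                             top2_frac = 0.90) {
  depth <- sum(arr)
  if (depth < min_coverage) return("uncallable")
  per_base <- apply(arr, 1L, sum)
  ord <- order(-per_base, seq_along(per_base))   # ties broken A<C<G<T
  b1 <- ord[1]; b2 <- ord[2]
  mf_num <- round(minor_frac * 1e6)
  t2_num <- round(top2_frac * 1e6)
  crit1 <- per_base[b2] * 1e6 >= mf_num * depth
  strands_ok <- function(b) arr[b, "f", "hi"] >= 1L && arr[b, "r", "hi"] >= 1L
  crit2 <- strands_ok(b1) && strands_ok(b2)
  crit3 <- (per_base[b1] + per_base[b2]) * 1e6 >= t2_num * depth
  if (crit1 && crit2 && crit3) return("polymorphic")
  if (per_base[b2] * 1e6 < mf_num * depth &&
      per_base[b1] * 1e6 >= t2_num * depth && strands_ok(b1))
    return("monomorphic")
  "ambiguous"
}

# weak compositions of 0..max_sum into k nonnegative parts
weak_compositions <- function(k, max_sum) {
  if (k == 1L) return(matrix(0:max_sum, ncol = 1L))
  sub <- weak_compositions(k - 1L, max_sum)
  rs <- rowSums(sub)
  do.call(rbind, lapply(0:max_sum, function(v)
    cbind(v, sub[rs <= max_sum - v, , drop = FALSE])))
}

# allele_counts-shaped table from a matrix of {A,C} x strand x qual cells
# columns of `cells`: A_f_hi, A_f_lo, A_r_hi, A_r_lo, C_f_hi, C_f_lo,
# C_r_hi, C_r_lo
counts_table_from_cells <- function(cells) {
  z <- integer(nrow(cells))
  dt <- data.table::data.table(
    breed = "pool", contig = "c", pos = seq_len(nrow(cells)) - 1L,
    n_A_f = cells[, 1] + cells[, 2], n_C_f = cells[, 5] + cells[, 6],
    n_G_f = z, n_T_f = z,
    n_A_r = cells[, 3] + cells[, 4], n_C_r = cells[, 7] + cells[, 8],
    n_G_r = z, n_T_r = z,
    q_A_f = cells[, 1], q_C_f = cells[, 5], q_G_f = z, q_T_f = z,
    q_A_r = cells[, 3], q_C_r = cells[, 7], q_G_r = z, q_T_r = z)
  dt[, depth := n_A_f + n_C_f + n_A_r + n_C_r]
  dt
}

# write a SAM file from a record list: each element
# c(qname, flag, pos1, cigar, seq, qual) (+ optional NH int)
write_test_sam <- function(records, path = tempfile(fileext = ".sam"),
                           contig = "chr1", len = 100000L) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", contig, len))
  for (r in records) {
    nh <- if (length(r) >= 7) r[7] else "1"
    lines <- c(lines, sprintf("%s\t%s\t%s\t%s\t50\t%s\t=\t%s\t0\t%s\t%s\tNH:i:%s",
                              r[1], r[2], contig, r[3], r[4], r[3], r[5], r[6], nh))
  }
  writeLines(lines, path)
  path
}

# two-transcript annotation from exon matrices (0-based half-open)
pair_annotation <- function(exA, exB, strand = "+", contig = "c") {
  exA <- matrix(as.integer(exA), ncol = 2)
  exB <- matrix(as.integer(exB), ncol = 2)
  tx <- data.frame(transcript_id = c("tA", "tB"), gene_id = "g",
                   contig = contig, strand = strand)
  ex <- rbind(data.frame(transcript_id = "tA", start = exA[, 1], end = exA[, 2]),
              data.frame(transcript_id = "tB", start = exB[, 1], end = exB[, 2]))
  tx_annotation(tx, ex)
}

# random two-isoform gene with a construction-labelled splicing edit;
# returns exon matrices, strand and the expected event category
random_labeled_gene <- function(type = NULL) {
  types <- c("exon_skipping", "alt_5ss", "alt_3ss", "intron_retention",
             "mutually_exclusive", "alt_last_exon")
  if (is.null(type)) type <- sample(types, 1L)
  strand <- sample(c("+", "-"), 1L)
  n_ex <- sample(3:6, 1L)
  ex_len <- sample(80:200, n_ex, replace = TRUE)
  in_len <- sample(100:250, n_ex - 1L, replace = TRUE)
  starts <- cumsum(c(0L, head(ex_len, -1) + in_len))
  exA <- cbind(starts, starts + ex_len)
  delta <- sample(10:40, 1L)
  internal <- 2:(n_ex - 1L)
  k <- internal[sample.int(length(internal), 1L)]   # an internal exon
  exB <- exA
  expected <- type
  if (type == "exon_skipping") {
    exB <- exA[-k, , drop = FALSE]
  } else if (type %in% c("alt_5ss", "alt_3ss")) {
    # move a genomic intron boundary; the role (donor/acceptor) depends on
    # strand: the genomic-left boundary is the donor on "+" only
    left_boundary <- sample(c(TRUE, FALSE), 1L)
    if (left_boundary) exB[k, 2] <- exA[k, 2] - delta   # genomic intron start
    else exB[k + 1L, 1] <- exA[k + 1L, 1] + delta       # genomic intron end
    expected <- if (left_boundary == (strand == "+")) "alt_5ss" else "alt_3ss"
  } else if (type == "intron_retention") {
    exB <- rbind(exA[seq_len(k - 1L), , drop = FALSE],
                 c(exA[k, 1], exA[k + 1L, 2]),
                 if (k + 2L <= n_ex) exA[(k + 2L):n_ex, , drop = FALSE])
  } else if (type == "mutually_exclusive") {
    # widen the gap after exon k and give each isoform its own middle exon
    shift <- 400L
    exA2 <- exA; exA2[(k + 1L):n_ex, ] <- exA[(k + 1L):n_ex, ] + shift
    x <- c(exA[k, 2] + 100L, exA[k, 2] + 180L)
    y <- c(x[2] + 50L, x[2] + 130L)
    exB <- rbind(exA2[seq_len(k), , drop = FALSE], y,
                 exA2[(k + 1L):n_ex, , drop = FALSE])
    exA <- rbind(exA2[seq_len(k), , drop = FALSE], x,
                 exA2[(k + 1L):n_ex, , drop = FALSE])
  } else if (type == "alt_last_exon") {
    # replace the genomically-terminal exon on the transcript 3' side
    if (strand == "+") {
      exB[n_ex, ] <- c(exA[n_ex, 2] + 150L, exA[n_ex, 2] + 280L)
    } else {
      exB[1, ] <- c(exA[1, 1] - 280L, exA[1, 1] - 150L)
      if (exB[1, 1] < 0) { exA <- exA + 300L; exB <- exB + 300L }
    }
  }
  rownames(exA) <- rownames(exB) <- NULL
  list(exA = exA, exB = exB, strand = strand, expected = expected)
}
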