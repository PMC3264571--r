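#' Single-TSS multi-isoform genes
#'
#' Selects genes whose isoforms all share one transcription start site and
#' that have at least two isoforms.  TSS equality is strict (a 1-bp offset
#' excludes the gene); isoform-usage comparisons are made within these TSS
#' groups, and alternative first exons cannot occur inside them.
#'
#' @param annotation a [tx_annotation()].
#' @return list with `genes` (character vector of selected gene ids) and
#'   `tss_groups` (data.frame transcript_id, gene_id, tss for the
#'   selected genes).
#' @export
single_tss_multi_isoform <- function(annotation) {
  tss <- transcript_tss(annotation)
  by_gene <- split(tss, tss$gene_id)
  sel <- vapply(by_gene, function(d)
    nrow(d) >= 2L && length(unique(d$tss)) == 1L, logical(1))
  genes <- sort(names(by_gene)[sel])
  list(genes = genes, tss_groups = tss[tss$gene_id %in% genes, ])
}

# splice-site roles under strand: donor is the intron boundary nearer the
# transcript 5' end
intron_donor <- function(iv, strand) if (strand == "+") iv[, 1] else iv[, 2]
intron_acceptor <- function(iv, strand) if (strand == "+") iv[, 2] else iv[, 1]

sig <- function(category, ivs) {
  ivs <- ivs[order(ivs[, 1], ivs[, 2]), , drop = FALSE]
  paste0(category, ":", paste(ivs[, 1], ivs[, 2], sep = "-", collapse = ";"))
}

# classify events for one ordered isoform pair (exon matrices, strand)
classify_pair <- function(exA, exB, strand) {
  introns_of <- function(ex) {
    if (nrow(ex) < 2L) return(matrix(integer(0), ncol = 2))
    cbind(ex[-nrow(ex), 2], ex[-1, 1])
  }
  inA <- introns_of(exA)
  inB <- introns_of(exB)
  events <- list()
  usedA <- rep(FALSE, nrow(inA)); usedB <- rep(FALSE, nrow(inB))

  add <- function(cat, ivs) {
    events[[length(events) + 1L]] <<- list(category = cat, coords = ivs)
  }

  # exon skipping: intron of X spans >=1 full exon of Y with both flanking
  # splice sites shared (Y's introns + inner exons tile X's intron exactly)
  skip_scan <- function(inX, exY, inY, markX, markY) {
    for (i in seq_len(nrow(inX))) {
      inside <- which(exY[, 1] > inX[i, 1] & exY[, 2] < inX[i, 2])
      if (!length(inside)) next
      yin <- which(inY[, 1] >= inX[i, 1] & inY[, 2] <= inX[i, 2])
      if (!length(yin)) next
      segs <- rbind(exY[inside, , drop = FALSE], inY[yin, , drop = FALSE])
      segs <- segs[order(segs[, 1]), , drop = FALSE]
      tiles <- segs[1, 1] == inX[i, 1] && segs[nrow(segs), 2] == inX[i, 2] &&
        all(segs[-1, 1] == segs[-nrow(segs), 2])
      if (tiles) {
        add("exon_skipping", exY[inside, , drop = FALSE])
        if (markX == "A") usedA[i] <<- TRUE else usedB[i] <<- TRUE
        if (markY == "A") usedA[yin] <<- TRUE else usedB[yin] <<- TRUE
      }
    }
  }
  skip_scan(inA, exB, inB, "A", "B")
  skip_scan(inB, exA, inA, "B", "A")

  # intron retention: intron of X strictly inside an exon of Y
  ir_scan <- function(inX, exY, markX) {
    for (i in seq_len(nrow(inX))) {
      if (any(exY[, 1] < inX[i, 1] & inX[i, 2] < exY[, 2])) {
        add("intron_retention", inX[i, , drop = FALSE])
        if (markX == "A") usedA[i] <<- TRUE else usedB[i] <<- TRUE
      }
    }
  }
  ir_scan(inA, exB, "A")
  ir_scan(inB, exA, "B")

  # mutually exclusive exons: internal exon x of A and y of B flanked by
  # introns sharing outer boundaries, with x and y disjoint and private
  if (nrow(exA) >= 3L && nrow(exB) >= 3L) {
    for (ia in 2:(nrow(exA) - 1L)) {
      prevA <- ia - 1L; nextA <- ia
      dA <- inA[prevA, 1]; aA <- inA[nextA, 2]
      for (ib in 2:(nrow(exB) - 1L)) {
        dB <- inB[ib - 1L, 1]; aB <- inB[ib, 2]
        if (dA != dB || aA != aB) next
        x <- exA[ia, ]; y <- exB[ib, ]
        disjoint <- x[2] <= y[1] || y[2] <= x[1]
        privx <- !any(exB[, 1] == x[1] & exB[, 2] == x[2])
        privy <- !any(exA[, 1] == y[1] & exA[, 2] == y[2])
        if (disjoint && privx && privy) {
          add("mutually_exclusive", rbind(x, y))
          usedA[c(prevA, nextA)] <- TRUE
          usedB[c(ib - 1L, ib)] <- TRUE
        }
      }
    }
  }

  # alternative last exon: last introns (transcript orientation) share the
  # donor, differ at the acceptor, and the terminal exons are disjoint
  if (nrow(inA) && nrow(inB)) {
    lastA <- if (strand == "+") nrow(inA) else 1L
    lastB <- if (strand == "+") nrow(inB) else 1L
    if (!usedA[lastA] && !usedB[lastB]) {
      ivA <- inA[lastA, , drop = FALSE]; ivB <- inB[lastB, , drop = FALSE]
      dA <- intron_donor(ivA, strand); dB <- intron_donor(ivB, strand)
      aA <- intron_acceptor(ivA, strand); aB <- intron_acceptor(ivB, strand)
      if (dA == dB && aA != aB) {
        termA <- if (strand == "+") exA[nrow(exA), ] else exA[1, ]
        termB <- if (strand == "+") exB[nrow(exB), ] else exB[1, ]
        if (termA[2] <= termB[1] || termB[2] <= termA[1]) {
          add("alt_last_exon", rbind(termA, termB))
          usedA[lastA] <- TRUE; usedB[lastB] <- TRUE
        }
      }
    }
  }

  # alternative 5'/3' splice sites on remaining overlapping intron pairs
  for (i in seq_len(nrow(inA))) {
    if (usedA[i]) next
    for (j in seq_len(nrow(inB))) {
      if (usedB[j]) next
      ivA <- inA[i, , drop = FALSE]; ivB <- inB[j, , drop = FALSE]
      if (ivA[2] <= ivB[1] || ivB[2] <= ivA[1]) next  # no overlap
      if (all(ivA == ivB)) next
      dA <- intron_donor(ivA, strand); dB <- intron_donor(ivB, strand)
      aA <- intron_acceptor(ivA, strand); aB <- intron_acceptor(ivB, strand)
      if (aA == aB && dA != dB) add("alt_5ss", rbind(ivA, ivB))
      else if (dA == dB && aA != aB) add("alt_3ss", rbind(ivA, ivB))
    }
  }
  events
}

#' Classify alternative-splicing events within a TSS group
#'
#' For each unordered isoform pair of every selected gene, compares the
#' exon/intron chains in transcript-strand orientation and emits events in
#' six categories: `exon_skipping`, `alt_5ss`, `alt_3ss`,
#' `intron_retention`, `mutually_exclusive`, `alt_last_exon`.  Alternative
#' first exons are not emitted under the single-TSS restriction.  Events
#' are deduplicated across isoform pairs by (category, sorted coordinate
#' signature).
#'
#' @param annotation a [tx_annotation()].
#' @param genes gene ids to classify (default: the single-TSS
#'   multi-isoform genes).
#' @return data.table: gene, category, isoform_a, isoform_b, coords
#'   (1-based "start-end" pairs, semicolon-joined), strand.
#' @export
classify_events <- function(annotation, genes = NULL) {
  if (is.null(genes)) genes <- single_tss_multi_isoform(annotation)$genes
  tx_by_gene <- split(annotation$transcripts$transcript_id,
                      annotation$transcripts$gene_id)
  rows <- list()
  for (g in genes) {
    txs <- sort(tx_by_gene[[g]])
    strand <- tx_strand(annotation, txs[1])
    seen <- character(0)
    for (i in seq_len(length(txs) - 1L)) for (j in (i + 1L):length(txs)) {
      eA <- tx_exons(annotation, txs[i])
      eB <- tx_exons(annotation, txs[j])
      if (nrow(eA) > 1 && any(eA$start[-1] < eA$end[-nrow(eA)]))
        stop("annotation error: overlapping exons in ", txs[i])
      ev <- classify_pair(cbind(eA$start, eA$end), cbind(eB$start, eB$end),
                          strand)
      for (e in ev) {
        key <- sig(e$category, e$coords)
        if (key %in% seen) next
        seen <- c(seen, key)
        iv <- e$coords[order(e$coords[, 1]), , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.table::data.table(
          gene = g, category = e$category,
          isoform_a = txs[i], isoform_b = txs[j],
          coords = paste(iv[, 1] + 1L, iv[, 2], sep = "-", collapse = ";"),
          strand = strand)
      }
    }
  }
  if (!length(rows))
    return(data.table::data.table(gene = character(), category = character(),
                                  isoform_a = character(),
                                  isoform_b = character(),
                                  coords = character(), strand = character()))
  data.table::rbindlist(rows)
}

#' Square-root Jensen-Shannon divergence
#'
#' `JS(P, Q) = H(M) - (H(P) + H(Q)) / 2` with `M = (P + Q) / 2` and
#' entropy in bits (log base 2, `0 log 0 = 0`); returns `sqrt(JS)`, a
#' metric bounded in `[0, 1]`.
#'
#' @param p,q probability vectors of equal dimension, each summing to 1.
#' @return the statistic, a scalar in `[0, 1]`.
#' @export
sqrt_jsd <- function(p, q) {
  if (length(p) != length(q)) stop("dimension mismatch between P and Q")
  stopifnot(abs(sum(p) - 1) < 1e-6, abs(sum(q) - 1) < 1e-6)
  m <- (p + q) / 2
  h <- function(x) -sum(ifelse(x > 0, x * log2(x), 0))
  js <- h(m) - (h(p) + h(q)) / 2
  sqrt(max(js, 0))
}

# vectorized sqrt JSD between two column-probability matrices
sqrt_jsd_mat <- function(P, Q) {
  h <- function(M) -colSums(ifelse(M > 0, M * log2(M), 0))
  js <- h((P + Q) / 2) - (h(P) + h(Q)) / 2
  sqrt(pmax(js, 0))
}

#' Bootstrap test of differential isoform usage
#'
#' The observed statistic is the square-root Jensen-Shannon divergence of
#' the two breeds' isoform-usage distributions (counts normalized).  The
#' null pools both breeds' isoform counts and draws `n_boot` pairs of
#' multinomial samples of the original totals from the pooled proportions;
#' `p = (1 + #\{null >= observed\}) / (n_boot + 1)`.
#'
#' @param counts_a,counts_b per-isoform fragment counts (equal length
#'   >= 2, positive totals).
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed optional RNG seed for the bootstrap.
#' @return list: statistic, p.
#' @export
diff_splicing_test <- function(counts_a, counts_b, n_boot = 10000L,
                               seed = NULL) {
  if (length(counts_a) != length(counts_b) || length(counts_a) < 2L)
    stop("need per-isoform counts of equal dimension >= 2")
  ta <- sum(counts_a); tb <- sum(counts_b)
  if (ta <= 0 || tb <= 0) stop("untestable: a breed has zero total count")
  obs <- sqrt_jsd(counts_a / ta, counts_b / tb)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  pp <- (counts_a + counts_b) / (ta + tb)
  A <- stats::rmultinom(n_boot, ta, pp) / ta
  B <- stats::rmultinom(n_boot, tb, pp) / tb
  null <- sqrt_jsd_mat(A, B)
  p <- (1 + sum(null >= obs - 1e-12)) / (n_boot + 1)
  list(statistic = obs, p = p)
}

#' Differential splicing screen over many genes
#'
#' Runs [diff_splicing_test()] per gene and adjusts p-values with
#' [bh_fdr()].  Genes with an all-zero breed are flagged untestable and
#' excluded from the FDR.
#'
#' @param counts named list; each element is a 2-row matrix (breeds) by
#'   isoform columns of fragment counts, or a list of two count vectors.
#' @param n_boot bootstrap replicates per gene.
#' @param seed base RNG seed; gene i uses `seed + i`.
#' @return data.frame: gene, statistic, p, q, untestable.
#' @export
diff_splicing_screen <- function(counts, n_boot = 10000L, seed = 1L) {
  genes <- names(counts)
  stat <- rep(NA_real_, length(genes)); p <- rep(NA_real_, length(genes))
  untestable <- logical(length(genes))
  for (i in seq_along(genes)) {
    x <- counts[[i]]
    if (is.matrix(x)) x <- list(x[1, ], x[2, ])
    if (sum(x[[1]]) <= 0 || sum(x[[2]]) <= 0) {
      untestable[i] <- TRUE
      next
    }
    r <- diff_splicing_test(x[[1]], x[[2]], n_boot = n_boot, seed = seed + i)
    stat[i] <- r$statistic; p[i] <- r$p
  }
  q <- rep(NA_real_, length(genes))
  q[!untestable] <- bh_fdr(p[!untestable])
  data.frame(gene = genes, statistic = stat, p = p, q = q,
             untestable = untestable, stringsAsFactors = FALSE)
}

#' Write splicing events as BED12-compatible intervals plus TSV
#' @param events events table from [classify_events()].
#' @param annotation a [tx_annotation()].
#' @param path_tsv,path_bed output paths (either may be NULL).
#' @return invisibly, the paths written.
#' @export
write_events <- function(events, annotation, path_tsv = NULL,
                         path_bed = NULL) {
  if (!is.null(path_tsv)) data.table::fwrite(events, path_tsv, sep = "\t")
  if (!is.null(path_bed)) {
    lines <- character(0)
    for (i in seq_len(nrow(events))) {
      ctg <- tx_contig(annotation, events$isoform_a[i])
      ivs <- do.call(rbind, lapply(strsplit(events$coords[i], ";")[[1]],
                                   function(s) as.integer(strsplit(s, "-")[[1]])))
      s <- min(ivs[, 1]) - 1L; e <- max(ivs[, 2])
      sizes <- ivs[, 2] - ivs[, 1] + 1L
      starts <- ivs[, 1] - 1L - s
      lines <- c(lines, sprintf(
        "%s\t%d\t%d\t%s_%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
        ctg, s, e, events$gene[i], events$category[i], events$strand[i],
        s, e, nrow(ivs), paste0(paste(sizes, collapse = ","), ","),
        paste0(paste(starts, collapse = ","), ",")))
    }
    writeLines(lines, path_bed)
  }
  invisible(c(tsv = path_tsv, bed = path_bed))
}
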