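#' Simulate a reference genome and gene models
#'
#' Builds one contig carrying `n_genes` gene loci separated by fixed
#' intergenic gaps.  Every gene has one primary transcript whose CDS starts
#' with ATG, ends with a stop codon, contains no internal stop, and has
#' length divisible by 3.  A configurable fraction of genes (with at least
#' three exons) receives a second isoform that shares the TSS and skips one
#' internal exon; the skipping isoform carries no CDS record (the skip
#' disrupts the reading frame, as for a non-functional splice variant).
#' Optionally, unannotated transcribed intervals are placed in the gaps at
#' distances straddling the 1,000-bp intergenic rule.
#'
#' Deterministic under a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `reference` (named `DNAStringSet`), `annotation`
#'   (a [tx_annotation()]), and `unannotated` (data.frame of intervals with
#'   their true distance to the nearest gene).
#' @export
simulate_genome_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  n2 <- round(config$two_isoform_frac * config$n_genes)
  two_iso <- sort(sample.int(config$n_genes, n2))

  contig <- "chr1"
  seq_parts <- character(0)
  offset <- 0L
  tx_rows <- list(); exon_rows <- list(); cds_rows <- list()
  gene_meta <- list()

  rand_bases <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
  # safe range sampling (immune to sample()'s scalar expansion)
  sample_range <- function(rng, n) {
    v <- rng[1]:rng[2]
    v[sample.int(length(v), n, replace = TRUE)]
  }

  for (gi in seq_len(config$n_genes)) {
    # intergenic gap precedes each locus
    seq_parts <- c(seq_parts, rand_bases(config$intergenic_gap))
    offset <- offset + config$intergenic_gap
    gid <- sprintf("g%03d", gi)
    n_ex <- sample_range(config$exons_per_gene, 1L)
    if (gi %in% two_iso) n_ex <- max(3L, n_ex)
    ex_lens <- sample_range(config$exon_len, n_ex)
    in_lens <- if (n_ex > 1) sample_range(config$intron_len, n_ex - 1L)
    else integer(0)
    tx_len <- sum(ex_lens)

    utr5 <- sample_range(config$utr5_len, 1L)
    cds_len <- 3L * ((tx_len - utr5 - 10L) %/% 3L)
    if (cds_len < 24L)
      stop("configuration error: exon lengths too short to host a CDS")
    utr3 <- tx_len - utr5 - cds_len

    n_codon <- cds_len %/% 3L
    cds_seq <- paste0("ATG",
                      paste(sample(SENSE_CODONS, n_codon - 2L, replace = TRUE),
                            collapse = ""),
                      sample(STOP_CODONS, 1L))
    mrna <- paste0(rand_bases(utr5), cds_seq, rand_bases(utr3))

    # interleave exon pieces with introns (transcript orientation)
    ex_tx_start <- cumsum(c(0L, ex_lens[-n_ex]))
    pieces <- character(0)
    locus_off <- integer(n_ex)  # exon starts within locus, tx orientation
    pos <- 0L
    for (k in seq_len(n_ex)) {
      locus_off[k] <- pos
      pieces <- c(pieces, substr(mrna, ex_tx_start[k] + 1L, ex_tx_start[k] + ex_lens[k]))
      pos <- pos + ex_lens[k]
      if (k < n_ex) {
        pieces <- c(pieces, rand_bases(in_lens[k]))
        pos <- pos + in_lens[k]
      }
    }
    locus_seq <- paste(pieces, collapse = "")
    locus_len <- nchar(locus_seq)
    strand <- sample(c("+", "-"), 1L)

    # map a transcript-coordinate interval to locus intervals (tx orientation)
    tx2locus <- function(s, e) {
      out <- list()
      for (k in seq_len(n_ex)) {
        a <- max(s, ex_tx_start[k]); b <- min(e, ex_tx_start[k] + ex_lens[k])
        if (a < b)
          out[[length(out) + 1L]] <- c(locus_off[k] + (a - ex_tx_start[k]),
                                       locus_off[k] + (b - ex_tx_start[k]))
      }
      do.call(rbind, out)
    }
    to_genomic <- function(iv) {
      # iv: matrix of locus [start,end) in tx orientation
      if (strand == "-") iv <- cbind(locus_len - iv[, 2], locus_len - iv[, 1])
      iv[order(iv[, 1]), , drop = FALSE] + offset
    }

    genome_locus <- if (strand == "+") locus_seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(locus_seq)))

    ex_iv <- to_genomic(tx2locus(0L, tx_len))
    cds_iv <- to_genomic(tx2locus(utr5, utr5 + cds_len))

    t1 <- paste0(gid, "t1")
    tx_rows[[length(tx_rows) + 1L]] <-
      data.frame(transcript_id = t1, gene_id = gid, contig = contig,
                 strand = strand, stringsAsFactors = FALSE)
    exon_rows[[length(exon_rows) + 1L]] <-
      data.frame(transcript_id = t1, start = ex_iv[, 1], end = ex_iv[, 2])
    cds_rows[[length(cds_rows) + 1L]] <-
      data.frame(transcript_id = t1, start = cds_iv[, 1], end = cds_iv[, 2])

    if (gi %in% two_iso) {
      internal <- 2:(n_ex - 1L)
      skip <- internal[sample.int(length(internal), 1L)]
      keep <- setdiff(seq_len(n_ex), skip)
      iv2 <- do.call(rbind, lapply(keep, function(k)
        c(locus_off[k], locus_off[k] + ex_lens[k])))
      ex_iv2 <- to_genomic(iv2)
      t2 <- paste0(gid, "t2")
      tx_rows[[length(tx_rows) + 1L]] <-
        data.frame(transcript_id = t2, gene_id = gid, contig = contig,
                   strand = strand, stringsAsFactors = FALSE)
      exon_rows[[length(exon_rows) + 1L]] <-
        data.frame(transcript_id = t2, start = ex_iv2[, 1], end = ex_iv2[, 2])
    }

    gene_meta[[gi]] <- data.frame(gene_id = gid, start = offset,
                                  end = offset + locus_len,
                                  n_isoforms = if (gi %in% two_iso) 2L else 1L,
                                  stringsAsFactors = FALSE)
    seq_parts <- c(seq_parts, genome_locus)
    offset <- offset + locus_len
  }

  genome <- paste(c(seq_parts, rand_bases(config$intergenic_gap)), collapse = "")

  ann <- tx_annotation(do.call(rbind, tx_rows),
                       do.call(rbind, exon_rows),
                       cds = do.call(rbind, cds_rows),
                       contigs = stats::setNames(nchar(genome), contig))

  # unannotated transcribed intervals in the gaps
  unannot <- data.frame(contig = character(), start = integer(),
                        end = integer(), dist = integer(),
                        stringsAsFactors = FALSE)
  spans <- ann$genes
  place_unannot <- function(n, dist) {
    out <- list()
    if (n < 1) return(out)
    len <- 300L
    for (j in seq_len(min(n, nrow(spans)))) {
      # place upstream of gene j, `dist` bp from its start
      s <- spans$start[j] - dist - len
      e <- spans$end[j]  # unused
      if (s >= 0 && (j == 1 || s >= spans$end[j - 1] + dist))
        out[[length(out) + 1L]] <- data.frame(contig = contig, start = s,
                                              end = s + len, dist = dist,
                                              stringsAsFactors = FALSE)
    }
    out
  }
  unannot <- rbind(unannot,
                   do.call(rbind, c(place_unannot(config$n_unannotated_far, 1200L),
                                    place_unannot(config$n_unannotated_near, 400L),
                                    list(unannot))))

  attr(ann, "two_isoform_genes") <- sprintf("g%03d", two_iso)
  list(reference = Biostrings::DNAStringSet(stats::setNames(genome, contig)),
       annotation = ann,
       unannotated = unannot)
}

# save/restore global RNG state so simulator calls do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
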