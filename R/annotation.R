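#' Transcript annotation container
#'
#' A light container for gene models: genes, transcripts, exons and CDS
#' intervals.  All coordinates are stored 0-based half-open internally; the
#' GTF reader/writer converts to and from the 1-based inclusive GTF dialect.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `contig`, `strand` ("+" or "-").
#' @param exons data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open). Exons of a transcript must not overlap.
#' @param cds data.frame with the same columns as `exons`; may be empty.
#'   CDS intervals must lie within exons and total a multiple of 3 per
#'   transcript.
#' @param contigs named integer vector of contig lengths (optional; inferred
#'   from the data when missing).
#' @return An object of class `tx_annotation`: a list with elements
#'   `genes`, `transcripts`, `exons`, `cds`, `contigs`.
#' @export
tx_annotation <- function(transcripts, exons, cds = NULL, contigs = NULL) {
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  if (is.null(cds)) {
    cds <- data.frame(transcript_id = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  } else {
    cds <- as.data.frame(cds, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("transcript_id", "gene_id", "contig", "strand") %in%
                  names(transcripts)),
            all(c("transcript_id", "start", "end") %in% names(exons)))
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  cds$start <- as.integer(cds$start); cds$end <- as.integer(cds$end)
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  if (nrow(cds)) cds <- cds[order(cds$transcript_id, cds$start), , drop = FALSE]

  # structural checks
  for (tx in split(exons, exons$transcript_id)) {
    if (nrow(tx) > 1 && any(tx$start[-1] < tx$end[-nrow(tx)]))
      stop("overlapping exons within transcript ", tx$transcript_id[1])
  }
  if (nrow(cds)) {
    tot <- tapply(cds$end - cds$start, cds$transcript_id, sum)
    if (any(tot %% 3 != 0))
      stop("CDS length not a multiple of 3 for: ",
           paste(names(tot)[tot %% 3 != 0], collapse = ", "))
  }

  # gene spans derived from exons
  if (nrow(exons)) {
    tx2gene <- stats::setNames(transcripts$gene_id, transcripts$transcript_id)
    ex_gene <- tx2gene[exons$transcript_id]
    genes <- data.frame(
      gene_id = names(tapply(exons$start, ex_gene, min)),
      start = as.integer(tapply(exons$start, ex_gene, min)),
      end = as.integer(tapply(exons$end, ex_gene, max)),
      stringsAsFactors = FALSE)
    meta <- transcripts[!duplicated(transcripts$gene_id),
                        c("gene_id", "contig", "strand")]
    genes <- merge(genes, meta, by = "gene_id", sort = TRUE)
    genes <- genes[order(genes$contig, genes$start), , drop = FALSE]
    rownames(genes) <- NULL
  } else {
    genes <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), contig = character(),
                        strand = character(), stringsAsFactors = FALSE)
  }

  if (is.null(contigs)) {
    contigs <- tapply(genes$end, genes$contig, max)
    contigs <- stats::setNames(as.integer(contigs), names(contigs))
  }
  structure(list(genes = genes, transcripts = transcripts,
                 exons = exons, cds = cds, contigs = contigs),
            class = "tx_annotation")
}

#' @export
print.tx_annotation <- function(x, ...) {
  cat("tx_annotation:", nrow(x$genes), "genes,",
      nrow(x$transcripts), "transcripts on",
      length(x$contigs), "contig(s)\n")
  invisible(x)
}

# exon table for one transcript, genomic order
tx_exons <- function(ann, tx) {
  e <- ann$exons[ann$exons$transcript_id == tx, , drop = FALSE]
  e[order(e$start), , drop = FALSE]
}

tx_cds <- function(ann, tx) {
  e <- ann$cds[ann$cds$transcript_id == tx, , drop = FALSE]
  e[order(e$start), , drop = FALSE]
}

tx_strand <- function(ann, tx) {
  ann$transcripts$strand[match(tx, ann$transcripts$transcript_id)]
}

tx_contig <- function(ann, tx) {
  ann$transcripts$contig[match(tx, ann$transcripts$transcript_id)]
}

tx_length <- function(ann, tx) {
  e <- ann$exons[ann$exons$transcript_id == tx, , drop = FALSE]
  sum(e$end - e$start)
}

# genomic positions (0-based) of transcript bases, in transcript 5'->3' order
tx_posmap <- function(ann, tx) {
  e <- tx_exons(ann, tx)
  pos <- unlist(mapply(function(s, ee) s:(ee - 1L), e$start, e$end,
                       SIMPLIFY = FALSE), use.names = FALSE)
  if (tx_strand(ann, tx) == "-") pos <- rev(pos)
  as.integer(pos)
}

# introns (gaps between consecutive exons), genomic order; 0-based half-open
tx_introns <- function(exons) {
  if (nrow(exons) < 2)
    return(data.frame(start = integer(), end = integer()))
  data.frame(start = exons$end[-nrow(exons)], end = exons$start[-1])
}

#' Transcription start sites
#'
#' The TSS of a transcript is the genomic position of its first transcribed
#' base: the 5'-most exon start on "+" transcripts, the 3'-most exon end
#' minus one on "-" transcripts.
#'
#' @param ann a [tx_annotation()].
#' @return data.frame with columns `transcript_id`, `gene_id`, `tss`.
#' @export
transcript_tss <- function(ann) {
  tx <- ann$transcripts
  tss <- vapply(tx$transcript_id, function(t) {
    e <- ann$exons[ann$exons$transcript_id == t, , drop = FALSE]
    if (tx$strand[match(t, tx$transcript_id)] == "+") min(e$start)
    else max(e$end) - 1L
  }, integer(1))
  data.frame(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
             tss = as.integer(tss), stringsAsFactors = FALSE)
}

#' Write gene models to GTF
#'
#' Emits `exon` and `CDS` features with `gene_id` and `transcript_id`
#' attributes, 1-based inclusive coordinates, and correct CDS frame fields.
#'
#' @param ann a [tx_annotation()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  lines <- character(0)
  for (i in seq_len(nrow(ann$transcripts))) {
    tx <- ann$transcripts$transcript_id[i]
    g <- ann$transcripts$gene_id[i]
    strand <- ann$transcripts$strand[i]
    contig <- ann$transcripts$contig[i]
    attr <- sprintf('gene_id "%s"; transcript_id "%s";', g, tx)
    e <- tx_exons(ann, tx)
    lines <- c(lines, sprintf("%s\tbreedtx\texon\t%d\t%d\t.\t%s\t.\t%s",
                              contig, e$start + 1L, e$end, strand, attr))
    cd <- tx_cds(ann, tx)
    if (nrow(cd)) {
      # frame: bases of the codon completed by previous CDS pieces (5'->3')
      ord <- if (strand == "+") seq_len(nrow(cd)) else rev(seq_len(nrow(cd)))
      lens <- (cd$end - cd$start)[ord]
      frame <- (3L - (cumsum(c(0L, lens[-length(lens)])) %% 3L)) %% 3L
      frame_gen <- integer(nrow(cd)); frame_gen[ord] <- frame
      lines <- c(lines, sprintf("%s\tbreedtx\tCDS\t%d\t%d\t.\t%s\t%d\t%s",
                                contig, cd$start + 1L, cd$end, strand,
                                frame_gen, attr))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Parses `exon` and `CDS` records of a GTF2.2 file (via rtracklayer) into a
#' [tx_annotation()], converting to the package's 0-based half-open
#' coordinates.
#'
#' @param path GTF file path.
#' @param contigs optional named vector of contig lengths.
#' @return a [tx_annotation()].
#' @export
read_gtf <- function(path, contigs = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    stringsAsFactors = FALSE)
  ex <- df[df$type == "exon", c("transcript_id", "start", "end")]
  cd <- df[df$type == "CDS", c("transcript_id", "start", "end")]
  txdf <- df[df$type %in% c("exon", "CDS"), ]
  txdf <- txdf[!duplicated(txdf$transcript_id),
               c("transcript_id", "gene_id", "contig", "strand")]
  tx_annotation(txdf, ex, cds = cd, contigs = contigs)
}

#' Read a FASTA file as a DNAStringSet
#' @param path FASTA path.
#' @return `Biostrings::DNAStringSet` with names truncated at the first space.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write sequences to FASTA
#' @param seqs named `DNAStringSet` (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}
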