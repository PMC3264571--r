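#' Between-breed fixed differences among all-callable monomorphic sites
#'
#' Restricts to sites called monomorphic in every breed (the determinable
#' base set), and emits one record per site where at least one pair of
#' breed consensus bases differs, with per-pair difference counts.
#'
#' @param calls multi-breed calls table from [call_all()].
#' @return list with `differences` (data.table: contig, pos, one consensus
#'   column per breed, `differing_pairs` as "a|b" semicolon-joined),
#'   `pair_counts` (data.frame pair, n), and `n_determinable`.
#' @export
cross_breed_differences <- function(calls) {
  breeds <- sort(unique(calls$breed))
  if (length(breeds) < 2L)
    stop("at least two breeds are required for a between-breed comparison")
  w <- data.table::dcast(calls, contig + pos ~ breed,
                         value.var = c("status", "consensus"))
  stat <- as.matrix(w[, paste0("status_", breeds), with = FALSE])
  mono <- !is.na(stat) & stat == "monomorphic"
  det <- rowSums(mono) == length(breeds)
  n_det <- sum(det)
  if (n_det == 0L)
    warning("no site is monomorphic-callable in all breeds")
  cons <- as.matrix(w[, paste0("consensus_", breeds), with = FALSE])[det, ,
                                                                     drop = FALSE]
  base <- w[det, .(contig, pos)]
  pairs <- utils::combn(breeds, 2L)
  pair_lab <- apply(pairs, 2L, paste, collapse = "|")
  diff_mat <- sapply(seq_len(ncol(pairs)), function(k) {
    cons[, match(pairs[1, k], breeds)] != cons[, match(pairs[2, k], breeds)]
  })
  if (n_det == 1L) diff_mat <- matrix(diff_mat, nrow = 1L)
  if (n_det == 0L) diff_mat <- matrix(logical(0), ncol = ncol(pairs))
  any_diff <- rowSums(diff_mat) > 0L
  differences <- base[any_diff]
  consd <- cons[any_diff, , drop = FALSE]
  colnames(consd) <- paste0("consensus_", breeds)
  differences <- cbind(differences, data.table::as.data.table(consd))
  differences[, differing_pairs := apply(
    diff_mat[any_diff, , drop = FALSE], 1L,
    function(z) paste(pair_lab[z], collapse = ";"))]
  pair_counts <- data.frame(pair = pair_lab, n = colSums(diff_mat),
                            stringsAsFactors = FALSE)
  list(differences = differences[], pair_counts = pair_counts,
       n_determinable = n_det)
}

# CDS genomic positions of one transcript in transcript 5'->3' order
cds_posmap <- function(ann, tx) {
  cd <- tx_cds(ann, tx)
  pos <- unlist(mapply(function(s, e) s:(e - 1L), cd$start, cd$end,
                       SIMPLIFY = FALSE), use.names = FALSE)
  if (tx_strand(ann, tx) == "-") pos <- rev(pos)
  as.integer(pos)
}

#' Annotate the coding effect of between-breed differences
#'
#' Locates each difference in the gene models: positions inside a CDS get
#' their codon identified through the CDS reading frame on the transcript
#' strand and the effect classified by translating reference versus
#' alternate codon (`synonymous`, `nonsynonymous`, `stop_gained`,
#' `stop_lost`); exonic positions outside any CDS are `exonic-noncoding`;
#' everything else is `other`.  When a position lies in several CDS
#' transcripts the one with the longest CDS wins (ties by transcript id).
#'
#' @param diffs `differences` table from [cross_breed_differences()].
#' @param annotation a [tx_annotation()].
#' @param reference named `DNAStringSet` (or character) reference genome.
#' @return the input table completed with `region`, `gene`, `transcript`,
#'   `ref`, `alt`, `codon_ref`, `codon_alt`, `aa_ref`, `aa_alt`, `effect`.
#' @export
annotate_effect <- function(diffs, annotation, reference) {
  if (is.character(reference)) reference <- Biostrings::DNAStringSet(reference)
  refch <- lapply(seq_along(reference), function(i)
    strsplit(as.character(reference[[i]]), "", fixed = TRUE)[[1]])
  names(refch) <- names(reference)

  cds_tab <- annotation$cds
  cds_tab$gene <- annotation$transcripts$gene_id[
    match(cds_tab$transcript_id, annotation$transcripts$transcript_id)]
  cds_tab$contig <- annotation$transcripts$contig[
    match(cds_tab$transcript_id, annotation$transcripts$transcript_id)]
  cds_len <- tapply(cds_tab$end - cds_tab$start, cds_tab$transcript_id, sum)
  ex_tab <- annotation$exons
  ex_tab$contig <- annotation$transcripts$contig[
    match(ex_tab$transcript_id, annotation$transcripts$transcript_id)]

  n <- nrow(diffs)
  region <- character(n); gene <- rep(NA_character_, n)
  transcript <- rep(NA_character_, n)
  refb <- character(n); altb <- rep(NA_character_, n)
  codon_ref <- rep(NA_character_, n); codon_alt <- rep(NA_character_, n)
  aa_ref <- rep(NA_character_, n); aa_alt <- rep(NA_character_, n)
  effect <- rep("none", n)
  cons_cols <- grep("^consensus_", names(diffs), value = TRUE)
  pm_cache <- list()

  for (i in seq_len(n)) {
    p <- diffs$pos[i]; ctg <- diffs$contig[i]
    if (!ctg %in% names(refch) || p >= length(refch[[ctg]]))
      stop("coordinate error: position outside reference contigs")
    rb <- refch[[ctg]][p + 1L]
    refb[i] <- rb
    cons <- unlist(diffs[i, cons_cols, with = FALSE])
    alts <- sort(setdiff(unique(cons), rb))
    if (length(alts)) altb[i] <- alts[1]

    in_cds <- which(cds_tab$contig == ctg & cds_tab$start <= p & p < cds_tab$end)
    if (length(in_cds)) {
      txs <- unique(cds_tab$transcript_id[in_cds])
      txs <- txs[order(-cds_len[txs], txs)]
      tx <- txs[1]
      region[i] <- "CDS"
      transcript[i] <- tx
      gene[i] <- cds_tab$gene[match(tx, cds_tab$transcript_id)]
      strand <- tx_strand(annotation, tx)
      if (is.null(pm_cache[[tx]])) pm_cache[[tx]] <- cds_posmap(annotation, tx)
      pm <- pm_cache[[tx]]
      idx <- match(p, pm) - 1L
      ci <- idx %/% 3L
      cpos <- pm[(3L * ci + 1L):(3L * ci + 3L)]
      rc <- refch[[ctg]][cpos + 1L]
      if (strand == "-") rc <- comp_base(rc)
      within <- idx %% 3L + 1L
      ac <- rc
      if (!is.na(altb[i]))
        ac[within] <- if (strand == "-") comp_base(altb[i]) else altb[i]
      codon_ref[i] <- paste(rc, collapse = "")
      codon_alt[i] <- paste(ac, collapse = "")
      if (!is.na(altb[i])) {
        cls <- classify_codon_change(codon_ref[i], codon_alt[i])
        effect[i] <- cls$effect
        aa_ref[i] <- cls$aa_ref; aa_alt[i] <- cls$aa_alt
      }
    } else {
      in_ex <- which(ex_tab$contig == ctg & ex_tab$start <= p & p < ex_tab$end)
      region[i] <- if (length(in_ex)) "exonic-noncoding" else "other"
      if (length(in_ex)) {
        tx <- sort(ex_tab$transcript_id[in_ex])[1]
        gene[i] <- annotation$transcripts$gene_id[
          match(tx, annotation$transcripts$transcript_id)]
      }
    }
  }
  out <- data.table::copy(diffs)
  out[, `:=`(region = region, gene = gene, transcript = transcript,
             ref = refb, alt = altb, codon_ref = codon_ref,
             codon_alt = codon_alt, aa_ref = aa_ref, aa_alt = aa_alt,
             effect = effect)]
  out[]
}

#' Genes with sufficient CDS coverage
#'
#' A gene is retained when the fraction of its CDS bases (union over
#' transcripts) covered by at least `min_cov` deduplicated fragments
#' reaches `min_frac`.  Genes without CDS records are excluded.
#'
#' @param annotation a [tx_annotation()].
#' @param counts single-breed `allele_counts` table (or filtered subset).
#' @param min_frac minimum covered CDS fraction (default 0.5, inclusive).
#' @param min_cov minimum fragment depth (default 10).
#' @return character vector of retained gene ids.
#' @export
genes_with_cds_coverage <- function(annotation, counts, min_frac = 0.5,
                                    min_cov = 10L) {
  if (length(unique(counts$breed)) > 1L)
    stop("supply a single breed's counts (filter the table by breed)")
  depth_map <- counts[, .(contig, pos, depth)]
  data.table::setkey(depth_map, contig, pos)
  cds <- annotation$cds
  if (!nrow(cds)) return(character(0))
  cds$gene <- annotation$transcripts$gene_id[
    match(cds$transcript_id, annotation$transcripts$transcript_id)]
  cds$contig <- annotation$transcripts$contig[
    match(cds$transcript_id, annotation$transcripts$transcript_id)]
  keep <- character(0)
  for (g in sort(unique(annotation$transcripts$gene_id))) {
    sub <- cds[cds$gene == g, , drop = FALSE]
    if (!nrow(sub)) next
    cds_pos <- unique(unlist(mapply(function(s, e) s:(e - 1L), sub$start,
                                    sub$end, SIMPLIFY = FALSE),
                             use.names = FALSE))
    want <- data.table::data.table(contig = sub$contig[1],
                                   pos = as.integer(cds_pos))
    qq <- depth_map[want, on = c("contig", "pos")]
    covered <- sum(!is.na(qq$depth) & qq$depth >= min_cov)
    if (covered / length(cds_pos) >= min_frac) keep <- c(keep, g)
  }
  keep
}

#' Flag transcripts as intergenic
#'
#' TRUE when the minimum distance from the interval to any annotated gene
#' span (strand-ignoring) is at least `min_dist` base pairs.  Overlap means
#' distance zero.  An empty annotation flags everything intergenic.
#'
#' @param intervals data.frame with `contig`, `start`, `end` (0-based
#'   half-open).
#' @param annotation a [tx_annotation()].
#' @param min_dist minimum distance in bp (default 1000, inclusive).
#' @return logical vector, one flag per interval.
#' @export
flag_intergenic <- function(intervals, annotation, min_dist = 1000L) {
  g <- annotation$genes
  vapply(seq_len(nrow(intervals)), function(i) {
    gg <- g[g$contig == intervals$contig[i], , drop = FALSE]
    if (!nrow(gg)) return(TRUE)
    d <- pmax(0L, gg$start - intervals$end[i], intervals$start[i] - gg$end)
    min(d) >= min_dist
  }, logical(1))
}

#' Write annotated differences as TSV (1-based positions)
#' @param diffs completed differences from [annotate_effect()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_differences <- function(diffs, path) {
  out <- data.table::copy(diffs)
  out[, pos := pos + 1L]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
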