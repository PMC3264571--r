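#' Spike fixed differences and within-breed SNPs into breed haplotypes
#'
#' Fixed differences alter exactly one breed's haplotype (assigned round
#' robin across breeds); a fraction `frac_coding_diffs` is placed inside
#' CDS, the remainder in exonic non-coding (UTR) positions.  The expected
#' coding effect of each CDS change is recorded by translating the
#' reference and alternate codons.  When coding differences are requested
#' and space permits, the first spiked change is a premature stop codon
#' truncating the final five amino acids of some gene.  Within-breed SNP
#' records do not alter the haplotype; they carry a minor-allele fraction
#' that the fragment simulator uses when sampling reads.
#'
#' @param reference named `DNAStringSet` reference genome.
#' @param annotation a [tx_annotation()].
#' @param config a [sim_config()].
#' @return list with `haplotypes` (per-breed named character vectors of
#'   contig sequences) and `truth` (data.frame of variant-truth records:
#'   contig, 0-based pos, kind, breed, ref/alt genomic bases, minor_frac,
#'   region, gene, transcript, codon/aa fields, expected_effect).
#' @export
spike_variants <- function(reference, annotation, config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)

  contig <- names(reference)[1]
  ref_chars <- strsplit(as.character(reference[[1]]), "", fixed = TRUE)[[1]]
  breeds <- config$breeds

  # Strand-balanced positions: under FR pairing the genome-left `read_len`
  # transcribed bases of a locus receive forward reads only, so the
  # both-strands criterion abstains there.  Variants are preferentially
  # placed outside this margin so clean recovery is well defined.
  balanced <- integer(0)
  for (t in unique(annotation$exons$transcript_id)) {
    pm <- tx_posmap(annotation, t)
    L <- length(pm)
    if (L <= config$read_len) next
    drop <- if (tx_strand(annotation, t) == "+")
      seq_len(config$read_len) else (L - config$read_len + 1L):L
    balanced <- c(balanced, pm[-drop])
  }
  balanced <- unique(balanced)

  # CDS codon pool: primary transcripts, codons 2..(k-1) (skip ATG and stop)
  cds_pool <- list()
  for (tx in unique(annotation$cds$transcript_id)) {
    strand <- tx_strand(annotation, tx)
    gid <- annotation$transcripts$gene_id[
      match(tx, annotation$transcripts$transcript_id)]
    cd <- tx_cds(annotation, tx)
    pos <- unlist(mapply(function(s, e) s:(e - 1L), cd$start, cd$end,
                         SIMPLIFY = FALSE), use.names = FALSE)
    if (strand == "-") pos <- rev(pos)  # transcript 5'->3' order
    k <- length(pos) %/% 3L
    for (ci in 2:(k - 1L)) {
      cds_pool[[length(cds_pool) + 1L]] <-
        list(tx = tx, gene = gid, strand = strand, codon_idx = ci,
             gpos = pos[(3L * (ci - 1L) + 1L):(3L * ci)])
    }
  }

  # exonic non-coding (UTR) position pool
  exonic <- unique(unlist(mapply(function(s, e) s:(e - 1L),
                                 annotation$exons$start, annotation$exons$end,
                                 SIMPLIFY = FALSE), use.names = FALSE))
  cds_positions <- unique(unlist(mapply(function(s, e) s:(e - 1L),
                                        annotation$cds$start, annotation$cds$end,
                                        SIMPLIFY = FALSE), use.names = FALSE))
  utr_pool <- setdiff(exonic, cds_positions)

  pos2gene <- function(p) {
    g <- annotation$genes
    hit <- which(g$start <= p & p < g$end)
    if (length(hit)) g$gene_id[hit[1]] else NA_character_
  }

  truth <- list()
  used_pos <- integer(0)
  used_codon <- character(0)  # "tx:codon_idx"

  codon_balanced <- vapply(cds_pool, function(e)
    all(e$gpos %in% balanced), logical(1))
  if (sum(codon_balanced) >= round(config$frac_coding_diffs * config$n_fixed_diffs))
    cds_pool <- cds_pool[codon_balanced]
  utr_pool_bal <- intersect(utr_pool, balanced)

  n_fix <- config$n_fixed_diffs
  n_coding <- round(config$frac_coding_diffs * n_fix)
  n_noncoding <- n_fix - n_coding
  if (n_coding > length(cds_pool))
    stop("configuration error: more coding differences requested than available CDS codons")
  if (n_noncoding > length(utr_pool))
    stop("configuration error: more non-coding differences requested than available UTR positions")

  hap_chars <- stats::setNames(
    lapply(breeds, function(b) ref_chars), breeds)

  codon_of <- function(gpos, strand) {
    cc <- ref_chars[gpos + 1L]
    if (strand == "-") cc <- comp_base(cc)
    paste(cc, collapse = "")
  }

  emit_coding <- function(entry, within_codon, alt_tx_base, breed) {
    # within_codon: 1..3 position on transcript strand
    gp <- entry$gpos[within_codon]
    ref_codon <- codon_of(entry$gpos, entry$strand)
    cvec <- strsplit(ref_codon, "")[[1]]
    cvec[within_codon] <- alt_tx_base
    alt_codon <- paste(cvec, collapse = "")
    cls <- classify_codon_change(ref_codon, alt_codon)
    alt_genomic <- if (entry$strand == "-") comp_base(alt_tx_base) else alt_tx_base
    ref_genomic <- ref_chars[gp + 1L]
    hap_chars[[breed]][gp + 1L] <<- alt_genomic
    truth[[length(truth) + 1L]] <<- data.frame(
      contig = contig, pos = gp, kind = "fixed_between", breed = breed,
      ref = ref_genomic, alt = alt_genomic, minor_frac = NA_real_,
      region = "CDS", gene = entry$gene, transcript = entry$tx,
      codon_ref = ref_codon, codon_alt = alt_codon,
      aa_ref = cls$aa_ref, aa_alt = cls$aa_alt,
      expected_effect = cls$effect, well_covered = gp %in% balanced,
      stringsAsFactors = FALSE)
    used_pos <<- c(used_pos, gp)
    used_codon <<- c(used_codon, paste0(entry$tx, ":", entry$codon_idx))
  }

  breed_cycle <- function(i) breeds[((i - 1L) %% length(breeds)) + 1L]
  spiked <- 0L

  # guaranteed premature stop truncating the final 5 codons, when possible
  if (n_coding > 0L) {
    placed <- FALSE
    for (entry in cds_pool) {
      cd <- tx_cds(annotation, entry$tx)
      k <- sum(cd$end - cd$start) %/% 3L
      if (entry$codon_idx != k - 5L) next
      edits <- stop_gaining_edits(codon_of(entry$gpos, entry$strand))
      if (!length(edits)) next
      ed <- edits[[1]]
      spiked <- spiked + 1L
      emit_coding(entry, ed$pos, ed$base, breed_cycle(spiked))
      placed <- TRUE
      break
    }
    if (!placed)
      warning("no codon available for a premature-stop spike truncating the final 5 codons")
  }

  # remaining coding differences
  avail <- which(!vapply(cds_pool, function(e)
    paste0(e$tx, ":", e$codon_idx) %in% used_codon, logical(1)))
  pick <- avail[sample.int(length(avail), n_coding - spiked)]
  for (ix in pick) {
    entry <- cds_pool[[ix]]
    within <- sample(1:3, 1L)
    ref_codon <- codon_of(entry$gpos, entry$strand)
    ref_tx_base <- substr(ref_codon, within, within)
    alt_tx_base <- sample(setdiff(BASES, ref_tx_base), 1L)
    spiked <- spiked + 1L
    emit_coding(entry, within, alt_tx_base, breed_cycle(spiked))
  }

  # non-coding (UTR exonic) fixed differences
  pool <- setdiff(if (length(utr_pool_bal) >= n_noncoding) utr_pool_bal
                  else utr_pool, used_pos)
  pick <- if (n_noncoding > 0) pool[sample.int(length(pool), n_noncoding)] else integer(0)
  for (gp in pick) {
    spiked <- spiked + 1L
    breed <- breed_cycle(spiked)
    ref_b <- ref_chars[gp + 1L]
    alt_b <- sample(setdiff(BASES, ref_b), 1L)
    hap_chars[[breed]][gp + 1L] <- alt_b
    truth[[length(truth) + 1L]] <- data.frame(
      contig = contig, pos = gp, kind = "fixed_between", breed = breed,
      ref = ref_b, alt = alt_b, minor_frac = NA_real_,
      region = "UTR", gene = pos2gene(gp), transcript = NA_character_,
      codon_ref = NA_character_, codon_alt = NA_character_,
      aa_ref = NA_character_, aa_alt = NA_character_,
      expected_effect = "none", well_covered = gp %in% balanced,
      stringsAsFactors = FALSE)
    used_pos <- c(used_pos, gp)
  }

  # within-breed SNPs: haplotype untouched; reads will carry the minor allele
  mf_cycle <- config$minor_allele_fracs
  exonic_bal <- intersect(exonic, balanced)
  for (b in breeds) {
    pool <- setdiff(if (length(exonic_bal) >= config$n_within_snps * length(breeds))
      exonic_bal else exonic, used_pos)
    if (config$n_within_snps > length(pool))
      stop("configuration error: more within-SNPs requested than available exonic positions")
    pick <- if (config$n_within_snps > 0)
      pool[sample.int(length(pool), config$n_within_snps)] else integer(0)
    for (j in seq_along(pick)) {
      gp <- pick[j]
      ref_b <- ref_chars[gp + 1L]
      minor <- sample(setdiff(BASES, ref_b), 1L)
      truth[[length(truth) + 1L]] <- data.frame(
        contig = contig, pos = gp, kind = "snp_within", breed = b,
        ref = ref_b, alt = minor,
        minor_frac = mf_cycle[((j - 1L) %% length(mf_cycle)) + 1L],
        region = if (gp %in% cds_positions) "CDS" else "UTR",
        gene = pos2gene(gp), transcript = NA_character_,
        codon_ref = NA_character_, codon_alt = NA_character_,
        aa_ref = NA_character_, aa_alt = NA_character_,
        expected_effect = NA_character_, well_covered = gp %in% balanced,
        stringsAsFactors = FALSE)
      used_pos <- c(used_pos, gp)
    }
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(contig = character(), pos = integer(), kind = character(),
               breed = character(), ref = character(), alt = character(),
               minor_frac = numeric(), region = character(),
               gene = character(), transcript = character(),
               codon_ref = character(), codon_alt = character(),
               aa_ref = character(), aa_alt = character(),
               expected_effect = character(), well_covered = logical(),
               stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  haplotypes <- lapply(hap_chars, function(ch)
    stats::setNames(paste(ch, collapse = ""), contig))
  list(haplotypes = haplotypes, truth = truth)
}
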