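#' Calling thresholds for site classification
#'
#' Coverage and polymorphism filters: a site is callable when covered by at
#' least `min_coverage` deduplicated fragments; a polymorphic call requires
#' (1) a minor-allele read fraction of at least `minor_frac`, (2) both top
#' alleles supported by at least one read on each strand with base quality
#' at least `min_qual`, and (3) the two most frequent alleles jointly
#' accounting for at least `top2_frac` of the reads.
#'
#' @param min_coverage minimum fragment depth (default 10).
#' @param minor_frac minimum minor-allele fraction (default 0.10).
#' @param min_qual minimum base quality, Phred (default 20).
#' @param top2_frac minimum joint fraction of the top two alleles
#'   (default 0.90).
#' @return list of class `calling_thresholds`.
#' @export
calling_thresholds <- function(min_coverage = 10L, minor_frac = 0.10,
                               min_qual = 20L, top2_frac = 0.90) {
  stopifnot(min_coverage >= 1, minor_frac > 0, minor_frac <= 0.5,
            top2_frac > 0, top2_frac <= 1)
  structure(list(min_coverage = as.integer(min_coverage),
                 minor_frac = minor_frac,
                 min_qual = as.integer(min_qual),
                 top2_frac = top2_frac),
            class = "calling_thresholds")
}

#' Build per-site allele counts from SAM alignments
#'
#' Tallies base observations per (breed, contig, position) from primary,
#' uniquely-mapped (NH tag), non-duplicate records.  Spliced alignments
#' contribute nothing inside N-skipped introns.  Overlapping mates of one
#' fragment are deduplicated so each fragment contributes at most one count
#' per site, keeping the higher-quality base call.  Counts are split by
#' base, strand, and whether base quality reaches `thresholds$min_qual`.
#'
#' @param sam named character vector of SAM paths (names are breed labels;
#'   a single unnamed path is labelled "pool").
#' @param thresholds a [calling_thresholds()].
#' @return `data.table` of class `allele_counts` with columns `breed`,
#'   `contig`, `pos` (0-based), `depth`, `n_<base>_<f|r>` (all reads) and
#'   `q_<base>_<f|r>` (quality-passing reads).
#' @export
build_pileup <- function(sam, thresholds = calling_thresholds()) {
  if (is.null(names(sam)))
    names(sam) <- if (length(sam) == 1L) "pool" else
      paste0("pool", seq_along(sam))
  out <- list()
  skipped <- integer(0)
  for (b in names(sam)) {
    pr <- parse_sam_records(sam[[b]])
    skipped[b] <- pr$n_skipped
    rec <- sam_usable(pr$records)
    if (!nrow(rec)) next
    blk <- cigar_m_blocks(rec)

    # per-base expansion
    idx <- sequence(blk$len)
    pos <- rep(blk$rstart, blk$len) + idx - 1L
    recv <- rep(blk$rec, blk$len)
    qoff <- rep(blk$qstart, blk$len) + idx  # 1-based index into SEQ

    seq_cat <- paste(rec$seq, collapse = "")
    qual_cat <- paste(rec$qual, collapse = "")
    soff <- c(0L, cumsum(nchar(rec$seq)))
    gidx <- soff[recv] + qoff
    seq_raw <- as.integer(charToRaw(seq_cat))
    qual_raw <- as.integer(charToRaw(qual_cat))
    lut <- integer(256L)
    lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
    lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L

    dt <- data.table::data.table(
      contig = rec$contig[recv],
      pos = pos,
      qname = rec$qname[recv],
      strand = c("f", "r")[1L + (bitwAnd(rec$flag[recv], 0x10L) > 0L)],
      base = lut[seq_raw[gidx]],
      qual = qual_raw[gidx] - 33L)
    dt <- dt[base > 0L]

    # fragment deduplication: keep the higher-quality call of the two mates
    data.table::setorder(dt, contig, pos, qname, -qual, strand)
    dt <- unique(dt, by = c("contig", "pos", "qname"))

    dt[, grp := paste0(c("A", "C", "G", "T")[base], "_", strand)]
    lev <- as.vector(outer(c("A", "C", "G", "T"), c("f", "r"),
                           function(x, y) paste0(x, "_", y)))
    all_w <- data.table::dcast(dt[, .N, by = .(contig, pos, grp)],
                               contig + pos ~ factor(grp, levels = lev),
                               value.var = "N", fill = 0L, drop = FALSE)
    q_w <- data.table::dcast(dt[qual >= thresholds$min_qual,
                                .N, by = .(contig, pos, grp)],
                             contig + pos ~ factor(grp, levels = lev),
                             value.var = "N", fill = 0L, drop = FALSE)
    data.table::setnames(all_w, lev, paste0("n_", lev), skip_absent = TRUE)
    for (cn in paste0("n_", lev)) if (!cn %in% names(all_w)) all_w[, (cn) := 0L]
    data.table::setnames(q_w, lev, paste0("q_", lev), skip_absent = TRUE)
    for (cn in paste0("q_", lev)) if (!cn %in% names(q_w)) q_w[, (cn) := 0L]
    w <- merge(all_w, q_w, by = c("contig", "pos"), all.x = TRUE)
    for (cn in paste0("q_", lev)) w[is.na(get(cn)), (cn) := 0L]
    w[, depth := rowSums(.SD), .SDcols = paste0("n_", lev)]
    w[, breed := b]
    out[[b]] <- w
  }
  res <- data.table::rbindlist(out, use.names = TRUE)
  if (!nrow(res))
    res <- data.table::data.table(contig = character(), pos = integer(),
                                  breed = character(), depth = integer())
  data.table::setcolorder(res, c("breed", "contig", "pos", "depth"))
  data.table::setattr(res, "thresholds", thresholds)
  data.table::setattr(res, "n_skipped", skipped)
  data.table::setattr(res, "class", c("allele_counts", class(res)))
  res[]
}

# vectorized site classification on an allele_counts table
call_sites_internal <- function(w, thresholds) {
  lev <- as.vector(outer(c("A", "C", "G", "T"), c("f", "r"),
                         function(x, y) paste0(x, "_", y)))
  nm <- as.matrix(w[, paste0("n_", lev), with = FALSE])
  qm <- as.matrix(w[, paste0("q_", lev), with = FALSE])
  cnt <- nm[, 1:4, drop = FALSE] + nm[, 5:8, drop = FALSE]       # per base
  qf <- qm[, 1:4, drop = FALSE]; qr <- qm[, 5:8, drop = FALSE]
  depth <- rowSums(cnt)
  n <- nrow(w)
  i1 <- max.col(cnt, ties.method = "first")   # base order A<C<G<T on ties
  top1 <- cnt[cbind(seq_len(n), i1)]
  cnt2 <- cnt; cnt2[cbind(seq_len(n), i1)] <- -1L
  i2 <- max.col(cnt2, ties.method = "first")
  top2 <- pmax(cnt2[cbind(seq_len(n), i2)], 0L)
  sup <- (qf > 0L) & (qr > 0L)                 # both strands at >= min_qual
  sup1 <- sup[cbind(seq_len(n), i1)]
  sup2 <- sup[cbind(seq_len(n), i2)]
  f_minor <- ifelse(depth > 0, top2 / depth, 0)
  eps <- 1e-9
  top2_ok <- (top1 + top2) >= thresholds$top2_frac * depth - eps
  top1_ok <- top1 >= thresholds$top2_frac * depth - eps

  status <- rep("ambiguous", n)
  consensus <- rep(NA_character_, n)
  poly <- f_minor >= thresholds$minor_frac - eps & sup1 & sup2 & top2_ok
  mono <- f_minor < thresholds$minor_frac - eps & top1_ok & sup1
  status[poly] <- "polymorphic"
  status[!poly & mono] <- "monomorphic"
  consensus[!poly & mono] <- c("A", "C", "G", "T")[i1[!poly & mono]]
  unc <- depth < thresholds$min_coverage
  status[unc] <- "uncallable"
  consensus[unc] <- NA_character_
  list(status = status, consensus = consensus, depth = depth,
       top1 = c("A", "C", "G", "T")[i1], top2 = c("A", "C", "G", "T")[i2],
       n_top1 = top1, n_top2 = top2)
}

#' Classify a single site from its allele counts
#'
#' Applies the coverage and polymorphism filters to one site.  A site is
#' `uncallable` below `min_coverage`; `polymorphic` when the minor fraction,
#' strand/quality support of both top alleles, and top-two dominance
#' criteria all hold; `monomorphic` (with a consensus base) when the minor
#' fraction is below threshold and the top base is dominant and supported
#' on both strands at quality; otherwise `ambiguous`.
#'
#' @param counts 4x2 integer matrix of read counts, rows A,C,G,T, columns
#'   forward/reverse strand.
#' @param counts_q 4x2 matrix restricted to reads with base quality >=
#'   `thresholds$min_qual` (defaults to `counts`, i.e. all reads pass).
#' @param thresholds a [calling_thresholds()].
#' @return list with `status`, `consensus` (base or NA), `depth`.
#' @export
call_site <- function(counts, counts_q = counts,
                      thresholds = calling_thresholds()) {
  stopifnot(all(dim(counts) == c(4, 2)), all(dim(counts_q) == c(4, 2)),
            all(counts_q <= counts))
  lev <- as.vector(outer(c("A", "C", "G", "T"), c("f", "r"),
                         function(x, y) paste0(x, "_", y)))
  w <- data.table::as.data.table(
    c(stats::setNames(as.list(as.vector(counts)), paste0("n_", lev)),
      stats::setNames(as.list(as.vector(counts_q)), paste0("q_", lev))))
  r <- call_sites_internal(w, thresholds)
  list(status = r$status, consensus = r$consensus, depth = r$depth)
}

#' Call all sites of an allele-count table
#'
#' Vectorized site classification plus a per-breed summary of surveyed
#' sites (depth at or above the coverage floor) and polymorphic calls,
#' with the SNP percentage reported to three decimals.
#'
#' @param counts an `allele_counts` table from [build_pileup()].
#' @param thresholds a [calling_thresholds()] (defaults to the thresholds
#'   the pileup was built with).
#' @return list with `calls` (data.table breed, contig, pos, status,
#'   consensus, depth) and `summary` (data.frame breed, n_surveyed,
#'   n_polymorphic, pct_polymorphic).
#' @export
call_all <- function(counts, thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- attr(counts, "thresholds")
  if (is.null(thresholds)) thresholds <- calling_thresholds()
  if (!nrow(counts)) {
    warning("empty allele-count table")
    return(list(calls = data.table::data.table(
      breed = character(), contig = character(), pos = integer(),
      status = character(), consensus = character(), depth = integer()),
      summary = data.frame(breed = character(), n_surveyed = integer(),
                           n_polymorphic = integer(),
                           pct_polymorphic = numeric())))
  }
  r <- call_sites_internal(counts, thresholds)
  calls <- data.table::data.table(
    breed = counts$breed, contig = counts$contig, pos = counts$pos,
    status = r$status, consensus = r$consensus, depth = r$depth,
    top1 = r$top1, top2 = r$top2, n_top1 = r$n_top1, n_top2 = r$n_top2)
  summ <- calls[, .(n_surveyed = sum(depth >= thresholds$min_coverage),
                    n_polymorphic = sum(status == "polymorphic")),
                by = breed]
  summ[, pct_polymorphic := round_half_up(
    100 * n_polymorphic / pmax(n_surveyed, 1L), 3L)]
  list(calls = calls[, .(breed, contig, pos, status, consensus, depth,
                         top1, top2, n_top1, n_top2)],
       summary = as.data.frame(summ))
}

#' Write site calls as TSV (1-based positions)
#' @param calls calls table from [call_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_calls <- function(calls, path) {
  out <- data.table::copy(calls)[, .(breed, contig, pos = pos + 1L,
                                     status, consensus, depth)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write polymorphic sites as a minimal VCF v4.2
#'
#' One record per polymorphic site per breed; REF is the major and ALT the
#' minor allele at the site, with `AF` the minor read fraction and the
#' breed recorded in INFO.
#'
#' @param calls calls table from [call_all()].
#' @param path output path.
#' @param contigs optional named contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_polymorphic_vcf <- function(calls, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=AF,Number=1,Type=Float,Description="Minor allele read fraction">',
           '##INFO=<ID=BREED,Number=1,Type=String,Description="Breed pool">',
           '##INFO=<ID=DP,Number=1,Type=Integer,Description="Fragment depth">')
  if (!is.null(contigs))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                          as.integer(contigs)))
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  p <- calls[status == "polymorphic"]
  body <- if (nrow(p)) sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.4f;BREED=%s;DP=%d",
    p$contig, p$pos + 1L, p$top1, p$top2, p$n_top2 / p$depth,
    p$breed, p$depth) else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
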