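# Minimal SAM v1 text parsing tailored to the pileup and fragment-counting
# needs of this package: mandatory columns, NH tag, and spliced CIGAR block
# arithmetic.  Records whose CIGAR-implied query length disagrees with the
# sequence length are skipped and counted.

parse_sam_records <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  empty <- data.table::data.table(
    qname = character(), flag = integer(), contig = character(),
    pos = integer(), mapq = integer(), cigar = character(),
    seq = character(), qual = character(), nh = integer())
  if (!length(ln)) return(list(records = empty, n_skipped = 0L))
  f <- data.table::tstrsplit(ln, "\t", fixed = TRUE, keep = 1:11)
  r <- regexpr("NH:i:[0-9]+", ln)
  nh <- ifelse(r > 0L,
               suppressWarnings(as.integer(substr(ln, r + 5L,
                                                  r + attr(r, "match.length") - 1L))),
               NA_integer_)
  rec <- data.table::data.table(
    qname = f[[1]], flag = as.integer(f[[2]]), contig = f[[3]],
    pos = as.integer(f[[4]]) - 1L, mapq = as.integer(f[[5]]),
    cigar = f[[6]], seq = f[[10]], qual = f[[11]], nh = nh)

  # record-level sanity: CIGAR query length must match SEQ length
  qlen <- cigar_query_length(rec$cigar)
  bad <- !is.na(qlen) & rec$seq != "*" & qlen != nchar(rec$seq)
  bad[is.na(bad)] <- FALSE
  n_skipped <- sum(bad)
  if (n_skipped > 0) {
    warning(n_skipped, " malformed SAM record(s) skipped")
    rec <- rec[!bad]
  }
  list(records = rec, n_skipped = n_skipped)
}

cigar_ops <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)
  ops <- regmatches(cigar, m)
  nops <- lengths(ops)
  op <- unlist(ops, use.names = FALSE)
  list(rec = rep(seq_along(cigar), nops),
       len = as.integer(sub(".$", "", op)),
       type = substr(op, nchar(op), nchar(op)))
}

cigar_query_length <- function(cigar) {
  out <- rep(NA_integer_, length(cigar))
  valid <- cigar != "*" & !is.na(cigar)
  if (!any(valid)) return(out)
  oo <- cigar_ops(cigar[valid])
  q <- oo$len * (oo$type %in% c("M", "I", "S", "=", "X"))
  out[valid] <- as.integer(tapply(q, oo$rec, sum)[as.character(seq_len(sum(valid)))])
  out
}

# aligned M-blocks of each record: data.table(rec, rstart, len, qstart)
# rstart 0-based genomic, qstart 0-based offset into SEQ
cigar_m_blocks <- function(rec_dt) {
  oo <- cigar_ops(rec_dt$cigar)
  dt <- data.table::data.table(rec = oo$rec, len = oo$len, type = oo$type)
  dt[, refc := type %in% c("M", "D", "N", "=", "X")]
  dt[, qc := type %in% c("M", "I", "S", "=", "X")]
  dt[, ref_before := cumsum(data.table::shift(len * refc, fill = 0L)), by = rec]
  dt[, q_before := cumsum(data.table::shift(len * qc, fill = 0L)), by = rec]
  blk <- dt[type %in% c("M", "=", "X")]
  blk[, rstart := rec_dt$pos[rec] + ref_before]
  blk[, qstart := q_before]
  blk[, c("type", "refc", "qc", "ref_before", "q_before") := NULL]
  blk[]
}

# gaps (N ops) of each record: data.table(rec, gstart, gend) 0-based half-open
cigar_n_gaps <- function(rec_dt) {
  oo <- cigar_ops(rec_dt$cigar)
  dt <- data.table::data.table(rec = oo$rec, len = oo$len, type = oo$type)
  dt[, refc := type %in% c("M", "D", "N", "=", "X")]
  dt[, ref_before := cumsum(data.table::shift(len * refc, fill = 0L)), by = rec]
  gp <- dt[type == "N"]
  gp[, gstart := rec_dt$pos[rec] + ref_before]
  gp[, gend := gstart + len]
  gp[, c("type", "refc", "ref_before", "len") := NULL]
  gp[]
}

# primary, mapped, non-duplicate, uniquely-mapped records
sam_usable <- function(rec) {
  keep <- bitwAnd(rec$flag, 0x4L) == 0L &      # mapped
    bitwAnd(rec$flag, 0x100L) == 0L &          # primary
    bitwAnd(rec$flag, 0x400L) == 0L &          # not duplicate
    bitwAnd(rec$flag, 0x800L) == 0L            # not supplementary
  uniq <- is.na(rec$nh) | rec$nh == 1L
  rec[keep & uniq]
}
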