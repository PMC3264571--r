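#' Count fragments by isoform-compatibility class
#'
#' A fragment is compatible with an isoform when every aligned block of
#' both mates falls within the isoform's exons and every splice junction
#' used (N CIGAR gap) matches an exon-exon junction of that isoform.
#' Fragments per gene are grouped into classes keyed by their compatible
#' isoform set; fragments compatible with no isoform of any gene are
#' tallied separately.  Orphan mates count as single-end evidence.
#'
#' @param sam path to one breed's SAM file.
#' @param annotation a [tx_annotation()].
#' @return list with `classes` (data.table gene, isoforms "a|b", count),
#'   `n_unassigned`, and `library_size` (total mapped fragments).
#' @export
count_compatible_fragments <- function(sam, annotation) {
  rec <- sam_usable(parse_sam_records(sam)$records)
  if (!nrow(rec))
    return(list(classes = data.table::data.table(
      gene = character(), isoforms = character(), count = integer()),
      n_unassigned = 0L, library_size = 0L))
  blk <- cigar_m_blocks(rec)
  gaps <- cigar_n_gaps(rec)

  # per-fragment blocks and junctions (union over mates)
  qn <- rec$qname; ctgv <- rec$contig
  blk[, qname := qn[rec]]
  blk[, contig := ctgv[rec]]
  if (nrow(gaps)) gaps[, qname := qn[rec]] else gaps[, qname := character(0)]
  fb <- blk[, .(contig = contig[1],
                blocks = list(unique(cbind(rstart, rstart + len)))),
            by = qname]
  fj <- gaps[, .(junc = list(unique(cbind(gstart, gend)))), by = qname]
  lib_size <- length(unique(rec$qname))

  # per-gene isoform structures
  genes <- annotation$genes
  tx_by_gene <- split(annotation$transcripts$transcript_id,
                      annotation$transcripts$gene_id)
  iso_struct <- lapply(sort(unique(annotation$transcripts$transcript_id)),
                       function(t) {
    e <- tx_exons(annotation, t)
    list(exons = cbind(e$start, e$end),
         junc = as.matrix(tx_introns(e)))
  })
  names(iso_struct) <- sort(unique(annotation$transcripts$transcript_id))

  class_key <- character(0); class_gene <- character(0)
  class_count <- integer(0)
  bump <- new.env(parent = emptyenv())
  n_unassigned <- 0L

  data.table::setkey(fb, qname)
  junc_by_q <- stats::setNames(fj$junc, fj$qname)

  for (qi in seq_len(nrow(fb))) {
    q <- fb$qname[qi]
    bl <- fb$blocks[[qi]]
    jn <- junc_by_q[[q]]
    ctg <- fb$contig[qi]
    span_s <- min(bl[, 1]); span_e <- max(bl[, 2])
    cand_genes <- genes$gene_id[genes$contig == ctg &
                                  genes$start < span_e & genes$end > span_s]
    hit <- FALSE
    for (g in cand_genes) {
      compat <- character(0)
      for (t in tx_by_gene[[g]]) {
        st <- iso_struct[[t]]
        ok <- all(vapply(seq_len(nrow(bl)), function(k) {
          any(st$exons[, 1] <= bl[k, 1] & bl[k, 2] <= st$exons[, 2])
        }, logical(1)))
        if (ok && !is.null(jn) && nrow(jn)) {
          ok <- all(vapply(seq_len(nrow(jn)), function(k) {
            nrow(st$junc) > 0 &&
              any(st$junc[, 1] == jn[k, 1] & st$junc[, 2] == jn[k, 2])
          }, logical(1)))
        }
        if (ok) compat <- c(compat, t)
      }
      if (length(compat)) {
        hit <- TRUE
        key <- paste0(g, "\r", paste(sort(compat), collapse = "|"))
        cur <- if (!is.null(bump[[key]])) bump[[key]] else 0L
        bump[[key]] <- cur + 1L
      }
    }
    if (!hit) n_unassigned <- n_unassigned + 1L
  }

  keys <- ls(bump)
  if (length(keys)) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    classes <- data.table::data.table(
      gene = vapply(parts, `[`, "", 1L),
      isoforms = vapply(parts, `[`, "", 2L),
      count = vapply(keys, function(k) bump[[k]], integer(1)))
    data.table::setorder(classes, gene, isoforms)
  } else {
    classes <- data.table::data.table(gene = character(),
                                      isoforms = character(),
                                      count = integer())
  }
  list(classes = classes, n_unassigned = n_unassigned,
       library_size = lib_size)
}

#' Isoform abundance by expectation-maximization, with FPKM
#'
#' Per gene, a multinomial EM over isoform origin proportions: the E-step
#' splits each ambiguous fragment class among its compatible isoforms in
#' proportion to the current estimates, the M-step re-normalizes.  The
#' log-likelihood is non-decreasing; iteration stops when the relative
#' change of all proportions falls below `tol` or at `max_iter`.
#' FPKM uses the isoform's exonic length:
#' `FPKM = count / (l/1e3 * N/1e6)`.
#'
#' @param compat result of [count_compatible_fragments()].
#' @param annotation a [tx_annotation()].
#' @param max_iter maximum EM iterations (default 1000).
#' @param tol relative-change convergence tolerance (default 1e-8).
#' @param library_size total mapped fragments N (defaults to the count in
#'   `compat`).
#' @return data.table with one row per (gene, isoform): expected `count`,
#'   exonic `length`, `fpkm`; attribute `gene_fpkm` holds the per-gene sums.
#' @export
em_isoform_abundance <- function(compat, annotation, max_iter = 1000L,
                                 tol = 1e-8, library_size = NULL) {
  N <- if (is.null(library_size)) compat$library_size else library_size
  tx_by_gene <- split(annotation$transcripts$transcript_id,
                      annotation$transcripts$gene_id)
  rows <- list()
  for (g in sort(names(tx_by_gene))) {
    txs <- sort(tx_by_gene[[g]])
    lens <- vapply(txs, function(t) as.numeric(tx_length(annotation, t)),
                   numeric(1))
    if (any(lens <= 0)) stop("isoform with non-positive effective length")
    cls <- compat$classes[compat$classes$gene == g, ]
    K <- length(txs)
    if (!nrow(cls)) {
      rows[[g]] <- data.table::data.table(gene = g, isoform = txs,
                                          count = 0, length = lens, fpkm = 0)
      next
    }
    sets <- strsplit(cls$isoforms, "|", fixed = TRUE)
    A <- matrix(FALSE, nrow = nrow(cls), ncol = K,
                dimnames = list(NULL, txs))
    for (i in seq_along(sets)) A[i, sets[[i]]] <- TRUE
    ncl <- cls$count
    alpha <- rep(1 / K, K)
    for (it in seq_len(max_iter)) {
      denom <- as.vector(A %*% alpha)
      W <- A * rep(alpha, each = nrow(A)) / denom      # E-step responsibilities
      ec <- colSums(W * ncl)
      alpha_new <- ec / sum(ncl)
      if (max(abs(alpha_new - alpha) / pmax(alpha, 1e-12)) < tol) {
        alpha <- alpha_new
        break
      }
      alpha <- alpha_new
    }
    denom <- as.vector(A %*% alpha)
    ec <- colSums(A * rep(alpha, each = nrow(A)) / denom * ncl)
    fpkm <- ec / (lens / 1e3 * N / 1e6)
    rows[[g]] <- data.table::data.table(gene = g, isoform = txs,
                                        count = ec, length = lens,
                                        fpkm = fpkm)
  }
  out <- data.table::rbindlist(rows)
  gf <- out[, .(fpkm = sum(fpkm), count = sum(count)), by = gene]
  data.table::setattr(out, "gene_fpkm", as.data.frame(gf))
  data.table::setattr(out, "library_size", N)
  out[]
}

# EM log-likelihood for one gene's classes at given proportions
em_loglik <- function(A, ncl, alpha) {
  sum(ncl * log(as.vector(A %*% alpha)))
}

#' Upper-quartile normalization of a count matrix
#'
#' Scales each column (breed/library) by the 75th percentile of its
#' nonzero gene counts (linear interpolation between order statistics,
#' rank `1 + 0.75 (n - 1)`), then multiplies by the geometric mean of all
#' scale factors so the output stays on a count-like scale.
#'
#' @param mat numeric matrix, genes x breeds.
#' @return list with `normalized` matrix and `scale_factors`.
#' @export
upper_quartile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  sf <- apply(mat, 2L, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) stop("all-zero column in count matrix")
    as.numeric(stats::quantile(nz, 0.75, type = 7, names = FALSE))
  })
  gm <- exp(mean(log(sf)))
  normalized <- sweep(mat, 2L, sf, "/") * gm
  list(normalized = normalized, scale_factors = sf)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values (monotone minimum of `m * p_(j) / j` over
#' `j >= i` on sorted p-values, capped at 1, original order restored).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Poisson likelihood-ratio test of differential expression
#'
#' Two-sided test of equal Poisson rates for one gene's fragment counts in
#' two libraries with sizes `na`, `nb` as offsets.  The fold change is
#' `log2((countB/nb) / (countA/na))`; when either count is zero a
#' 0.5-fragment pseudocount enters the fold change (display only, the test
#' uses raw counts).  Vectorized over genes; q-values come from [bh_fdr()]
#' across the supplied set, and `significant` requires both
#' `|log2FC| >= lfc_min` and `q < alpha`.
#'
#' @param count_a,count_b integer vectors of fragment counts.
#' @param na,nb library sizes (total mapped fragments).
#' @param lfc_min minimum absolute log2 fold change (default 1, i.e.
#'   2-fold).
#' @param alpha FDR threshold (default 0.05).
#' @param genes optional gene ids.
#' @return data.frame: gene, log2fc, p, q, significant.
#' @export
de_test <- function(count_a, count_b, na, nb, lfc_min = 1, alpha = 0.05,
                    genes = NULL) {
  stopifnot(all(count_a >= 0), all(count_b >= 0), na > 0, nb > 0)
  m <- length(count_a)
  lam <- (count_a + count_b) / (na + nb)
  ll0 <- count_a * log(ifelse(lam > 0, lam * na, 1)) - lam * na +
    count_b * log(ifelse(lam > 0, lam * nb, 1)) - lam * nb
  la <- count_a / na; lb <- count_b / nb
  ll1 <- ifelse(count_a > 0, count_a * log(la * na), 0) - la * na +
    ifelse(count_b > 0, count_b * log(lb * nb), 0) - lb * nb
  stat <- pmax(2 * (ll1 - ll0), 0)
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  both_zero <- count_a == 0 & count_b == 0
  p[both_zero] <- 1
  ca <- ifelse(count_a == 0 | count_b == 0, count_a + 0.5, count_a)
  cb <- ifelse(count_a == 0 | count_b == 0, count_b + 0.5, count_b)
  log2fc <- log2((cb / nb) / (ca / na))
  log2fc[both_zero] <- 0
  q <- bh_fdr(p)
  data.frame(gene = if (is.null(genes)) seq_len(m) else genes,
             log2fc = log2fc, p = p, q = q,
             significant = abs(log2fc) >= lfc_min & q < alpha,
             stringsAsFactors = FALSE)
}

#' Detected and breed-specific genes from abundance
#'
#' A gene is detected in a breed when its FPKM exceeds
#' `detect_threshold`; it is breed-specific when detected in exactly one
#' breed.
#'
#' @param fpkm numeric matrix, genes x breeds (gene FPKM).
#' @param detect_threshold FPKM detection threshold (default 0: any
#'   evidence counts as detected).
#' @return list with per-breed `detected` and `specific` gene-id sets.
#' @export
detect_breed_specific <- function(fpkm, detect_threshold = 0) {
  fpkm <- as.matrix(fpkm)
  det <- fpkm > detect_threshold
  n_det <- rowSums(det)
  list(detected = apply(det, 2L, function(z) rownames(fpkm)[z],
                        simplify = FALSE),
       specific = lapply(colnames(fpkm), function(b)
         rownames(fpkm)[det[, b] & n_det == 1L]) |>
         stats::setNames(colnames(fpkm)))
}
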