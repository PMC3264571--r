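# Paired-end fragment simulation over breed haplotypes.

# isoform-usage profiles: list[[breed]][[gene]] = named probability vector
usage_profiles <- function(config, annotation) {
  two_iso <- attr(annotation, "two_isoform_genes")
  tx_by_gene <- split(annotation$transcripts$transcript_id,
                      annotation$transcripts$gene_id)
  if (is.null(two_iso))
    two_iso <- names(tx_by_gene)[lengths(tx_by_gene) == length(config$usage_base)]
  shifted <- if (config$n_usage_shift > 0)
    sort(two_iso)[seq_len(min(config$n_usage_shift, length(two_iso)))] else character(0)
  shift_breed <- config$breeds[config$n_breeds]
  out <- list()
  for (b in config$breeds) {
    prof <- list()
    for (g in names(tx_by_gene)) {
      txs <- sort(tx_by_gene[[g]])
      u <- if (length(txs) == 1L) 1
      else if (g %in% shifted && b == shift_breed &&
               length(txs) == length(config$usage_shift)) config$usage_shift
      else if (length(txs) == length(config$usage_base)) config$usage_base
      else rep(1 / length(txs), length(txs))
      prof[[g]] <- stats::setNames(u, txs)
    }
    out[[b]] <- prof
  }
  out
}

expr_matrix <- function(config, annotation) {
  genes <- sort(unique(annotation$transcripts$gene_id))
  if (is.null(config$expr_profile)) {
    m <- matrix(1, nrow = length(genes), ncol = config$n_breeds)
  } else {
    m <- config$expr_profile
    if (nrow(m) != length(genes))
      stop("configuration error: expr_profile rows must match gene count")
  }
  dimnames(m) <- list(genes, config$breeds)
  m
}

# compress a sorted vector of 0-based genomic positions into [start,end) blocks
pos_to_blocks <- function(gpos) {
  br <- c(0L, which(diff(gpos) > 1L), length(gpos))
  t(vapply(seq_len(length(br) - 1L), function(i) {
    c(gpos[br[i] + 1L], gpos[br[i + 1L]] + 1L)
  }, integer(2)))
}

blocks_to_cigar <- function(blocks) {
  n <- nrow(blocks)
  parts <- character(0)
  for (i in seq_len(n)) {
    parts <- c(parts, paste0(blocks[i, 2] - blocks[i, 1], "M"))
    if (i < n) parts <- c(parts, paste0(blocks[i + 1, 1] - blocks[i, 2], "N"))
  }
  paste(parts, collapse = "")
}

#' Simulate aligned paired-end fragments per breed
#'
#' Samples ~`frag_len`-bp fragments from transcript sequences according to
#' each breed's isoform usage and per-gene expression multipliers, injects
#' within-breed minor alleles and sequencing errors, and writes one SAM
#' file per breed with spliced (M/N) CIGARs, proper-pair flags, quality
#' strings, and `NH:i:1` tags.  Two placement modes:
#'
#' * `"random"`: fragment counts are Poisson with mean
#'   `depth * expr * usage * L / frag_len`, starts uniform; minor alleles
#'   are Bernoulli(`minor_frac`) per fragment.
#' * `"tiling"`: deterministic fragment starts at every multiple of
#'   `stride` (clipped to the transcript), giving exactly
#'   `frag_len / stride` coverage at every transcribed base; minor alleles
#'   are assigned by even spacing over the fragments covering the site, so
#'   the realised minor fraction is `round(n * minor_frac) / n`.
#'
#' Error modes: `"lowqual"` gives every erroneous base quality `qual_low`
#' (so a Q20 filter removes all errors); `"realistic"` draws base
#' qualities independently of error status.
#'
#' Deterministic (byte-identical SAM output) under a fixed config seed.
#'
#' @param spiked result of [spike_variants()] (haplotypes + truth), or a
#'   list with `haplotypes` only.
#' @param annotation a [tx_annotation()].
#' @param config a [sim_config()].
#' @param dir output directory for `<breed>.sam` files.
#' @param mode fragment placement mode.
#' @param error_mode error-quality coupling mode.
#' @param stride tiling stride (default `max(1, round(frag_len / target))`
#'   per transcript, where `target` is its coverage target).
#' @return list with `sam` (named vector of file paths), `fragment_truth`
#'   (data.frame breed/gene/transcript/n_fragments) and `library`
#'   (data.frame breed/total/mapped/unique fragment counts).
#' @export
simulate_fragments <- function(spiked, annotation, config, dir,
                               mode = c("random", "tiling"),
                               error_mode = c("lowqual", "realistic"),
                               stride = NULL) {
  mode <- match.arg(mode)
  error_mode <- match.arg(error_mode)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 2L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  haplotypes <- spiked$haplotypes
  truth <- spiked$truth
  if (!all(config$breeds %in% names(haplotypes)))
    stop("configuration error: breed without haplotype/usage profile")
  usage <- usage_profiles(config, annotation)
  expr <- expr_matrix(config, annotation)

  F <- config$frag_len; R <- config$read_len
  qh <- config$qual_high; ql <- config$qual_low

  tx_tab <- annotation$transcripts[order(annotation$transcripts$transcript_id), ]
  posmaps <- lapply(tx_tab$transcript_id, function(t) tx_posmap(annotation, t))
  names(posmaps) <- tx_tab$transcript_id

  sam_paths <- character(0)
  ft_rows <- list()
  lib_rows <- list()

  for (b in config$breeds) {
    hap <- haplotypes[[b]]
    hapch <- lapply(hap, function(s) strsplit(s, "", fixed = TRUE)[[1]])
    snps <- truth[truth$kind == "snp_within" & truth$breed == b, , drop = FALSE]
    lines <- character(0)
    contigs <- names(hap)
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", contigs,
                        vapply(hap, nchar, integer(1))))
    n_frag_total <- 0L

    for (ti in seq_len(nrow(tx_tab))) {
      t <- tx_tab$transcript_id[ti]
      g <- tx_tab$gene_id[ti]
      contig <- tx_tab$contig[ti]
      pm <- posmaps[[t]]
      L <- length(pm)
      u <- usage[[b]][[g]][[t]]
      target <- config$depth * expr[g, b] * u
      if (target <= 0) next

      if (mode == "tiling") {
        S <- if (is.null(stride)) max(1L, as.integer(round(F / target))) else as.integer(stride)
        kmin <- floor(-F / S) + 1L
        kmax <- ceiling(L / S) - 1L
        if (kmax < kmin) next
        st <- S * (kmin:kmax)
        fs <- pmax(0L, st); fe <- pmin(L, st + F)
        keep <- fs < fe
        fs <- fs[keep]; fe <- fe[keep]
      } else {
        n <- stats::rpois(1L, target * L / F)
        if (n == 0L) next
        if (L <= F) {
          fs <- rep(0L, n); fe <- rep(L, n)
        } else {
          fs <- sort(sample.int(L - F + 1L, n, replace = TRUE) - 1L)
          fe <- fs + F
        }
      }
      n_frag <- length(fs)
      if (!n_frag) next

      # within-breed minor-allele carriers, per SNP on this transcript
      frag_subs <- vector("list", n_frag)
      if (nrow(snps)) {
        tx_hit <- match(snps$pos, pm)
        for (si in which(!is.na(tx_hit) & snps$contig == contig)) {
          ts <- tx_hit[si] - 1L  # 0-based transcript coordinate
          cov <- which(fs <= ts & ts < fe)
          if (!length(cov)) next
          mf <- snps$minor_frac[si]
          carriers <- if (mode == "tiling") {
            ii <- seq_along(cov)
            cov[floor(ii * mf) > floor((ii - 1L) * mf)]
          } else {
            cov[stats::runif(length(cov)) < mf]
          }
          for (f in carriers)
            frag_subs[[f]] <- rbind(frag_subs[[f]],
                                    c(snps$pos[si], match(snps$alt[si], BASES)))
        }
      }

      chv <- hapch[[contig]]
      for (f in seq_len(n_frag)) {
        w <- fe[f] - fs[f]
        rlen <- min(R, w)
        ivs <- list(c(fs[f], fs[f] + rlen), c(fe[f] - rlen, fe[f]))
        qname <- sprintf("%s:%s:%06d", b, t, f)
        recs <- vector("list", 2L)
        starts <- integer(2L)
        for (ri in 1:2) {
          gpos <- sort(pm[(ivs[[ri]][1] + 1L):ivs[[ri]][2]])
          blocks <- pos_to_blocks(gpos)
          chars <- chv[gpos + 1L]
          subs <- frag_subs[[f]]
          if (!is.null(subs)) {
            hit <- match(subs[, 1], gpos)
            ok <- !is.na(hit)
            chars[hit[ok]] <- BASES[subs[ok, 2]]
          }
          nch <- length(chars)
          qual <- rep(qh, nch)
          if (config$error_rate > 0) {
            err <- which(stats::runif(nch) < config$error_rate)
            for (e in err)
              chars[e] <- sample(setdiff(BASES, chars[e]), 1L)
            if (error_mode == "lowqual") qual[err] <- ql
          }
          if (error_mode == "realistic")
            qual <- sample(c(qh, ql), nch, replace = TRUE, prob = c(0.85, 0.15))
          starts[ri] <- blocks[1, 1]
          recs[[ri]] <- list(blocks = blocks,
                             seq = paste(chars, collapse = ""),
                             qual = intToUtf8(qual + 33L))
        }
        ord <- order(starts)
        left <- recs[[ord[1]]]; right <- recs[[ord[2]]]
        span <- max(right$blocks[, 2]) - left$blocks[1, 1]
        lines <- c(lines,
          sprintf("%s\t99\t%s\t%d\t50\t%s\t=\t%d\t%d\t%s\t%s\tNH:i:1",
                  qname, contig, left$blocks[1, 1] + 1L,
                  blocks_to_cigar(left$blocks), right$blocks[1, 1] + 1L,
                  span, left$seq, left$qual),
          sprintf("%s\t147\t%s\t%d\t50\t%s\t=\t%d\t%d\t%s\t%s\tNH:i:1",
                  qname, contig, right$blocks[1, 1] + 1L,
                  blocks_to_cigar(right$blocks), left$blocks[1, 1] + 1L,
                  -span, right$seq, right$qual))
      }
      ft_rows[[length(ft_rows) + 1L]] <-
        data.frame(breed = b, gene = g, transcript = t,
                   n_fragments = n_frag, stringsAsFactors = FALSE)
      n_frag_total <- n_frag_total + n_frag
    }

    path <- file.path(dir, paste0(b, ".sam"))
    writeLines(c(header, lines), path)
    sam_paths[b] <- path
    lib_rows[[length(lib_rows) + 1L]] <-
      data.frame(breed = b, total = n_frag_total, mapped = n_frag_total,
                 unique = n_frag_total, stringsAsFactors = FALSE)
  }

  list(sam = sam_paths,
       fragment_truth = do.call(rbind, c(ft_rows, list(NULL))),
       library = do.call(rbind, lib_rows))
}
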