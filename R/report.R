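#' Round half up at a given precision
#'
#' Decimal rounding with ties away from zero (the convention of printed
#' summary tables), unlike base R's banker's rounding.
#'
#' @param x numeric vector (non-negative).
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

#' Alignment summary percentages
#'
#' Percent of fragments mapped and percent of mapped fragments that are
#' uniquely mapped, rounded half-up to one decimal.
#'
#' @param total,mapped,unique fragment counts with
#'   `0 <= unique <= mapped <= total` and `total > 0`.
#' @return list with `percent_mapped` and `percent_unique`.
#' @export
alignment_summary <- function(total, mapped, unique) {
  if (any(total <= 0)) stop("total fragment count must be positive")
  stopifnot(all(unique <= mapped), all(mapped <= total), all(unique >= 0))
  list(percent_mapped = round_half_up(100 * mapped / total, 1L),
       percent_unique = round_half_up(100 * unique / mapped, 1L))
}

#' Divergence percentage
#'
#' `100 * n_diff / n_denominator` rounded half-up to `decimals` places.
#'
#' @param n_diff,n_denominator base counts, `0 <= n_diff <= n_denominator`,
#'   `n_denominator > 0`.
#' @param decimals decimal places (default 3).
#' @return the percentage.
#' @export
divergence_summary <- function(n_diff, n_denominator, decimals = 3L) {
  if (any(n_denominator <= 0)) stop("denominator must be positive")
  stopifnot(all(n_diff >= 0), all(n_diff <= n_denominator))
  round_half_up(100 * n_diff / n_denominator, decimals)
}

sam_library_stats <- function(sam_paths) {
  rows <- lapply(names(sam_paths), function(b) {
    rec <- parse_sam_records(sam_paths[[b]])$records
    per <- rec[, .(mapped = any(bitwAnd(flag, 0x4L) == 0L),
                   uniq = any(bitwAnd(flag, 0x4L) == 0L &
                                (is.na(nh) | nh == 1L))), by = qname]
    data.frame(breed = b, total = nrow(per), mapped = sum(per$mapped),
               unique = sum(per$uniq), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full comparison pipeline
#'
#' Executes pileup, site calling, between-breed divergence with effect
#' annotation, abundance estimation with upper-quartile normalized
#' fold-change DE calls, and single-TSS differential-splicing testing, in
#' order, writing every stage's tables under `outdir` plus a
#' machine-readable run summary and a log.  With fewer than two breeds the
#' comparison stages are skipped with a notice.  Rerunning with an
#' identical configuration and seed reproduces identical outputs.
#'
#' @param config either a [sim_config()] (the synthetic cohort is
#'   generated under `outdir/sim`) or a list with elements `sam` (named
#'   vector of per-breed SAM paths), `fasta`, `gtf`.
#' @param outdir output directory.
#' @param thresholds a [calling_thresholds()].
#' @param detect_threshold FPKM detection threshold for breed-specific
#'   calls.
#' @param lfc_min,alpha DE thresholds (default 2-fold, FDR 0.05).
#' @param n_boot bootstrap replicates for the splicing test.
#' @param splice_seed RNG seed of the splicing bootstrap.
#' @param sim_mode,sim_error_mode fragment-simulation modes when `config`
#'   is a `sim_config`.
#' @return an object of class `breedtx_run` (invisibly): the run summary.
#' @export
run_pipeline <- function(config, outdir,
                         thresholds = calling_thresholds(),
                         detect_threshold = 0, lfc_min = 1, alpha = 0.05,
                         n_boot = 1000L, splice_seed = 1L,
                         sim_mode = "random", sim_error_mode = "lowqual") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  log_lines <- c(sprintf("breedtx run, thresholds: min_coverage=%d minor_frac=%g min_qual=%d top2_frac=%g",
                         thresholds$min_coverage, thresholds$minor_frac,
                         thresholds$min_qual, thresholds$top2_frac))
  emit <- function(path) { manifest <<- c(manifest, path); path }
  fail <- function(stage, e) {
    writeLines(manifest, file.path(outdir, "partial_manifest.txt"))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }

  # ---- inputs ----
  st <- "inputs"
  res <- tryCatch({
    if (inherits(config, "sim_config")) {
      simdir <- file.path(outdir, "sim")
      gen <- simulate_genome_annotation(config)
      spiked <- spike_variants(gen$reference, gen$annotation, config)
      frags <- simulate_fragments(spiked, gen$annotation, config, simdir,
                                  mode = sim_mode,
                                  error_mode = sim_error_mode)
      write_fasta(gen$reference, emit(file.path(simdir, "reference.fa")))
      write_gtf(gen$annotation, emit(file.path(simdir, "annotation.gtf")))
      data.table::fwrite(spiked$truth,
                         emit(file.path(simdir, "variant_truth.tsv")),
                         sep = "\t")
      log_lines <- c(log_lines, sprintf("simulated cohort seed=%d", config$seed))
      list(reference = gen$reference, annotation = gen$annotation,
           sam = frags$sam)
    } else {
      list(reference = read_fasta(config$fasta),
           annotation = read_gtf(config$gtf),
           sam = unlist(config$sam))
    }
  }, error = function(e) fail(st, e))
  reference <- res$reference; annotation <- res$annotation; sam <- res$sam
  breeds <- names(sam)

  # ---- alignment summary ----
  lib <- tryCatch(sam_library_stats(sam), error = function(e) fail("alignment_summary", e))
  als <- alignment_summary(lib$total, lib$mapped, lib$unique)
  lib$percent_mapped <- als$percent_mapped
  lib$percent_unique <- als$percent_unique
  utils::write.table(lib, emit(file.path(outdir, "library_stats.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # ---- pileup + calling ----
  st <- "pileup_calling"
  calls_res <- tryCatch({
    counts <- build_pileup(sam, thresholds)
    ca <- call_all(counts, thresholds)
    write_site_calls(ca$calls, emit(file.path(outdir, "site_calls.tsv")))
    write_polymorphic_vcf(ca$calls,
                          emit(file.path(outdir, "polymorphic.vcf")),
                          contigs = annotation$contigs)
    utils::write.table(ca$summary,
                       emit(file.path(outdir, "snp_summary.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    list(counts = counts, calls = ca$calls, summary = ca$summary,
         n_skipped = attr(counts, "n_skipped"))
  }, error = function(e) fail(st, e))

  # ---- divergence ----
  st <- "divergence"
  div <- NULL
  if (length(breeds) >= 2L) {
    div <- tryCatch({
      cbd <- cross_breed_differences(calls_res$calls)
      ann_d <- annotate_effect(cbd$differences, annotation, reference)
      write_differences(ann_d, emit(file.path(outdir, "differences.tsv")))
      pc <- cbd$pair_counts
      pc$pct <- divergence_summary(pc$n, max(cbd$n_determinable, 1L), 3L)
      utils::write.table(pc, emit(file.path(outdir, "pair_counts.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      cov_genes <- genes_with_cds_coverage(
        annotation, calls_res$counts[breed == breeds[1]])
      writeLines(cov_genes, emit(file.path(outdir, "genes_cds_covered.tsv")))
      list(differences = ann_d, pair_counts = pc,
           n_determinable = cbd$n_determinable, cds_covered = cov_genes)
    }, error = function(e) fail(st, e))
  } else {
    log_lines <- c(log_lines, "divergence stage skipped: fewer than two breeds")
  }

  # ---- expression ----
  st <- "expression"
  expr <- tryCatch({
    ab_list <- list()
    for (b in breeds) {
      cc <- count_compatible_fragments(sam[[b]], annotation)
      ab_list[[b]] <- em_isoform_abundance(cc, annotation,
                                           library_size = lib$total[lib$breed == b])
    }
    genes <- sort(unique(annotation$transcripts$gene_id))
    fpkm <- sapply(breeds, function(b) {
      gf <- attr(ab_list[[b]], "gene_fpkm")
      gf$fpkm[match(genes, gf$gene)]
    })
    cnt <- sapply(breeds, function(b) {
      gf <- attr(ab_list[[b]], "gene_fpkm")
      gf$count[match(genes, gf$gene)]
    })
    rownames(fpkm) <- rownames(cnt) <- genes
    uq <- upper_quartile_normalize(fpkm + 0)  # scale on FPKM
    iso <- data.table::rbindlist(
      lapply(breeds, function(b) data.table::copy(ab_list[[b]])[, breed := b]))
    data.table::fwrite(iso, emit(file.path(outdir, "abundance.tsv")), sep = "\t")
    utils::write.table(
      data.frame(breed = breeds, scale_factor = uq$scale_factors),
      emit(file.path(outdir, "scale_factors.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
    de <- list()
    if (length(breeds) >= 2L) {
      prs <- utils::combn(breeds, 2L)
      for (k in seq_len(ncol(prs))) {
        a <- prs[1, k]; b2 <- prs[2, k]
        d <- de_test(round(cnt[, a]), round(cnt[, b2]),
                     lib$total[lib$breed == a], lib$total[lib$breed == b2],
                     lfc_min = lfc_min, alpha = alpha, genes = genes)
        de[[paste0(a, "|", b2)]] <- d
        utils::write.table(
          d, emit(file.path(outdir, sprintf("de_%s_vs_%s.tsv", a, b2))),
          sep = "\t", row.names = FALSE, quote = FALSE)
      }
    }
    spec <- detect_breed_specific(fpkm, detect_threshold)
    list(fpkm = fpkm, counts = cnt, de = de, specific = spec,
         abundance = ab_list)
  }, error = function(e) fail(st, e))

  # ---- splicing ----
  st <- "splicing"
  spl <- NULL
  if (length(breeds) >= 2L) {
    spl <- tryCatch({
      stg <- single_tss_multi_isoform(annotation)
      ev <- classify_events(annotation, stg$genes)
      write_events(ev, annotation,
                   path_tsv = emit(file.path(outdir, "splice_events.tsv")),
                   path_bed = emit(file.path(outdir, "splice_events.bed")))
      tests <- list()
      prs <- utils::combn(breeds, 2L)
      for (k in seq_len(ncol(prs))) {
        a <- prs[1, k]; b2 <- prs[2, k]
        cl <- lapply(stg$genes, function(g) {
          xa <- expr$abundance[[a]][gene == g]
          xb <- expr$abundance[[b2]][gene == g]
          rbind(xa$count[match(sort(xa$isoform), xa$isoform)],
                xb$count[match(sort(xb$isoform), xb$isoform)])
        })
        names(cl) <- stg$genes
        r <- diff_splicing_screen(cl, n_boot = n_boot, seed = splice_seed)
        tests[[paste0(a, "|", b2)]] <- r
        utils::write.table(
          r, emit(file.path(outdir, sprintf("splicing_%s_vs_%s.tsv", a, b2))),
          sep = "\t", row.names = FALSE, quote = FALSE)
      }
      list(genes = stg$genes, events = ev, tests = tests)
    }, error = function(e) fail(st, e))
  } else {
    log_lines <- c(log_lines, "splicing stage skipped: fewer than two breeds")
  }

  # ---- summary ----
  summary <- structure(list(
    breeds = breeds, library = lib, snp_summary = calls_res$summary,
    n_skipped_records = calls_res$n_skipped,
    n_determinable = if (!is.null(div)) div$n_determinable else NA_integer_,
    pair_counts = if (!is.null(div)) div$pair_counts else NULL,
    n_differences = if (!is.null(div)) nrow(div$differences) else NA_integer_,
    n_de_significant = if (length(expr$de))
      vapply(expr$de, function(d) sum(d$significant), integer(1)) else NULL,
    n_breed_specific = vapply(expr$specific$specific, length, integer(1)),
    n_splice_events = if (!is.null(spl)) nrow(spl$events) else NA_integer_,
    n_single_tss_genes = if (!is.null(spl)) length(spl$genes) else NA_integer_,
    outdir = outdir), class = "breedtx_run")
  jsonlite::write_json(summary[setdiff(names(summary), "outdir")],
                       emit(file.path(outdir, "run_summary.json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(c(log_lines,
               sprintf("skipped malformed records: %s",
                       paste(calls_res$n_skipped, collapse = ","))),
             emit(file.path(outdir, "run.log")))
  writeLines(manifest, file.path(outdir, "manifest.txt"))
  invisible(summary)
}

#' @export
print.breedtx_run <- function(x, ...) {
  cat("breedtx pipeline run:", paste(x$breeds, collapse = ", "), "\n")
  cat("library stats:\n"); print(x$library)
  cat("determinable bases (monomorphic in all breeds):", x$n_determinable, "\n")
  if (!is.null(x$pair_counts)) {
    cat("between-breed differences:\n"); print(x$pair_counts)
  }
  if (!is.null(x$n_de_significant)) {
    cat("significant DE genes per pair:\n"); print(x$n_de_significant)
  }
  cat("breed-specific genes:", paste(names(x$n_breed_specific),
                                     x$n_breed_specific, collapse = "; "), "\n")
  if (!is.na(x$n_splice_events))
    cat("splicing:", x$n_single_tss_genes, "single-TSS genes,",
        x$n_splice_events, "events\n")
  invisible(x)
}
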