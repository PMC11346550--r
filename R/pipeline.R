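#' Pipeline run configuration
#'
#' Either a \code{sim} configuration (the self-contained synthetic study) or
#' a \code{paths} list pointing at real inputs (annotation GTF, genome FASTA,
#' sites BED6+2, circ/mRNA/nascent count TSVs, library-size TSV). All module
#' configurations travel with the run and are serialized alongside the
#' outputs for provenance.
#'
#' @param out_dir output directory (NULL keeps everything in memory).
#' @param seed integer seed; overrides the seed of \code{sim}.
#' @param sim a \code{sim_config}, or NULL when \code{paths} is given.
#' @param paths named list of input files (annotation, genome, sites,
#'   circ_counts, mrna_counts, nascent_gene_counts, nascent_circ_counts,
#'   library_sizes); all must exist.
#' @param de,nascent,peaks module configurations.
#' @param kmer_k k-mer length for the composition table.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(out_dir = NULL, seed = 1, sim = sim_config(seed = seed),
                       paths = NULL, de = de_config(),
                       nascent = nascent_de_config(),
                       peaks = peak_filter_config(), kmer_k = 6) {
  if (!is.null(paths)) {
    missing <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(missing) > 0) {
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
    }
    sim <- NULL
  } else if (is.null(sim)) {
    stop("either 'sim' or 'paths' must be supplied")
  } else {
    sim$seed <- seed
  }
  structure(list(out_dir = out_dir, seed = seed, sim = sim, paths = paths,
                 de = de, nascent = nascent, peaks = peaks, kmer_k = kmer_k),
            class = "run_config")
}

# internal: load all pipeline inputs from a paths list
load_inputs <- function(paths) {
  ls_df <- utils::read.delim(paths$library_sizes)
  list(
    ann = read_gtf(paths$annotation),
    genome = if (!is.null(paths$genome))
      Biostrings::readDNAStringSet(paths$genome) else NULL,
    sites = read_sites(paths$sites),
    circ_counts = read_circ_table(paths$circ_counts),
    mrna_counts = utils::read.delim(paths$mrna_counts),
    nascent_gene_counts = utils::read.delim(paths$nascent_gene_counts),
    nascent_circ_counts = read_circ_table(paths$nascent_circ_counts),
    library_sizes = stats::setNames(ls_df$steady, ls_df$sample),
    nascent_library_sizes = stats::setNames(ls_df$nascent, ls_df$sample)
  )
}

# internal: per-gene sums of a circ-level vector
sum_by_gene <- function(x, gene_id, genes) {
  out <- stats::setNames(rep(0, length(genes)), genes)
  if (length(x) > 0) {
    agg <- tapply(x, gene_id, sum)
    out[names(agg)] <- agg
  }
  out
}

#' Run the full analysis pipeline
#'
#' Executes (optionally) simulate, then quantify, nascent, binding and ratio
#' stages, collects every stage's tables and test statistics into one report
#' and, when \code{out_dir} is set, writes the TSVs plus a JSON summary and
#' the serialized configuration.
#'
#' @param config a \code{run_config}.
#' @return the report, a list of class \code{circ_report}, invisibly when
#'   written to disk.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  inp <- if (!is.null(config$paths)) {
    load_inputs(config$paths)
  } else {
    sim <- simulate_study(config$sim)
    list(ann = sim$ann, genome = sim$genome, sites = sim$sites,
         circ_counts = sim$circ_counts, mrna_counts = sim$mrna_counts,
         nascent_gene_counts = sim$nascent_gene_counts,
         nascent_circ_counts = sim$nascent_circ_counts,
         library_sizes = sim$library_sizes,
         nascent_library_sizes = sim$nascent_library_sizes,
         truth = sim$truth_genes)
  }
  report <- list(config = config)

  ## --- quantify: steady-state circRNA fold changes -----------------------
  cm <- count_matrix(inp$circ_counts)
  rpm <- normalize_rpm(cm, inp$library_sizes)
  det <- overlap_sets(detected_set(cm, "WT", config$de$min_bsj_reads),
                      detected_set(cm, "KO", config$de$min_bsj_reads))
  de <- classify_de(rpm[det$shared, "WT"], rpm[det$shared, "KO"], config$de)
  report$detected <- lapply(det, length)
  report$de_results <- de
  report$de_summary <- summarize_de(de)
  report$cumfrac_wt <- cumulative_fraction(log2(de$norm_wt + config$de$pseudocount))
  report$cumfrac_ko <- cumulative_fraction(log2(de$norm_ko + config$de$pseudocount))
  # counts are discrete, so ties are expected; the approximate p is fine here
  report$ks_circ <- suppressWarnings(stats::ks.test(de$norm_ko, de$norm_wt))

  mm <- count_matrix(inp$mrna_counts, id_col = "gene_id")
  mrpm <- normalize_rpm(mm, inp$library_sizes)
  report$ks_mrna <- suppressWarnings(stats::ks.test(mrpm[, "KO"], mrpm[, "WT"]))

  ## --- nascent: per-gene circRNA fraction and nascent up-calls -----------
  ncm <- count_matrix(inp$nascent_circ_counts)
  ngm <- count_matrix(inp$nascent_gene_counts, id_col = "gene_id")
  genes <- rownames(ngm)
  fracs <- lapply(c(WT = "WT", KO = "KO"), function(s) {
    circ <- sum_by_gene(ncm[, s], inp$nascent_circ_counts$gene_id, genes)
    tot <- ngm[, s]
    # genes must show both linear splicing and backsplicing in the condition
    ok <- circ >= 1 & (tot - circ) >= 1
    f <- nascent_circ_fraction(circ[ok], tot[ok])
    stats::setNames(f, genes[ok])
  })
  report$nascent_fraction_test <- compare_fractions(fracs$WT, fracs$KO)
  nrpm <- normalize_rpm(ncm, inp$nascent_library_sizes)
  ndet <- overlap_sets(detected_set(ncm, "WT", 1), detected_set(ncm, "KO", 1))
  nfc <- (nrpm[ndet$shared, "KO"] + config$de$pseudocount) /
    (nrpm[ndet$shared, "WT"] + config$de$pseudocount)
  report$nascent_up <- classify_nascent_up(nfc, config$nascent)

  ## --- binding: filtering, annotation, flanking-intron enrichment --------
  hc <- filter_high_confidence(inp$sites, config$peaks)
  report$n_sites_high_confidence <- nrow(hc)
  annot <- annotate_features(hc, inp$ann)
  report$feature_distribution <- feature_distribution(annot, inp$ann)
  if (!is.null(inp$genome)) {
    report$composition <- nucleotide_composition(hc, inp$genome)
    report$kmers <- kmer_top(hc, inp$genome, k = config$kmer_k)
  }

  shared_circs <- inp$circ_counts[inp$circ_counts$circ_id %in% det$shared, ]
  classes <- classify_exons(inp$ann, shared_circs)
  up_ids <- de$circ_id[de$label == "up"]
  report$fi_profiles <- profile_flanking_introns(inp$ann, classes, hc, up_ids)
  report$fi_class_test <- compare_flanking_groups(report$fi_profiles, "class")
  circ_fi <- report$fi_profiles[report$fi_profiles$class == "circ_e", ]
  report$fi_group_test <- if (length(unique(circ_fi$group)) == 2) {
    compare_flanking_groups(circ_fi, "group")
  } else NULL

  nascent_shared <- inp$nascent_circ_counts[
    inp$nascent_circ_counts$circ_id %in% ndet$shared, ]
  nclasses <- classify_exons(inp$ann, nascent_shared)
  report$exonic_binding <- exonic_binding_fraction(inp$ann, nclasses, hc)

  nascent_wt_genes <- genes[ngm[, "WT"] >= 1]
  gwb <- genes_with_binding(inp$ann, hc)
  flags <- gwb$flags[names(gwb$flags) %in% nascent_wt_genes]
  report$genes_with_binding <- list(
    n_with = sum(flags), n_total = length(flags),
    pct = round(100 * mean(flags), 1))
  glen <- inp$ann$genes$length[match(names(gwb$flags), inp$ann$genes$gene_id)]
  coding <- inp$ann$genes$biotype[match(names(gwb$flags),
                                        inp$ann$genes$gene_id)] == "coding"
  report$gene_length_test <- gene_length_comparison(
    glen[coding & gwb$flags], glen[coding & !gwb$flags])

  ## --- ratio: per-gene circRNA:mRNA shift --------------------------------
  circ_genes <- unique(shared_circs$gene_id)
  circ_genes <- circ_genes[circ_genes %in% rownames(mrpm)]
  cw <- sum_by_gene(rpm[shared_circs$circ_id, "WT"], shared_circs$gene_id,
                    circ_genes)
  ck <- sum_by_gene(rpm[shared_circs$circ_id, "KO"], shared_circs$gene_id,
                    circ_genes)
  report$ratio_records <- ratio_records(circ_genes, cw, ck,
                                        mrpm[circ_genes, "WT"],
                                        mrpm[circ_genes, "KO"],
                                        config$de$pseudocount)
  report$ratio_label_counts <- table(factor(report$ratio_records$label,
                                            c("increased", "decreased",
                                              "unchanged")))
  if (!is.null(inp$truth)) report$truth <- inp$truth
  class(report) <- "circ_report"

  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_tsv(report$de_results, file.path(d, "de_results.tsv"))
    write_tsv(report$fi_profiles, file.path(d, "fi_profiles.tsv"))
    write_tsv(report$nascent_fraction_test$pairs,
              file.path(d, "nascent_fractions.tsv"))
    write_tsv(report$ratio_records, file.path(d, "ratio_records.tsv"))
    fd <- report$feature_distribution
    write_tsv(data.frame(feature = names(fd$proportions),
                         count = fd$counts,
                         proportion = fd$proportions),
              file.path(d, "feature_distribution.tsv"))
    if (!is.null(report$kmers)) write_tsv(report$kmers, file.path(d, "kmers.tsv"))
    jsonlite::write_json(summary_list(report), file.path(d, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(config[setdiff(names(config), "out_dir")],
                         file.path(d, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    return(invisible(report))
  }
  report
}

# internal: scalar summary of a report, JSON-friendly
summary_list <- function(report) {
  list(
    n_detected_shared = report$detected$shared,
    de = report$de_summary,
    ks_circ_p = report$ks_circ$p.value,
    ks_mrna_p = report$ks_mrna$p.value,
    nascent_fraction_p = report$nascent_fraction_test$p_value,
    nascent_fraction_mean_wt = report$nascent_fraction_test$mean_wt,
    nascent_fraction_mean_ko = report$nascent_fraction_test$mean_ko,
    n_nascent_up = sum(report$nascent_up == "up"),
    n_sites_high_confidence = report$n_sites_high_confidence,
    pct_coding_genes = report$feature_distribution$pct_coding_genes,
    pct_intronic_coding = report$feature_distribution$pct_intronic_coding,
    fi_class_p_binding = report$fi_class_test$p_binding,
    fi_group_p_length = if (!is.null(report$fi_group_test))
      report$fi_group_test$p_length else NA,
    exonic_binding_pct = report$exonic_binding$pct,
    genes_with_binding_pct = report$genes_with_binding$pct,
    gene_length_p = report$gene_length_test$p_value,
    ratio_labels = as.list(report$ratio_label_counts)
  )
}

#' @export
print.circ_report <- function(x, ...) {
  s <- x$de_summary
  cat("circ_report\n")
  cat(sprintf("  shared circRNAs: %d; DE: %d (up %d = %.1f%%, down %d = %.1f%%)\n",
              x$detected$shared, s$n_de, s$n_up, s$pct_up, s$n_down, s$pct_down))
  cat(sprintf("  KS circ WT vs KO: p = %.3g; KS mRNA: p = %.3g\n",
              x$ks_circ$p.value, x$ks_mrna$p.value))
  cat(sprintf("  nascent fraction WT %.4f vs KO %.4f (p = %.3g, n = %d)\n",
              x$nascent_fraction_test$mean_wt, x$nascent_fraction_test$mean_ko,
              x$nascent_fraction_test$p_value, x$nascent_fraction_test$n))
  cat(sprintf("  high-confidence sites: %d (%.1f%% intronic on coding genes)\n",
              x$n_sites_high_confidence,
              x$feature_distribution$pct_intronic_coding))
  cat(sprintf("  exonic binding: %d/%d (%.1f%%); genes with binding: %.1f%%\n",
              x$exonic_binding$n_with, x$exonic_binding$n_total,
              x$exonic_binding$pct, x$genes_with_binding$pct))
  cat("  ratio labels:",
      paste(names(x$ratio_label_counts), x$ratio_label_counts,
            collapse = ", "), "\n")
  invisible(x)
}

#' Render the report's descriptive figures
#'
#' Writes the MA plot, the WT/KO cumulative-fraction curves, the
#' genomic-feature bar chart and the flanking-intron length boxplots as PNG
#' files; every plotted number is also present in the report's tables. An
#' empty DE table skips the MA plot with a warning.
#'
#' @param report a \code{circ_report}.
#' @param dir output directory.
#' @return character vector of files written, invisibly.
#' @export
plot_summaries <- function(report, dir) {
  stopifnot(inherits(report, "circ_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  png_dev <- function(f) grDevices::png(f, width = 900, height = 700, res = 120)

  de <- report$de_results
  if (nrow(de) == 0) {
    warning("empty DE table: MA plot skipped")
  } else {
    f <- file.path(dir, "ma_plot.png")
    png_dev(f)
    cols <- c(up = "firebrick", down = "steelblue", unchanged = "grey60")
    plot(de$mean_expr, de$log2fc, pch = 16, cex = 0.5, col = cols[de$label],
         xlab = "log2 mean RPM", ylab = "log2 fold change (KO/WT)",
         main = "Differential circRNA expression")
    graphics::abline(h = 0, lty = 2)
    grDevices::dev.off()
    written <- c(written, f)
  }

  f <- file.path(dir, "cumulative_fraction.png")
  png_dev(f)
  plot(report$cumfrac_wt$value, report$cumfrac_wt$fraction, type = "s",
       col = "grey30", xlab = "log2 circRNA RPM", ylab = "cumulative fraction",
       main = "circRNA levels", ylim = c(0, 1))
  graphics::lines(report$cumfrac_ko$value, report$cumfrac_ko$fraction,
                  type = "s", col = "firebrick")
  graphics::legend("bottomright", c("WT", "KO"),
                   col = c("grey30", "firebrick"), lty = 1)
  grDevices::dev.off()
  written <- c(written, f)

  f <- file.path(dir, "feature_distribution.png")
  png_dev(f)
  graphics::barplot(report$feature_distribution$proportions,
                    ylab = "proportion of binding-site annotations",
                    main = "Binding sites by genomic feature", las = 2)
  grDevices::dev.off()
  written <- c(written, f)

  if (nrow(report$fi_profiles) > 0) {
    f <- file.path(dir, "fi_length.png")
    png_dev(f)
    bound <- report$fi_profiles[report$fi_profiles$has_binding, ]
    graphics::boxplot(length ~ class, data = bound, log = "y",
                      ylab = "flanking-intron length (bp)",
                      main = "Flanking introns with binding")
    grDevices::dev.off()
    written <- c(written, f)
  }
  invisible(written)
}
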