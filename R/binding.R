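#' High-confidence peak filter configuration
#'
#' Both thresholds are strict, matching the usual "p < 0.05, reads > 5"
#' definition of a high-confidence crosslink site: a peak at exactly p = 0.05
#' or exactly 5 reads is excluded.
#'
#' @param max_p strict upper bound on the peak p-value.
#' @param min_reads strict lower bound on the peak read count.
#' @return list of class \code{peak_filter_config}.
#' @export
peak_filter_config <- function(max_p = 0.05, min_reads = 5) {
  stopifnot(max_p > 0, max_p <= 1, min_reads >= 0)
  structure(list(max_p = max_p, min_reads = min_reads),
            class = "peak_filter_config")
}

#' Filter binding sites to the high-confidence set
#' @param sites data.frame from \code{read_sites}.
#' @param config a \code{peak_filter_config}.
#' @return the subset with \code{p_value < max_p} and \code{reads > min_reads}.
#' @export
filter_high_confidence <- function(sites, config = peak_filter_config()) {
  if (is.null(sites$p_value) || anyNA(sites$p_value)) {
    stop("sites are missing p-values")
  }
  keep <- sites$p_value < config$max_p & sites$reads > config$min_reads
  sites[keep, , drop = FALSE]
}

# precedence used when a site touches several features of one gene
FEATURE_LEVELS <- c("CDS", "3'UTR", "5'UTR", "noncoding_exon", "intron",
                    "intergenic")

# internal: one row per genic feature interval (gene_id, feature, coords)
feature_table <- function(ann) {
  g <- ann$genes
  e <- ann$exons
  gi <- match(e$gene_id, g$gene_id)
  coding <- g$biotype[gi] == "coding" & !is.na(g$cds_start[gi])
  rows <- list()

  # noncoding genes (or coding genes without CDS): exons are noncoding_exon
  nc <- e[!coding, , drop = FALSE]
  if (nrow(nc) > 0) {
    rows$nc <- data.frame(gene_id = nc$gene_id, feature = "noncoding_exon",
                          chrom = nc$chrom, start = nc$start, end = nc$end)
  }

  ce <- e[coding, , drop = FALSE]
  if (nrow(ce) > 0) {
    cgi <- match(ce$gene_id, g$gene_id)
    cs <- g$cds_start[cgi]; cn <- g$cds_end[cgi]; strand <- g$strand[cgi]
    # CDS piece of each exon
    s1 <- pmax(ce$start, cs); e1 <- pmin(ce$end, cn)
    k <- e1 > s1
    if (any(k)) rows$cds <- data.frame(gene_id = ce$gene_id[k], feature = "CDS",
                                       chrom = ce$chrom[k], start = s1[k], end = e1[k])
    # exonic piece genomically left of the CDS: 5'UTR on "+", 3'UTR on "-"
    k <- ce$start < cs
    if (any(k)) rows$left <- data.frame(
      gene_id = ce$gene_id[k],
      feature = ifelse(strand[k] == "+", "5'UTR", "3'UTR"),
      chrom = ce$chrom[k], start = ce$start[k], end = pmin(ce$end[k], cs[k]))
    # exonic piece genomically right of the CDS
    k <- ce$end > cn
    if (any(k)) rows$right <- data.frame(
      gene_id = ce$gene_id[k],
      feature = ifelse(strand[k] == "+", "3'UTR", "5'UTR"),
      chrom = ce$chrom[k], start = pmax(ce$start[k], cn[k]), end = ce$end[k])
  }

  if (nrow(ann$introns) > 0) {
    rows$intr <- data.frame(gene_id = ann$introns$gene_id, feature = "intron",
                            chrom = ann$introns$chrom,
                            start = ann$introns$start, end = ann$introns$end)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate binding sites with genomic features
#'
#' Each site is assigned one feature per overlapped gene (>= 1 bp overlap) by
#' the precedence CDS > 3'UTR > 5'UTR > noncoding_exon > intron; sites
#' touching no gene are intergenic. A site overlapping two genes yields one
#' record per gene.
#'
#' @param sites data.frame of binding sites.
#' @param ann a \code{gene_annotation}.
#' @return data.frame with site_id, gene_id (NA for intergenic), feature.
#' @export
annotate_features <- function(sites, ann) {
  stopifnot(inherits(ann, "gene_annotation"))
  ft <- feature_table(ann)
  hits <- GenomicRanges::findOverlaps(as_granges0(sites), as_granges0(ft),
                                      minoverlap = 1L, ignore.strand = TRUE)
  si <- S4Vectors::queryHits(hits); fi <- S4Vectors::subjectHits(hits)
  rec <- data.frame(site_id = sites$site_id[si],
                    gene_id = ft$gene_id[fi],
                    feature = ft$feature[fi],
                    rank = match(ft$feature[fi], FEATURE_LEVELS))
  # best (lowest-rank) feature per site x gene
  key <- paste(rec$site_id, rec$gene_id)
  rec <- rec[order(key, rec$rank), , drop = FALSE]
  rec <- rec[!duplicated(paste(rec$site_id, rec$gene_id)), , drop = FALSE]
  genic <- unique(rec$site_id)
  inter <- sites$site_id[!sites$site_id %in% genic]
  out <- rbind(rec[, c("site_id", "gene_id", "feature")],
               if (length(inter) > 0)
                 data.frame(site_id = inter, gene_id = NA_character_,
                            feature = "intergenic"))
  rownames(out) <- NULL
  out
}

#' Feature distribution of annotated binding sites
#'
#' Proportions of annotation records per feature (summing to 1), plus the
#' fraction of distinct sites that touch a protein-coding gene and the number
#' of distinct coding genes bound.
#'
#' @param annotations data.frame from \code{annotate_features}.
#' @param ann the \code{gene_annotation} (for biotypes).
#' @return list with \code{proportions} (named, all features), \code{counts},
#'   \code{pct_coding_genes}, \code{n_coding_genes},
#'   \code{pct_intronic_coding} (intronic share among coding-gene records).
#' @export
feature_distribution <- function(annotations, ann) {
  if (nrow(annotations) == 0) stop("no annotated sites")
  counts <- table(factor(annotations$feature, levels = FEATURE_LEVELS))
  props <- counts / sum(counts)
  coding_genes <- ann$genes$gene_id[ann$genes$biotype == "coding"]
  on_coding <- annotations[!is.na(annotations$gene_id) &
                             annotations$gene_id %in% coding_genes, , drop = FALSE]
  n_sites <- length(unique(annotations$site_id))
  list(
    proportions = stats::setNames(as.numeric(props), names(props)),
    counts = stats::setNames(as.integer(counts), names(counts)),
    pct_coding_genes = round(100 * length(unique(on_coding$site_id)) / n_sites, 1),
    n_coding_genes = length(unique(on_coding$gene_id)),
    pct_intronic_coding = if (nrow(on_coding) > 0)
      round(100 * mean(on_coding$feature == "intron"), 1) else NA_real_
  )
}

# internal: strand-corrected site sequences as a DNAStringSet
site_sequences <- function(sites, genome) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  if (!all(sites$chrom %in% names(genome))) {
    stop("site chromosome(s) absent from genome: ",
         paste(setdiff(unique(sites$chrom), names(genome)), collapse = ", "))
  }
  lens <- Biostrings::width(genome)[match(sites$chrom, names(genome))]
  if (any(sites$start < 0 | sites$end > lens)) {
    stop("site interval out of chromosome bounds")
  }
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(sites)), function(i) {
    as.character(Biostrings::subseq(genome[[sites$chrom[i]]],
                                    start = sites$start[i] + 1L,
                                    end = sites$end[i]))
  }, character(1)))
  minus <- sites$strand == "-"
  if (any(minus)) seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  names(seqs) <- sites$site_id
  seqs
}

#' Nucleotide composition of binding-site sequences
#'
#' Frequencies of A, C, G, U over the strand-corrected (RNA-sense) site
#' sequences; minus-strand sites are reverse-complemented before counting and
#' T is reported as U. Frequencies sum to 1.
#'
#' @param sites data.frame of binding sites.
#' @param genome named \code{DNAStringSet} (one entry per chromosome).
#' @return named numeric vector (A, C, G, U).
#' @export
nucleotide_composition <- function(sites, genome) {
  seqs <- site_sequences(sites, genome)
  tot <- colSums(Biostrings::letterFrequency(seqs, c("A", "C", "G", "T")))
  freq <- tot / sum(tot)
  stats::setNames(as.numeric(freq), c("A", "C", "G", "U"))
}

#' Ranked k-mer table of binding-site sequences
#'
#' Counts all overlapping k-mers in the strand-corrected site sequences and
#' ranks them by count. Reported in RNA alphabet (U for T). Counts sum to
#' \code{sum(pmax(len - k + 1, 0))} over sites.
#'
#' @param sites data.frame of binding sites.
#' @param genome named \code{DNAStringSet}.
#' @param k k-mer length (>= 3).
#' @param top number of rows to return (Inf for all).
#' @return data.frame with kmer, count, freq, sorted by decreasing count
#'   (ties by k-mer).
#' @export
kmer_top <- function(sites, genome, k = 5, top = 20) {
  stopifnot(k >= 3)
  seqs <- site_sequences(sites, genome)
  counts <- colSums(Biostrings::oligonucleotideFrequency(seqs, width = k))
  counts <- counts[counts > 0]
  names(counts) <- chartr("T", "U", names(counts))
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  n <- min(length(counts), top)
  data.frame(kmer = names(counts)[seq_len(n)],
             count = as.integer(counts[seq_len(n)]),
             freq = as.numeric(counts[seq_len(n)] / sum(counts)))
}

#' Classify exons of circRNA-producing genes as circ-E or NE
#'
#' A backsplicing exon (circ-E) lies, in transcription order, between the
#' acceptor and donor exons of at least one detected circRNA of its gene; the
#' remaining exons of circRNA-producing genes are non-backsplicing exons
#' (NE). Genes without detected circRNAs contribute nothing. CircRNAs whose
#' junctions match no exon boundary of the representative transcript are
#' skipped with a warning.
#'
#' @param ann a \code{gene_annotation}.
#' @param circs data.frame with circ_id, gene_id, chrom, start, end (BSJ span,
#'   0-based half-open from acceptor-exon start to donor-exon end).
#' @return list with \code{exons} (gene_id, ordinal, start, end, class,
#'   circ_ids) and \code{circ_ranges} (circ_id, gene_id, acceptor_ordinal,
#'   donor_ordinal) for junction-matched circRNAs.
#' @export
classify_exons <- function(ann, circs) {
  stopifnot(inherits(ann, "gene_annotation"))
  ranges <- vector("list", nrow(circs))
  for (i in seq_len(nrow(circs))) {
    e <- ann$exons[ann$exons$gene_id == circs$gene_id[i], , drop = FALSE]
    a <- e[e$start == circs$start[i], , drop = FALSE]
    d <- e[e$end == circs$end[i], , drop = FALSE]
    if (nrow(e) == 0 || nrow(a) != 1 || nrow(d) != 1) {
      warning("circRNA ", circs$circ_id[i],
              ": junction matches no exon boundary; skipped")
      next
    }
    o <- sort(c(a$ordinal, d$ordinal))
    ranges[[i]] <- data.frame(circ_id = circs$circ_id[i],
                              gene_id = circs$gene_id[i],
                              acceptor_ordinal = o[1], donor_ordinal = o[2])
  }
  circ_ranges <- do.call(rbind, ranges)
  if (is.null(circ_ranges)) {
    return(list(exons = data.frame(gene_id = character(), ordinal = integer(),
                                   start = integer(), end = integer(),
                                   class = character(), circ_ids = character()),
                circ_ranges = data.frame(circ_id = character(),
                                         gene_id = character(),
                                         acceptor_ordinal = integer(),
                                         donor_ordinal = integer())))
  }
  out <- list()
  for (g in unique(circ_ranges$gene_id)) {
    e <- ann$exons[ann$exons$gene_id == g, , drop = FALSE]
    cr <- circ_ranges[circ_ranges$gene_id == g, , drop = FALSE]
    hit <- lapply(e$ordinal, function(o) {
      cr$circ_id[cr$acceptor_ordinal <= o & o <= cr$donor_ordinal]
    })
    out[[g]] <- data.frame(
      gene_id = g, ordinal = e$ordinal, start = e$start, end = e$end,
      class = ifelse(lengths(hit) > 0, "circ_e", "ne"),
      circ_ids = vapply(hit, paste, character(1), collapse = ",")
    )
  }
  exons <- do.call(rbind, out)
  rownames(exons) <- NULL
  list(exons = exons, circ_ranges = circ_ranges)
}

#' Flanking introns of an exon group
#'
#' For a contiguous group of exons (transcription-order ordinals), the
#' upstream flanking intron immediately precedes the group's first exon in
#' transcription direction and the downstream one immediately follows its
#' last exon; either is NULL at a transcript terminus. Genomic left/right is
#' derived from strand.
#'
#' @param ann a \code{gene_annotation}.
#' @param gene_id gene identifier.
#' @param ordinals transcription-order ordinals of the group's exons.
#' @return list with \code{upstream} and \code{downstream}, each a one-row
#'   intron data.frame or NULL.
#' @export
flanking_introns_of <- function(ann, gene_id, ordinals) {
  intr <- ann$introns[ann$introns$gene_id == gene_id, , drop = FALSE]
  a <- min(ordinals); d <- max(ordinals)
  pick <- function(ord) {
    r <- intr[intr$upstream_exon_ordinal == ord, , drop = FALSE]
    if (nrow(r) == 1) r else NULL
  }
  list(upstream = if (a >= 2) pick(a - 1L) else NULL,
       downstream = pick(d))
}

#' Profile flanking introns of circ-E groups and NE exons
#'
#' Collects every flanking intron (FI) of the circularized exon groups
#' (class circ-E) and of the remaining NE exons of the same genes, and
#' tallies per FI its length, the number of overlapping high-confidence
#' binding sites (>= 1 bp) and the binding intensity (summed site reads).
#' Each unique intron is profiled once: an intron flanking any circ-E group
#' is assigned to the circ-E class, otherwise to NE, so the two classes are
#' disjoint. The regulation group of an FI is "up" when any circRNA of its
#' gene (for circ-E, any circRNA it flanks) is labelled up.
#'
#' @param ann a \code{gene_annotation}.
#' @param classes result of \code{classify_exons}.
#' @param sites data.frame of (high-confidence) binding sites.
#' @param up_circs character vector of circ_ids labelled up (from
#'   \code{classify_de} or \code{classify_nascent_up}); may be NULL.
#' @return data.frame with gene_id, chrom, start, end, class, group, length,
#'   n_sites, intensity, has_binding.
#' @export
profile_flanking_introns <- function(ann, classes, sites, up_circs = NULL) {
  ex <- classes$exons
  cr <- classes$circ_ranges
  recs <- list()
  for (i in seq_len(nrow(cr))) {
    fi <- flanking_introns_of(ann, cr$gene_id[i],
                              c(cr$acceptor_ordinal[i], cr$donor_ordinal[i]))
    for (r in fi) {
      if (!is.null(r)) {
        recs[[length(recs) + 1L]] <- cbind(r, class = "circ_e",
                                           circ_id = cr$circ_id[i])
      }
    }
  }
  ne <- ex[ex$class == "ne", , drop = FALSE]
  for (i in seq_len(nrow(ne))) {
    fi <- flanking_introns_of(ann, ne$gene_id[i], ne$ordinal[i])
    for (r in fi) {
      if (!is.null(r)) {
        recs[[length(recs) + 1L]] <- cbind(r, class = "ne",
                                           circ_id = NA_character_)
      }
    }
  }
  if (length(recs) == 0) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), class = character(),
                      group = character(), length = integer(),
                      n_sites = integer(), intensity = integer(),
                      has_binding = logical()))
  }
  fi <- do.call(rbind, recs)
  # dedupe: one record per intron; circ-E assignment wins
  fi <- fi[order(fi$gene_id, fi$start, fi$class), , drop = FALSE]
  key <- paste(fi$gene_id, fi$start, fi$end)
  up_flag <- rep(FALSE, nrow(fi))
  if (!is.null(up_circs)) {
    gene_up <- unique(cr$gene_id[cr$circ_id %in% up_circs])
    up_flag <- ifelse(fi$class == "circ_e",
                      fi$circ_id %in% up_circs,
                      fi$gene_id %in% gene_up)
    # an intron may flank several circRNAs: up if any of them is up
    up_flag <- as.logical(tapply(up_flag, key, any)[key])
  }
  fi$group <- ifelse(up_flag, "up", "non-up")
  fi <- fi[!duplicated(key), , drop = FALSE]

  fi$length <- fi$end - fi$start
  hits <- GenomicRanges::findOverlaps(as_granges0(fi), as_granges0(sites),
                                      minoverlap = 1L, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  fi$n_sites <- as.integer(tabulate(qi, nbins = nrow(fi)))
  inten <- rep(0, nrow(fi))
  if (length(qi) > 0) {
    agg <- tapply(sites$reads[si], qi, sum)
    inten[as.integer(names(agg))] <- agg
  }
  fi$intensity <- as.integer(inten)
  fi$has_binding <- fi$n_sites > 0
  rownames(fi) <- NULL
  fi[, c("gene_id", "chrom", "start", "end", "class", "group", "length",
         "n_sites", "intensity", "has_binding")]
}

#' Compare flanking-intron profiles between two groups
#'
#' Chi-square tests (without continuity correction) on the proportion of FIs
#' with binding and on binned site counts (0 / 1 / >= 2), and two-tailed
#' Student's t-tests on FI length and binding intensity. Length and
#' intensity are compared among FIs with binding (\code{bound_only}), as the
#' per-FI intensity is only defined there.
#'
#' @param profiles data.frame from \code{profile_flanking_introns}.
#' @param by grouping column, "class" (circ-E vs NE) or "group" (up vs
#'   non-up).
#' @param bound_only restrict the length/intensity t-tests to FIs with
#'   binding (default TRUE).
#' @return list with per-test p-values, group means/proportions and sizes.
#' @export
compare_flanking_groups <- function(profiles, by = c("class", "group"),
                                    bound_only = TRUE) {
  by <- match.arg(by)
  grp <- factor(profiles[[by]])
  if (nlevels(grp) < 2) stop("need at least 2 non-empty groups in '", by, "'")
  tab <- table(grp, factor(profiles$has_binding, levels = c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0)) {
    stop("degenerate contingency table: empty group margin '",
         rownames(tab)[rowSums(tab) == 0][1], "'")
  }
  if (any(colSums(tab) == 0)) {
    stop("degenerate contingency table: zero margin for has_binding = ",
         colnames(tab)[colSums(tab) == 0][1])
  }
  chi_bind <- stats::chisq.test(tab, correct = FALSE)

  bins <- cut(profiles$n_sites, breaks = c(-0.5, 0.5, 1.5, Inf),
              labels = c("0", "1", "2+"))
  btab <- table(grp, bins)
  btab <- btab[, colSums(btab) > 0, drop = FALSE]
  chi_bins <- if (ncol(btab) >= 2) stats::chisq.test(btab, correct = FALSE)
              else NULL

  sub <- if (bound_only) profiles[profiles$has_binding, , drop = FALSE]
         else profiles
  sgrp <- factor(sub[[by]], levels = levels(grp))
  ttest_or_na <- function(v) {
    if (min(table(sgrp)) < 2) return(NULL)
    tryCatch(stats::t.test(v ~ sgrp, var.equal = TRUE),
             error = function(e) NULL)   # e.g. constant data
  }
  t_len <- ttest_or_na(sub$length)
  t_int <- ttest_or_na(sub$intensity)

  list(
    by = by,
    n = as.integer(table(grp)),
    groups = levels(grp),
    prop_bound = as.numeric(tab[, "TRUE"] / rowSums(tab)),
    p_binding = chi_bind$p.value,
    p_n_sites = if (!is.null(chi_bins)) chi_bins$p.value else NA_real_,
    p_length = if (!is.null(t_len)) t_len$p.value else NA_real_,
    p_intensity = if (!is.null(t_int)) t_int$p.value else NA_real_,
    mean_length = tapply(sub$length, sgrp, mean),
    mean_intensity = tapply(sub$intensity, sgrp, mean),
    mean_n_sites = tapply(profiles$n_sites, grp, mean)
  )
}

#' Fraction of circRNAs with binding in their composing exons
#'
#' A circRNA is flagged when any (high-confidence) binding site overlaps any
#' exon between its acceptor and donor exons.
#'
#' @param ann a \code{gene_annotation}.
#' @param classes result of \code{classify_exons}.
#' @param sites data.frame of binding sites.
#' @return list with n_with, n_total, fraction, pct (one decimal).
#' @export
exonic_binding_fraction <- function(ann, classes, sites) {
  cr <- classes$circ_ranges
  n_total <- nrow(cr)
  if (n_total == 0) return(list(n_with = 0L, n_total = 0L,
                                fraction = NA_real_, pct = NA_real_))
  sgr <- as_granges0(sites)
  flagged <- vapply(seq_len(n_total), function(i) {
    e <- ann$exons[ann$exons$gene_id == cr$gene_id[i] &
                     ann$exons$ordinal >= cr$acceptor_ordinal[i] &
                     ann$exons$ordinal <= cr$donor_ordinal[i], , drop = FALSE]
    length(GenomicRanges::findOverlaps(as_granges0(e), sgr, minoverlap = 1L,
                                       ignore.strand = TRUE)) > 0
  }, logical(1))
  n_with <- sum(flagged)
  list(n_with = as.integer(n_with), n_total = as.integer(n_total),
       fraction = n_with / n_total, pct = round(100 * n_with / n_total, 1))
}

#' Genes with at least one binding site
#'
#' Flags each gene whose span is overlapped (>= 1 bp) by any site and
#' reports the bound fraction.
#'
#' @param ann a \code{gene_annotation}.
#' @param sites data.frame of binding sites.
#' @param coding_only restrict to coding genes.
#' @return list with n_with, n_total, fraction, pct, and logical
#'   \code{flags} named by gene_id.
#' @export
genes_with_binding <- function(ann, sites, coding_only = FALSE) {
  g <- ann$genes
  if (coding_only) g <- g[g$biotype == "coding", , drop = FALSE]
  hits <- GenomicRanges::findOverlaps(as_granges0(g), as_granges0(sites),
                                      minoverlap = 1L, ignore.strand = TRUE)
  flags <- stats::setNames(seq_len(nrow(g)) %in% S4Vectors::queryHits(hits),
                           g$gene_id)
  list(n_with = as.integer(sum(flags)), n_total = as.integer(nrow(g)),
       fraction = mean(flags), pct = round(100 * mean(flags), 1),
       flags = flags)
}

#' Compare lengths of bound vs unbound genes
#'
#' Two-sided Wilcoxon rank-sum test on gene lengths, bound against unbound.
#'
#' @param lengths_bound,lengths_unbound numeric vectors of gene lengths (bp);
#'   each needs >= 3 genes.
#' @return list with p_value, median_bound, median_unbound, n_bound,
#'   n_unbound.
#' @export
gene_length_comparison <- function(lengths_bound, lengths_unbound) {
  if (length(lengths_bound) < 3 || length(lengths_unbound) < 3) {
    stop("each group needs at least 3 genes")
  }
  wt <- stats::wilcox.test(lengths_bound, lengths_unbound,
                           alternative = "two.sided", exact = FALSE)
  list(p_value = wt$p.value,
       median_bound = stats::median(lengths_bound),
       median_unbound = stats::median(lengths_unbound),
       n_bound = length(lengths_bound),
       n_unbound = length(lengths_unbound))
}
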