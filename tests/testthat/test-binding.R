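test_that("high-confidence filter applies both thresholds strictly", {
  sites <- make_sites("chr1", c(0, 10, 20, 30), c(5, 15, 25, 35),
                      reads = c(10, 5, 6, 100),
                      p_value = c(0.05, 0.01, 0.01, 0.049))
  kept <- filter_high_confidence(sites)
  # p = 0.05 excluded, reads = 5 excluded, p = 0.01/reads = 6 kept
  expect_setequal(kept$site_id, c("s003", "s004"))
  bad <- sites; bad$p_value[2] <- NA
  expect_error(filter_high_confidence(bad), "missing p-values")
})

test_that("feature annotation follows the precedence rule and per-base oracle", {
  ann <- tiny_annotation()
  intronic <- make_sites("chr1", 110, 130)      # inside gplus intron 1
  expect_equal(annotate_features(intronic, ann)$feature, "intron")
  nowhere <- make_sites("chr1", 5000, 5030)
  a <- annotate_features(nowhere, ann)
  expect_equal(a$feature, "intergenic")
  expect_true(is.na(a$gene_id))
  # CDS wins over intron when a site straddles the boundary
  straddle <- make_sites("chr1", 90, 120)       # exon1 CDS piece + intron
  expect_equal(annotate_features(straddle, ann)$feature, "CDS")
  # UTR orientation flips with strand: leftmost exon of gminus is its 3' end
  left_minus <- make_sites("chr1", 2000, 2040)
  rec <- annotate_features(left_minus, ann)
  expect_equal(rec$feature[rec$gene_id == "gminus"], "3'UTR")

  sim <- simulate_study(sim_config(seed = 13, n_genes = 40), sequence = FALSE)
  set.seed(99)
  n <- 500
  chrom <- sample(names(sim$chrom_lengths), n, replace = TRUE)
  start <- floor(runif(n) * (sim$chrom_lengths[chrom] - 50))
  rnd <- make_sites(chrom, start, start + sample(5:40, n, replace = TRUE))
  got <- annotate_features(rnd, sim$ann)
  for (i in sample(n, 120)) {   # spot-check a random subset per-base
    want <- oracle_features(rnd[i, ], sim$ann)
    have <- got[got$site_id == rnd$site_id[i], ]
    expect_setequal(paste(have$gene_id, have$feature),
                    paste(want$gene_id, want$feature))
  }
  # full-set agreement on the feature tally
  oracle_all <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(site_id = rnd$site_id[i], oracle_features(rnd[i, ], sim$ann))))
  expect_equal(as.vector(table(factor(got$feature, sort(unique(oracle_all$feature))))),
               as.vector(table(factor(oracle_all$feature))))
})

test_that("feature distribution sums to one and recovers planted proportions", {
  ann <- tiny_annotation()
  all_intron <- make_sites("chr1", c(110, 310, 510), c(120, 320, 520))
  fd <- feature_distribution(annotate_features(all_intron, ann), ann)
  expect_equal(unname(fd$proportions["intron"]), 1.0)
  expect_equal(sum(fd$proportions), 1.0)

  # plant 62% intronic / 38% CDS sites and recover the split
  set.seed(31)
  n <- 400
  is_intron <- runif(n) < 0.62
  start <- ifelse(is_intron,
                  sample(c(105, 305, 505, 705), n, replace = TRUE),
                  sample(c(210, 410, 610), n, replace = TRUE))
  planted <- make_sites("chr1", start, start + 5)
  fd <- feature_distribution(annotate_features(planted, ann), ann)
  expect_equal(unname(fd$proportions["intron"]), mean(is_intron))
  # order invariance
  fd2 <- feature_distribution(annotate_features(planted[sample(n), ], ann), ann)
  expect_equal(fd2$proportions, fd$proportions)
  expect_error(feature_distribution(data.frame(), ann), "no annotated")
})

test_that("nucleotide composition is strand-corrected and reported as RNA", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ATATCCGGAAAA"))
  plus <- make_sites("chr1", 0, 4, strand = "+")          # ATAT
  comp <- nucleotide_composition(plus, genome)
  expect_equal(unname(comp[c("A", "U")]), c(0.5, 0.5))
  expect_equal(sum(comp), 1.0)
  minus <- make_sites("chr1", 8, 12, strand = "-")        # AAAA -> UUUU
  expect_equal(unname(nucleotide_composition(minus, genome)["U"]), 1.0)
  expect_error(nucleotide_composition(make_sites("chr1", 8, 20), genome),
               "bounds")

  set.seed(41)
  sim <- simulate_study(sim_config(seed = 41, n_genes = 30))
  s <- sim$sites[sample(nrow(sim$sites), 50), ]
  comp <- nucleotide_composition(s, sim$genome)
  # per-base tally oracle over the strand-corrected strings
  tally <- c(A = 0, C = 0, G = 0, T = 0)
  for (i in seq_len(nrow(s))) {
    str <- substr(as.character(sim$genome[[s$chrom[i]]]), s$start[i] + 1, s$end[i])
    if (s$strand[i] == "-") {
      str <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(str)))
    }
    for (b in names(tally)) {
      tally[b] <- tally[b] + lengths(regmatches(str, gregexpr(b, str)))
    }
  }
  expect_equal(unname(comp), unname(tally / sum(tally)))
})

test_that("k-mer table ranks the planted motif first and conserves counts", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "TTTTTGGG"))
  km <- kmer_top(make_sites("chr1", 0, 5), genome, k = 5)
  expect_equal(km$kmer[1], "UUUUU")
  expect_error(kmer_top(make_sites("chr1", 0, 5), genome, k = 2), "k >= 3")

  sim <- simulate_study(sim_config(seed = 17, n_genes = 60))
  hc <- filter_high_confidence(sim$sites)
  km <- kmer_top(hc, sim$genome, k = 6, top = Inf)
  expect_equal(km$kmer[1], "UAUUUA")
  lens <- hc$end - hc$start
  expect_equal(sum(km$count), sum(pmax(lens - 6 + 1, 0)))
})

test_that("circ-E/NE classification partitions exons of circRNA genes", {
  ann <- tiny_annotation()
  circ <- data.frame(circ_id = "c1", gene_id = "gplus", chrom = "chr1",
                     start = 200, end = 500, strand = "+")   # exons 2-3
  cls <- classify_exons(ann, circ)
  expect_equal(sort(cls$exons$ordinal[cls$exons$class == "circ_e"]), c(2, 3))
  expect_equal(sort(cls$exons$ordinal[cls$exons$class == "ne"]), c(1, 4, 5))
  # NE only from circRNA-producing genes: gminus contributes nothing
  expect_false("gminus" %in% cls$exons$gene_id)

  all_span <- data.frame(circ_id = "c2", gene_id = "gplus", chrom = "chr1",
                         start = 0, end = 1000, strand = "+")
  cls2 <- classify_exons(ann, all_span)
  expect_equal(sum(cls2$exons$class == "ne"), 0)

  off <- data.frame(circ_id = "c3", gene_id = "gplus", chrom = "chr1",
                    start = 205, end = 500, strand = "+")
  expect_warning(cls3 <- classify_exons(ann, off), "no exon boundary")
  expect_equal(nrow(cls3$circ_ranges), 0)

  # simulated genes: membership oracle over every (exon, circ) pair
  sim <- simulate_study(sim_config(seed = 19, n_genes = 80), sequence = FALSE)
  cls <- classify_exons(sim$ann, sim$circ_counts)
  expect_gt(nrow(cls$exons), 200)
  for (g in unique(cls$exons$gene_id)) {
    e <- cls$exons[cls$exons$gene_id == g, ]
    circs <- sim$circ_counts[sim$circ_counts$gene_id == g, ]
    for (r in seq_len(nrow(e))) {
      # genomic membership: the exon lies inside some circRNA span
      inside <- any(circs$start <= e$start[r] & e$end[r] <= circs$end)
      expect_equal(e$class[r] == "circ_e", inside)
    }
  }
})

test_that("flanking introns follow transcription direction on both strands", {
  ann <- tiny_annotation()
  fi <- flanking_introns_of(ann, "gplus", c(2, 3))
  expect_equal(fi$upstream$upstream_exon_ordinal, 1)
  expect_equal(fi$upstream$start, 100)   # intron between exons 1 and 2
  expect_equal(fi$downstream$upstream_exon_ordinal, 3)
  expect_equal(fi$downstream$start, 500)

  # minus strand: transcription runs right to left, so the upstream FI is
  # the genomically rightmost of the two
  fi <- flanking_introns_of(ann, "gminus", c(2, 3))
  expect_equal(fi$upstream$start, 2700)
  expect_equal(fi$downstream$start, 2300)

  # termini: a group starting at exon 1 has no upstream FI
  expect_null(flanking_introns_of(ann, "gplus", 1)$upstream)
  expect_null(flanking_introns_of(ann, "gplus", 5)$downstream)
})

test_that("flanking-intron profiles tally sites and intensity per intron", {
  ann <- tiny_annotation()
  circ <- data.frame(circ_id = "c1", gene_id = "gplus", chrom = "chr1",
                     start = 200, end = 500, strand = "+")
  cls <- classify_exons(ann, circ)
  none <- profile_flanking_introns(ann, cls, make_sites("chr1", 5000, 5020))
  expect_true(all(!none$has_binding))
  expect_true(all(none$n_sites == 0))

  two <- make_sites("chr1", c(110, 150), c(130, 170), reads = c(7, 9))
  prof <- profile_flanking_introns(ann, cls, two)
  up_fi <- prof[prof$start == 100, ]     # upstream FI of the circ-E group
  expect_equal(up_fi$n_sites, 2)
  expect_equal(up_fi$intensity, 16)
  expect_equal(up_fi$class, "circ_e")
  expect_true(up_fi$has_binding)
  # intron 3 flanks both the circ-E group and NE exon 4: counted once, circ-E
  expect_equal(sum(prof$start == 500), 1)
  expect_equal(prof$class[prof$start == 500], "circ_e")

  # random layout: per-FI tallies match the per-base interval oracle
  sim <- simulate_study(sim_config(seed = 23, n_genes = 50), sequence = FALSE)
  hc <- filter_high_confidence(sim$sites)
  cls <- classify_exons(sim$ann, sim$circ_counts)
  prof <- profile_flanking_introns(sim$ann, cls, hc)
  expect_gt(nrow(prof), 100)
  idx <- sample(nrow(prof), 80)
  for (r in idx) {
    same_chrom <- hc[hc$chrom == prof$chrom[r], ]
    ov <- vapply(seq_len(nrow(same_chrom)), function(i)
      oracle_overlap(prof$start[r], prof$end[r],
                     same_chrom$start[i], same_chrom$end[i]), integer(1))
    expect_equal(prof$n_sites[r], sum(ov > 0))
    expect_equal(prof$intensity[r], sum(same_chrom$reads[ov > 0]))
    expect_equal(prof$has_binding[r], any(ov > 0))
    expect_equal(prof$length[r], prof$end[r] - prof$start[r])
  }
})

test_that("group comparison degenerates loudly and is flat for identical groups", {
  prof <- data.frame(
    gene_id = "g", chrom = "c", start = 0, end = 10,
    class = rep(c("circ_e", "ne"), each = 40),
    group = "non-up",
    length = rep(c(100, 200, 150, 400), 20),
    n_sites = rep(c(0, 2, 0, 1), 20),
    intensity = rep(c(0, 30, 0, 10), 20),
    has_binding = rep(c(FALSE, TRUE, FALSE, TRUE), 20))
  cmp <- compare_flanking_groups(prof, "class")
  expect_equal(cmp$p_binding, 1)
  expect_equal(cmp$p_length, 1)
  expect_equal(cmp$prop_bound, c(0.5, 0.5))

  allbound <- prof; allbound$has_binding <- TRUE
  expect_error(compare_flanking_groups(allbound, "class"),
               "zero margin")
  expect_error(compare_flanking_groups(prof[prof$class == "ne", ], "class"),
               "at least 2")
})

test_that("exonic binding fraction counts circRNAs with sites in their exons", {
  ann <- tiny_annotation()
  circ <- data.frame(circ_id = "c1", gene_id = "gplus", chrom = "chr1",
                     start = 200, end = 500, strand = "+")
  cls <- classify_exons(ann, circ)
  none <- exonic_binding_fraction(ann, cls, make_sites("chr1", 5000, 5020))
  expect_equal(none$n_with, 0)
  hit <- exonic_binding_fraction(ann, cls, make_sites("chr1", 250, 260))
  expect_equal(hit$n_with, 1)
  expect_equal(hit$pct, 100)
  # a site in the flanking intron does not count as exonic
  fi_site <- exonic_binding_fraction(ann, cls, make_sites("chr1", 110, 130))
  expect_equal(fi_site$n_with, 0)
})

test_that("gene length comparison is a two-sided rank test with medians", {
  set.seed(8)
  x <- rlnorm(100, 9, 0.4)
  same <- gene_length_comparison(x, x)
  expect_gt(same$p_value, 0.9)

  bound <- rlnorm(100, 9 + log(2), 0.4)
  unbound <- rlnorm(100, 9, 0.4)
  cmp <- gene_length_comparison(bound, unbound)
  expect_lt(cmp$p_value, 1e-6)
  expect_equal(cmp$median_bound / cmp$median_unbound, 2, tolerance = 0.25)
  # order invariance up to sidedness
  expect_equal(gene_length_comparison(unbound, bound)$p_value, cmp$p_value)
  expect_error(gene_length_comparison(x[1:2], x), "at least 3")
})

test_that("flanking-intron statistics are invariant under genome mirroring", {
  sim <- simulate_study(sim_config(seed = 29, n_genes = 40), sequence = FALSE)
  hc <- filter_high_confidence(sim$sites)
  cls <- classify_exons(sim$ann, sim$circ_counts)
  prof <- profile_flanking_introns(sim$ann, cls, hc)

  # reflect every coordinate through its chromosome length and flip strands
  L <- sim$chrom_lengths
  flip <- function(df) {
    new <- df
    new$start <- as.integer(L[df$chrom] - df$end)
    new$end <- as.integer(L[df$chrom] - df$start)
    if (!is.null(df$strand)) new$strand <- ifelse(df$strand == "+", "-", "+")
    new
  }
  genes_m <- flip(sim$ann$genes)[, c("gene_id", "name", "chrom", "strand", "biotype")]
  cds <- flip(data.frame(chrom = sim$ann$genes$chrom,
                         start = sim$ann$genes$cds_start,
                         end = sim$ann$genes$cds_end))
  genes_m$cds_start <- cds$start
  genes_m$cds_end <- cds$end
  ann_m <- gene_annotation(genes_m, flip(sim$ann$exons)[, c(
    "gene_id", "transcript_id", "chrom", "strand", "start", "end")])
  circs_m <- flip(sim$circ_counts)
  hc_m <- flip(hc)

  cls_m <- classify_exons(ann_m, circs_m)
  prof_m <- profile_flanking_introns(ann_m, cls_m, hc_m)
  sig <- function(p) {
    s <- p[order(p$gene_id, p$length, p$n_sites, p$intensity),
           c("gene_id", "class", "length", "n_sites", "intensity", "has_binding")]
    rownames(s) <- NULL
    s
  }
  expect_equal(sig(prof_m), sig(prof))
})
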