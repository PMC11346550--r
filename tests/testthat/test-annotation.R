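test_that("GTF coordinates convert to 0-based half-open with strand-aware ordinals", {
  gtf <- file.path(tempdir(), "two_exon.gtf")
  lines <- function(strand) c(
    sprintf('chr1\tx\tgene\t101\t400\t.\t%s\t.\tgene_id "g1";', strand),
    sprintf('chr1\tx\ttranscript\t101\t400\t.\t%s\t.\tgene_id "g1"; transcript_id "t1";', strand),
    sprintf('chr1\tx\texon\t101\t200\t.\t%s\t.\tgene_id "g1"; transcript_id "t1";', strand),
    sprintf('chr1\tx\texon\t301\t400\t.\t%s\t.\tgene_id "g1"; transcript_id "t1";', strand))

  writeLines(lines("+"), gtf)
  ann <- read_gtf(gtf)
  e <- ann$exons[order(ann$exons$start), ]
  expect_equal(e$start, c(100, 300))
  expect_equal(e$end, c(200, 400))
  expect_equal(e$ordinal, c(1, 2))
  expect_equal(ann$introns$start, 200)
  expect_equal(ann$introns$end, 300)

  writeLines(lines("-"), gtf)
  ann <- read_gtf(gtf)
  e <- ann$exons[order(ann$exons$start), ]
  expect_equal(e$ordinal, c(2, 1))
  expect_equal(ann$introns$upstream_exon_ordinal, 1)
})

test_that("malformed GTF lines and out-of-span exons are rejected", {
  gtf <- file.path(tempdir(), "bad.gtf")
  writeLines(c('chr1\tx\tgene\t1\t100', "short line"), gtf)
  expect_error(read_gtf(gtf), "malformed GTF line 1")

  writeLines(c(
    'chr1\tx\tgene\t101\t200\t.\t+\t.\tgene_id "g1";',
    'chr1\tx\texon\t101\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'), gtf)
  expect_error(read_gtf(gtf), "outside gene span")
})

test_that("derive_introns returns the gaps with transcription-order labels", {
  one <- data.frame(gene_id = "g", chrom = "c", strand = "+",
                    start = 0, end = 10)
  expect_equal(nrow(derive_introns(one)), 0)

  three <- data.frame(gene_id = "g", chrom = "c", strand = "+",
                      start = c(0, 20, 40), end = c(10, 30, 50))
  intr <- derive_introns(three)
  expect_equal(intr$start, c(10, 30))
  expect_equal(intr$end, c(20, 40))
  expect_equal(intr$upstream_exon_ordinal, c(1, 2))

  minus <- data.frame(gene_id = "g", chrom = "c", strand = "-",
                      start = c(0, 20), end = c(10, 30))
  intr <- derive_introns(minus)
  expect_equal(intr$start, 10)
  expect_equal(intr$end, 20)
  expect_equal(intr$upstream_exon_ordinal, 1)

  overlapping <- data.frame(gene_id = "g", chrom = "c", strand = "+",
                            start = c(0, 5), end = c(10, 20))
  expect_error(derive_introns(overlapping), "overlapping")
})

test_that("every multi-exon gene's introns abut their neighbouring exons", {
  sim <- simulate_genome_annotation(sim_config(seed = 11, n_genes = 30),
                                    sequence = FALSE)
  ann <- sim$ann
  for (g in ann$genes$gene_id) {
    e <- ann$exons[ann$exons$gene_id == g, ]
    i <- ann$introns[ann$introns$gene_id == g, ]
    expect_equal(nrow(i), nrow(e) - 1)
    # brute-force adjacency: each intron must abut exactly one exon end and
    # one exon start, with no gap or overlap
    for (r in seq_len(nrow(i))) {
      expect_equal(sum(e$end == i$start[r]), 1)
      expect_equal(sum(e$start == i$end[r]), 1)
    }
    # exons and introns tile the gene span
    pieces <- rbind(e[, c("start", "end")], i[, c("start", "end")])
    pieces <- pieces[order(pieces$start), ]
    expect_equal(pieces$start[-1], pieces$end[-nrow(pieces)])
    gg <- ann$genes[ann$genes$gene_id == g, ]
    expect_equal(min(pieces$start), gg$start)
    expect_equal(max(pieces$end), gg$end)
    expect_equal(gg$length, gg$end - gg$start)
  }
})

test_that("GTF write/read round-trips gene, exon and CDS coordinates", {
  sim <- simulate_genome_annotation(sim_config(seed = 5, n_genes = 25),
                                    sequence = FALSE)
  f <- file.path(tempdir(), "roundtrip.gtf")
  write_gtf(sim$ann, f)
  expect_no_warning(ann2 <- read_gtf(f))
  key <- function(a) {
    e <- a$exons[order(a$exons$gene_id, a$exons$start),
                 c("gene_id", "chrom", "strand", "start", "end", "ordinal")]
    rownames(e) <- NULL
    e
  }
  expect_equal(key(ann2), key(sim$ann))
  g1 <- sim$ann$genes[order(sim$ann$genes$gene_id), ]
  g2 <- ann2$genes[order(ann2$genes$gene_id), ]
  expect_equal(g2$start, g1$start)
  expect_equal(g2$end, g1$end)
  expect_equal(g2$strand, g1$strand)
  expect_equal(g2$biotype, g1$biotype)
  expect_equal(g2$cds_start, g1$cds_start)
  expect_equal(g2$cds_end, g1$cds_end)
})

test_that("interval overlap matches the per-base oracle and its invariants", {
  expect_equal(interval_overlap(0, 10, 10, 20), 0L)
  expect_equal(interval_overlap(0, 10, 5, 8), 3L)
  expect_equal(interval_overlap(0, 10, 5, 8, "chr1", "chr2"), 0L)

  set.seed(42)
  for (i in 1:1000) {
    s1 <- sample(0:80, 1); e1 <- s1 + sample(1:40, 1)
    s2 <- sample(0:80, 1); e2 <- s2 + sample(1:40, 1)
    ov <- interval_overlap(s1, e1, s2, e2)
    expect_identical(ov, oracle_overlap(s1, e1, s2, e2))
    # symmetry and the short-interval bound
    expect_identical(ov, interval_overlap(s2, e2, s1, e1))
    expect_lte(ov, min(e1 - s1, e2 - s2))
  }
})

test_that("sites BED6+2 writer and reader round-trip", {
  sites <- make_sites("chr2", c(10, 50), c(40, 90), strand = c("+", "-"),
                      reads = c(7, 9), p_value = c(0.01, 0.5))
  f <- file.path(tempdir(), "sites.bed")
  write_sites(sites, f)
  back <- read_sites(f)
  expect_equal(back, sites, ignore_attr = TRUE)
  bad <- sites; bad$p_value[1] <- 2
  expect_error(write_sites(bad, f), "p-values")
})
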