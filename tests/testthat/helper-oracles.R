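# Independent brute-force oracles and tiny fixtures shared across tests.
# Oracles deliberately avoid the package's interval arithmetic: they
# enumerate bases one at a time.

# per-base overlap count of two half-open intervals
oracle_overlap <- function(s1, e1, s2, e2, c1 = "c", c2 = "c") {
  if (c1 != c2) return(0L)
  sum((s1:(e1 - 1)) %in% (s2:(e2 - 1)))
}

# per-base feature call of one site against a gene_annotation, applying the
# precedence CDS > 3'UTR > 5'UTR > noncoding_exon > intron per gene
oracle_features <- function(site, ann) {
  prec <- c("CDS", "3'UTR", "5'UTR", "noncoding_exon", "intron", "intergenic")
  bases <- site$start:(site$end - 1)
  out <- list()
  for (gi in seq_len(nrow(ann$genes))) {
    g <- ann$genes[gi, ]
    if (g$chrom != site$chrom) next
    feats <- character(0)
    ex <- ann$exons[ann$exons$gene_id == g$gene_id, ]
    intr <- ann$introns[ann$introns$gene_id == g$gene_id, ]
    for (b in bases) {
      in_ex <- any(ex$start <= b & b < ex$end)
      if (in_ex) {
        if (g$biotype != "coding" || is.na(g$cds_start)) {
          feats <- c(feats, "noncoding_exon")
        } else if (g$cds_start <= b && b < g$cds_end) {
          feats <- c(feats, "CDS")
        } else if (b < g$cds_start) {
          feats <- c(feats, if (g$strand == "+") "5'UTR" else "3'UTR")
        } else {
          feats <- c(feats, if (g$strand == "+") "3'UTR" else "5'UTR")
        }
      } else if (any(intr$start <= b & b < intr$end)) {
        feats <- c(feats, "intron")
      }
    }
    if (length(feats) > 0) {
      out[[g$gene_id]] <- prec[min(match(feats, prec))]
    }
  }
  if (length(out) == 0) return(data.frame(gene_id = NA_character_,
                                          feature = "intergenic"))
  data.frame(gene_id = names(out), feature = unlist(out), row.names = NULL)
}

# a small two-gene annotation, one gene per strand, five exons each
tiny_annotation <- function() {
  ex <- function(gid, chrom, strand, starts, ends) {
    data.frame(gene_id = gid, chrom = chrom, strand = strand,
               start = starts, end = ends)
  }
  genes <- data.frame(
    gene_id = c("gplus", "gminus"),
    chrom = c("chr1", "chr1"),
    strand = c("+", "-"),
    biotype = c("coding", "coding"),
    cds_start = c(50L, 2050L),
    cds_end = c(950L, 2950L)
  )
  exons <- rbind(
    ex("gplus", "chr1", "+", c(0, 200, 400, 600, 800),
       c(100, 300, 500, 700, 1000)),
    ex("gminus", "chr1", "-", c(2000, 2200, 2400, 2600, 2800),
       c(2100, 2300, 2500, 2700, 3000))
  )
  gene_annotation(genes, exons)
}

# deterministic site table builder
make_sites <- function(chrom, start, end, strand = "+", reads = 10,
                       p_value = 0.01) {
  data.frame(site_id = sprintf("s%03d", seq_along(start)),
             chrom = chrom, start = start, end = end, strand = strand,
             reads = reads, p_value = p_value)
}

# null-study configuration: no planted effect anywhere
null_sim_config <- function(seed, n_genes = 60) {
  sim_config(seed = seed, n_genes = n_genes, ko_circ_boost = 1,
             site_rate_fi_up = 0.3, fi_len_multiplier_up = 1,
             cdk1_mrna_effect = 1, ko_mrna_effect = 1)
}

# per-gene nascent circRNA fraction vectors, as the pipeline builds them
nascent_fracs <- function(sim, sample) {
  ngm <- count_matrix(sim$nascent_gene_counts, id_col = "gene_id")
  genes <- rownames(ngm)
  circ <- stats::setNames(rep(0, length(genes)), genes)
  agg <- tapply(sim$nascent_circ_counts[[paste0("count_", sample)]],
                sim$nascent_circ_counts$gene_id, sum)
  circ[names(agg)] <- agg
  tot <- ngm[, sample]
  ok <- circ >= 1 & (tot - circ) >= 1
  stats::setNames(suppressMessages(nascent_circ_fraction(circ[ok], tot[ok])),
                  genes[ok])
}
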