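#' Configuration of the synthetic study generator
#'
#' Defines the planted study: a small multi-chromosome genome of
#' intron-containing genes on both strands, a subset of genes producing one
#' exonic circRNA each, binding peaks laid down at a background rate and
#' enriched (with longer introns) in the flanking introns of regulated
#' circRNAs, and WT/KO negative-binomial count tables where the knockout
#' boosts circRNA output of regulated genes while leaving mRNA levels
#' untouched except for a small "CDK1-like" subset whose mRNA drops.
#'
#' Defaults describe the study conditions emulated throughout the package:
#' 500 genes on 4 chromosomes, 4-8 exons of 100-300 bp, lognormal intron
#' lengths (meanlog 6.5, sdlog 0.6, i.e. median ~665 bp), 60% of genes
#' circRNA-producing of which 30% are regulated, background site rate
#' 0.3/kb with a 4x rate and 2x intron length in regulated flanking introns,
#' a 3x KO boost of regulated circRNAs, unchanged mRNA except a 0.6x drop
#' for the CDK1-like 5% of circ genes, NB dispersion 0.1, and the U/A-rich
#' hexamer UAUUUA planted in 80% of site sequences.
#'
#' @param seed integer; fixes every random draw, making all emitted files
#'   byte-identical across runs.
#' @param n_genes,n_chrom genome size.
#' @param exon_count_range,exon_len_range,intron_len_meanlog,intron_len_sdlog
#'   gene architecture (exon counts must allow an internal circularized
#'   group, so the minimum is 4).
#' @param frac_coding fraction of genes with a CDS (others are noncoding).
#' @param frac_circ_genes,frac_regulated,frac_cdk1_like planted gene classes;
#'   the latter two are fractions of circRNA-producing genes, and CDK1-like
#'   genes are drawn from the regulated ones.
#' @param site_rate_bg,site_rate_fi_up binding-site rates in sites/kb
#'   (fi_up defaults to 4x background); \code{site_width_range} in bp.
#' @param intensity_mean,intensity_size NB law of per-site read counts.
#' @param frac_alt_sites fraction of sites from the alternative p-value
#'   component Beta(0.2, 5); the rest are null Uniform(0, 1).
#' @param motif,motif_freq RNA-sense motif written into this fraction of site
#'   sequences.
#' @param fi_len_multiplier_up length multiplier of regulated flanking
#'   introns.
#' @param ko_circ_boost,ko_mrna_effect,cdk1_mrna_effect KO mean multipliers.
#' @param nb_dispersion shared NB dispersion of count tables (variance
#'   mu + dispersion * mu^2).
#' @param circ_mu_meanlog,circ_mu_sdlog,mrna_mu_meanlog,mrna_mu_sdlog,
#'   nascent_gene_mu_meanlog,nascent_gene_mu_sdlog,nascent_circ_scale
#'   lognormal laws of baseline means.
#' @param library_size,nascent_library_size total mapped reads per library.
#' @param intergenic_gap_range spacing between genes, bp.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 500,
                       n_chrom = 4,
                       exon_count_range = c(4, 8),
                       exon_len_range = c(100, 300),
                       intron_len_meanlog = 6.5,
                       intron_len_sdlog = 0.6,
                       frac_coding = 0.85,
                       frac_circ_genes = 0.6,
                       frac_regulated = 0.3,
                       frac_cdk1_like = 0.05,
                       site_rate_bg = 0.3,
                       site_rate_fi_up = NULL,
                       site_width_range = c(20, 40),
                       intensity_mean = 20,
                       intensity_size = 2,
                       frac_alt_sites = 0.7,
                       motif = "UAUUUA",
                       motif_freq = 0.8,
                       fi_len_multiplier_up = 2,
                       ko_circ_boost = 3,
                       ko_mrna_effect = 1,
                       cdk1_mrna_effect = 0.6,
                       nb_dispersion = 0.01,
                       circ_mu_meanlog = log(50),
                       circ_mu_sdlog = 0.4,
                       mrna_mu_meanlog = log(500),
                       mrna_mu_sdlog = 0.8,
                       nascent_gene_mu_meanlog = log(200),
                       nascent_gene_mu_sdlog = 0.7,
                       nascent_circ_scale = 0.3,
                       library_size = 1e6,
                       nascent_library_size = 2e5,
                       intergenic_gap_range = c(500, 2000)) {
  if (is.null(site_rate_fi_up)) site_rate_fi_up <- 4 * site_rate_bg
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 1, cfg$exon_count_range[1] >= 4,
            cfg$frac_circ_genes >= 0, cfg$frac_circ_genes <= 1,
            cfg$frac_regulated >= 0, cfg$frac_regulated <= 1,
            cfg$site_rate_bg >= 0, cfg$site_rate_fi_up >= 0,
            cfg$nb_dispersion >= 0, cfg$library_size > 0)
  structure(cfg, class = "sim_config")
}

# NB sampler parameterized by mean and dispersion (Poisson when disp = 0)
rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate the genome and gene annotation
#'
#' Lays the genes out gene-by-gene along the chromosomes (alternating
#' strands), chooses an internal contiguous exon group of 1-2 exons as the
#' circularized group of each circRNA-producing gene, lengthens the two
#' flanking introns of regulated groups by \code{fi_len_multiplier_up}, and
#' (optionally) draws a uniform-random nucleotide sequence for each
#' chromosome. The truth table records gene classes and per-flanking-intron
#' planted site rates.
#'
#' @param cfg a \code{sim_config}.
#' @param dir output directory for \code{genome.fa}, \code{annotation.gtf}
#'   and truth tables; NULL writes nothing.
#' @param sequence draw chromosome sequences (skippable for count-only
#'   studies).
#' @return list of class \code{circ_sim} with \code{$ann}
#'   (gene_annotation), \code{$genome}, \code{$circs}, \code{$truth_genes},
#'   \code{$truth_fi}, \code{$chrom_lengths} and \code{$cfg}.
#' @export
simulate_genome_annotation <- function(cfg = sim_config(), dir = NULL,
                                       sequence = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  if (diff(cfg$exon_len_range) < 0 || diff(cfg$intergenic_gap_range) < 0) {
    stop("infeasible length ranges")
  }

  n_circ <- round(cfg$frac_circ_genes * n)
  circ_genes <- sort(sample.int(n, n_circ))
  n_reg <- round(cfg$frac_regulated * n_circ)
  regulated <- sort(sample(circ_genes, n_reg))
  n_cdk <- min(n_reg, round(cfg$frac_cdk1_like * n_circ))
  cdk1_like <- sort(sample(regulated, n_cdk))

  gene_rows <- exon_rows <- circ_rows <- fi_rows <- vector("list", n)
  cursor <- stats::setNames(rep(0L, cfg$n_chrom),
                            paste0("chr", seq_len(cfg$n_chrom)))
  for (g in seq_len(n)) {
    gid <- sprintf("G%04d", g)
    chrom <- paste0("chr", (g - 1L) %% cfg$n_chrom + 1L)
    strand <- if (g %% 2 == 0) "-" else "+"
    n_ex <- sample(cfg$exon_count_range[1]:cfg$exon_count_range[2], 1)
    ex_len <- sample(cfg$exon_len_range[1]:cfg$exon_len_range[2], n_ex,
                     replace = TRUE)
    in_len <- pmax(60L, round(stats::rlnorm(n_ex - 1, cfg$intron_len_meanlog,
                                            cfg$intron_len_sdlog)))

    is_circ <- g %in% circ_genes
    a <- d <- NA_integer_
    if (is_circ) {
      span <- sample(1:2, 1)
      a <- sample(2:(n_ex - span), 1)        # internal group: both FIs exist
      d <- a + span - 1L
      if (g %in% regulated) {
        fi_idx <- c(a - 1L, d)               # introns flanking the group
        in_len[fi_idx] <- round(in_len[fi_idx] * cfg$fi_len_multiplier_up)
      }
    }

    # transcription-order piece lengths -> genomic layout
    piece_len <- integer(2 * n_ex - 1)
    piece_len[seq(1, 2 * n_ex - 1, by = 2)] <- ex_len
    if (n_ex > 1) piece_len[seq(2, 2 * n_ex - 2, by = 2)] <- in_len
    if (strand == "-") piece_len <- rev(piece_len)
    gap <- sample(cfg$intergenic_gap_range[1]:cfg$intergenic_gap_range[2], 1)
    gstart <- cursor[chrom] + gap
    bounds <- gstart + c(0L, cumsum(piece_len))
    cursor[chrom] <- bounds[length(bounds)]

    is_ex <- rep(c(TRUE, FALSE), length.out = 2 * n_ex - 1)
    ex_start <- bounds[-length(bounds)][is_ex]
    ex_end <- bounds[-1][is_ex]
    exon_rows[[g]] <- data.frame(gene_id = gid,
                                 transcript_id = paste0(gid, ".t1"),
                                 chrom = chrom, strand = strand,
                                 start = as.integer(ex_start),
                                 end = as.integer(ex_end))

    coding <- stats::runif(1) < cfg$frac_coding
    gene_rows[[g]] <- data.frame(
      gene_id = gid, name = gid, chrom = chrom, strand = strand,
      biotype = if (coding) "coding" else "noncoding",
      cds_start = if (coding)
        as.integer(floor((ex_start[1] + ex_end[1]) / 2)) else NA_integer_,
      cds_end = if (coding)
        as.integer(ceiling((ex_start[n_ex] + ex_end[n_ex]) / 2)) else NA_integer_
    )

    if (is_circ) {
      # exon with transcription ordinal k sits at genomic index k (+) / n-k+1 (-)
      g_idx <- function(k) if (strand == "+") k else n_ex - k + 1L
      members <- vapply(a:d, g_idx, integer(1))
      circ_rows[[g]] <- data.frame(
        circ_id = paste0("circ_", gid), gene_id = gid, chrom = chrom,
        start = as.integer(min(ex_start[members])),
        end = as.integer(max(ex_end[members])),
        strand = strand, acceptor_ordinal = a, donor_ordinal = d)
      # flanking introns in genomic coordinates, with their planted site rate
      intr_start <- bounds[-length(bounds)][!is_ex]
      intr_end <- bounds[-1][!is_ex]
      up_tx_ord <- if (strand == "+") seq_len(n_ex - 1L) else rev(seq_len(n_ex - 1L))
      fi_sel <- up_tx_ord %in% c(a - 1L, d)
      fi_rows[[g]] <- data.frame(
        gene_id = gid, chrom = chrom,
        start = as.integer(intr_start[fi_sel]),
        end = as.integer(intr_end[fi_sel]),
        planted_rate = if (g %in% regulated) cfg$site_rate_fi_up
                       else cfg$site_rate_bg)
    }
  }

  genes <- do.call(rbind, gene_rows)
  ann <- gene_annotation(genes, do.call(rbind, exon_rows))
  circs <- do.call(rbind, circ_rows)
  if (is.null(circs)) {
    circs <- data.frame(circ_id = character(), gene_id = character(),
                        chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        acceptor_ordinal = integer(), donor_ordinal = integer())
  }
  truth_fi <- do.call(rbind, fi_rows)
  if (is.null(truth_fi)) {
    truth_fi <- data.frame(gene_id = character(), chrom = character(),
                           start = integer(), end = integer(),
                           planted_rate = numeric())
  }
  chrom_lengths <- cursor + 1000L

  genome <- NULL
  if (sequence) {
    base_codes <- utf8ToInt("ACGT")
    genome <- Biostrings::DNAStringSet(vapply(chrom_lengths, function(L) {
      intToUtf8(base_codes[sample.int(4L, L, replace = TRUE)])
    }, character(1)))
    names(genome) <- names(chrom_lengths)
  }

  truth_genes <- data.frame(
    gene_id = genes$gene_id,
    circ_producing = seq_len(n) %in% circ_genes,
    regulated = seq_len(n) %in% regulated,
    cdk1_like = seq_len(n) %in% cdk1_like
  )

  sim <- structure(list(ann = ann, genome = genome, circs = circs,
                        truth_genes = truth_genes, truth_fi = truth_fi,
                        chrom_lengths = chrom_lengths, cfg = cfg),
                   class = "circ_sim")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_gtf(ann, file.path(dir, "annotation.gtf"))
    if (!is.null(genome)) {
      Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
    }
    write_tsv(truth_genes, file.path(dir, "truth_genes.tsv"))
    write_tsv(truth_fi, file.path(dir, "truth_fi.tsv"))
  }
  sim
}

#' Simulate binding sites over a simulated genome
#'
#' Background sites fall as a Poisson process at \code{site_rate_bg} per kb
#' over the whole genome; flanking introns of regulated circularized groups
#' receive additional sites so their total rate is \code{site_rate_fi_up}.
#' Per-site read counts are negative binomial; p-values come from a known
#' mixture (alternative Beta(0.2, 5) vs null Uniform), so the
#' high-confidence filter has known operating characteristics that are
#' independent of site location. When the genome sequence is present, the
#' configured motif is written into a fraction of site sequences
#' (strand-aware).
#'
#' @param cfg a \code{sim_config} (that used for the annotation).
#' @param sim the \code{circ_sim} from \code{simulate_genome_annotation}.
#' @param dir output directory for \code{sites.bed}, \code{truth_sites.tsv}
#'   (and the motif-carrying \code{genome.fa}); NULL writes nothing.
#' @return the \code{circ_sim} with \code{$sites}, \code{$truth_sites} and a
#'   possibly motif-edited \code{$genome}.
#' @export
simulate_binding_sites <- function(cfg, sim, dir = NULL) {
  stopifnot(inherits(sim, "circ_sim"))
  set.seed(cfg$seed + 1L)
  total_kb <- sum(sim$chrom_lengths) / 1000

  n_bg <- stats::rpois(1, cfg$site_rate_bg * total_kb)
  chrom <- sample(names(sim$chrom_lengths), n_bg, replace = TRUE,
                  prob = sim$chrom_lengths / sum(sim$chrom_lengths))
  start <- floor(stats::runif(n_bg) * (sim$chrom_lengths[chrom] - 60))
  width <- sample(cfg$site_width_range[1]:cfg$site_width_range[2], n_bg,
                  replace = TRUE)
  sites <- data.frame(chrom = chrom, start = as.integer(start),
                      end = as.integer(start + width))

  extra_rate <- cfg$site_rate_fi_up - cfg$site_rate_bg
  up_fi <- sim$truth_fi[sim$truth_fi$planted_rate > cfg$site_rate_bg, ,
                        drop = FALSE]
  if (extra_rate > 0 && nrow(up_fi) > 0) {
    n_extra <- stats::rpois(nrow(up_fi), extra_rate * (up_fi$end - up_fi$start) / 1000)
    idx <- rep(seq_len(nrow(up_fi)), n_extra)
    if (length(idx) > 0) {
      w <- sample(cfg$site_width_range[1]:cfg$site_width_range[2], length(idx),
                  replace = TRUE)
      s <- up_fi$start[idx] +
        floor(stats::runif(length(idx)) *
                pmax(1, up_fi$end[idx] - up_fi$start[idx] - w))
      sites <- rbind(sites, data.frame(chrom = up_fi$chrom[idx],
                                       start = as.integer(s),
                                       end = as.integer(s + w)))
    }
  }
  if (nrow(sites) == 0) {
    sim$sites <- data.frame(site_id = character(), chrom = character(),
                            start = integer(), end = integer(),
                            strand = character(), reads = integer(),
                            p_value = numeric())
    sim$truth_sites <- data.frame(site_id = character(), is_alt = logical())
    return(sim)
  }
  sites$end <- pmin(sites$end, sim$chrom_lengths[sites$chrom])

  # strand: that of an overlapped gene, random intergenically
  sites$strand <- sample(c("+", "-"), nrow(sites), replace = TRUE)
  hits <- GenomicRanges::findOverlaps(as_granges0(sites),
                                      as_granges0(sim$ann$genes),
                                      ignore.strand = TRUE, select = "first")
  genic <- !is.na(hits)
  sites$strand[genic] <- sim$ann$genes$strand[hits[genic]]

  ord <- order(sites$chrom, sites$start)
  sites <- sites[ord, , drop = FALSE]
  sites$site_id <- sprintf("site_%06d", seq_len(nrow(sites)))
  sites$reads <- as.integer(stats::rnbinom(nrow(sites), mu = cfg$intensity_mean,
                                           size = cfg$intensity_size))
  is_alt <- stats::runif(nrow(sites)) < cfg$frac_alt_sites
  sites$p_value <- ifelse(is_alt,
                          stats::rbeta(nrow(sites), 0.2, 5),
                          stats::runif(nrow(sites)))

  if (!is.null(sim$genome) && nzchar(cfg$motif)) {
    dna <- chartr("U", "T", cfg$motif)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
    k <- nchar(dna)
    plant <- which(stats::runif(nrow(sites)) < cfg$motif_freq &
                     sites$end - sites$start > k)
    if (length(plant) > 0) {
      off <- vapply(plant, function(i)
        sample.int(sites$end[i] - sites$start[i] - k + 1L, 1), integer(1))
      at <- sites$start[plant] + off          # 1-based start of the window
      ins <- ifelse(sites$strand[plant] == "-", rc, dna)
      edits <- data.frame(chrom = rep(sites$chrom[plant], each = k),
                          pos = rep(at, each = k) + seq_len(k) - 1L,
                          letter = unlist(strsplit(ins, "")))
      edits <- edits[!duplicated(edits[c("chrom", "pos")]), , drop = FALSE]
      for (ch in unique(edits$chrom)) {
        e <- edits[edits$chrom == ch, , drop = FALSE]
        sim$genome[[ch]] <- Biostrings::replaceLetterAt(
          sim$genome[[ch]], e$pos, paste(e$letter, collapse = ""))
      }
    }
  }

  rownames(sites) <- NULL
  sim$sites <- sites[, c("site_id", "chrom", "start", "end", "strand",
                         "reads", "p_value")]
  sim$truth_sites <- data.frame(site_id = sites$site_id, is_alt = is_alt)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_sites(sim$sites, file.path(dir, "sites.bed"))
    write_tsv(sim$truth_sites, file.path(dir, "truth_sites.tsv"))
    if (!is.null(sim$genome)) {
      Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
    }
  }
  sim
}

#' Simulate steady-state and nascent count tables
#'
#' CircRNA BSJ counts and gene-level mRNA counts are negative binomial with
#' shared dispersion. The knockout multiplies the circRNA mean of regulated
#' genes by \code{ko_circ_boost} (steady and nascent alike); mRNA means are
#' multiplied by \code{ko_mrna_effect} (1 by default) except CDK1-like genes,
#' which get \code{cdk1_mrna_effect}. Nascent tables share the effect
#' structure at a smaller library size, and each gene's nascent total is the
#' sum of its linear and BSJ nascent reads, so the circRNA fraction is well
#' defined.
#'
#' @param cfg a \code{sim_config}.
#' @param sim the \code{circ_sim} built so far.
#' @param dir output directory for the count TSVs; NULL writes nothing.
#' @return the \code{circ_sim} with \code{$circ_counts}, \code{$mrna_counts},
#'   \code{$nascent_gene_counts}, \code{$nascent_circ_counts},
#'   \code{$library_sizes}, \code{$nascent_library_sizes} and
#'   \code{$truth_circs}.
#' @export
simulate_counts <- function(cfg, sim, dir = NULL) {
  stopifnot(inherits(sim, "circ_sim"))
  set.seed(cfg$seed + 2L)
  tg <- sim$truth_genes
  circs <- sim$circs
  nc <- nrow(circs)
  disp <- cfg$nb_dispersion

  reg <- tg$regulated[match(circs$gene_id, tg$gene_id)]
  boost <- ifelse(reg, cfg$ko_circ_boost, 1)
  mu_c <- stats::rlnorm(nc, cfg$circ_mu_meanlog, cfg$circ_mu_sdlog)
  circ_counts <- cbind(circs[, c("circ_id", "chrom", "start", "end",
                                 "strand", "gene_id")],
                       count_WT = rnb(nc, mu_c, disp),
                       count_KO = rnb(nc, mu_c * boost, disp))

  ng <- nrow(tg)
  mu_m <- stats::rlnorm(ng, cfg$mrna_mu_meanlog, cfg$mrna_mu_sdlog)
  m_eff <- ifelse(tg$cdk1_like, cfg$cdk1_mrna_effect, cfg$ko_mrna_effect)
  mrna_counts <- data.frame(gene_id = tg$gene_id,
                            count_WT = rnb(ng, mu_m, disp),
                            count_KO = rnb(ng, mu_m * m_eff, disp))

  # nascent: linear reads per gene plus BSJ reads per circRNA; the gene
  # total is their sum so circ reads can never exceed it
  mu_nl <- stats::rlnorm(ng, cfg$nascent_gene_mu_meanlog,
                         cfg$nascent_gene_mu_sdlog)
  lin_wt <- rnb(ng, mu_nl, disp)
  lin_ko <- rnb(ng, mu_nl * m_eff, disp)
  mu_ncirc <- mu_c * cfg$nascent_circ_scale
  ncirc_wt <- rnb(nc, mu_ncirc, disp)
  ncirc_ko <- rnb(nc, mu_ncirc * boost, disp)
  nascent_circ_counts <- cbind(circs[, c("circ_id", "chrom", "start", "end",
                                         "strand", "gene_id")],
                               count_WT = ncirc_wt, count_KO = ncirc_ko)
  gi <- match(circs$gene_id, tg$gene_id)
  csum <- function(x) {
    out <- rep(0L, ng)
    if (nc > 0) {
      agg <- tapply(x, gi, sum)
      out[as.integer(names(agg))] <- agg
    }
    out
  }
  nascent_gene_counts <- data.frame(gene_id = tg$gene_id,
                                    count_WT = lin_wt + csum(ncirc_wt),
                                    count_KO = lin_ko + csum(ncirc_ko))

  sim$circ_counts <- circ_counts
  sim$mrna_counts <- mrna_counts
  sim$nascent_gene_counts <- nascent_gene_counts
  sim$nascent_circ_counts <- nascent_circ_counts
  sim$library_sizes <- c(WT = cfg$library_size, KO = cfg$library_size)
  sim$nascent_library_sizes <- c(WT = cfg$nascent_library_size,
                                 KO = cfg$nascent_library_size)
  sim$truth_circs <- data.frame(circ_id = circs$circ_id, true_fc = boost)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(circ_counts, file.path(dir, "circ_counts.tsv"))
    write_tsv(mrna_counts, file.path(dir, "mrna_counts.tsv"))
    write_tsv(nascent_gene_counts, file.path(dir, "nascent_gene_counts.tsv"))
    write_tsv(nascent_circ_counts, file.path(dir, "nascent_circ_counts.tsv"))
    write_tsv(data.frame(sample = names(sim$library_sizes),
                         steady = unname(sim$library_sizes),
                         nascent = unname(sim$nascent_library_sizes)),
              file.path(dir, "library_sizes.tsv"))
    write_tsv(sim$truth_circs, file.path(dir, "truth_circs.tsv"))
  }
  sim
}

#' Simulate a complete synthetic study
#'
#' Runs annotation, binding-site and count simulation in sequence under one
#' seed; with \code{dir} set, emits the whole run directory (FASTA, GTF,
#' BED6+2, count TSVs, truth tables) byte-identically for a given
#' configuration.
#'
#' @param cfg a \code{sim_config}.
#' @param dir optional output directory.
#' @param sequence draw chromosome sequences (needed for composition/k-mer
#'   analyses; skippable for count-level studies).
#' @return a \code{circ_sim} bundle.
#' @export
simulate_study <- function(cfg = sim_config(), dir = NULL, sequence = TRUE) {
  sim <- simulate_genome_annotation(cfg, dir = NULL, sequence = sequence)
  sim <- simulate_binding_sites(cfg, sim, dir = NULL)
  sim <- simulate_counts(cfg, sim, dir = NULL)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_gtf(sim$ann, file.path(dir, "annotation.gtf"))
    if (!is.null(sim$genome)) {
      Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
    }
    write_tsv(sim$truth_genes, file.path(dir, "truth_genes.tsv"))
    write_tsv(sim$truth_fi, file.path(dir, "truth_fi.tsv"))
    write_sites(sim$sites, file.path(dir, "sites.bed"))
    write_tsv(sim$truth_sites, file.path(dir, "truth_sites.tsv"))
    write_tsv(sim$circ_counts, file.path(dir, "circ_counts.tsv"))
    write_tsv(sim$mrna_counts, file.path(dir, "mrna_counts.tsv"))
    write_tsv(sim$nascent_gene_counts, file.path(dir, "nascent_gene_counts.tsv"))
    write_tsv(sim$nascent_circ_counts, file.path(dir, "nascent_circ_counts.tsv"))
    write_tsv(data.frame(sample = names(sim$library_sizes),
                         steady = unname(sim$library_sizes),
                         nascent = unname(sim$nascent_library_sizes)),
              file.path(dir, "library_sizes.tsv"))
    write_tsv(sim$truth_circs, file.path(dir, "truth_circs.tsv"))
  }
  sim
}

#' @export
print.circ_sim <- function(x, ...) {
  cat("circ_sim:", nrow(x$ann$genes), "genes,",
      nrow(x$circs), "circRNAs,",
      if (!is.null(x$sites)) nrow(x$sites) else 0, "binding sites\n")
  cat("  regulated:", sum(x$truth_genes$regulated),
      " cdk1-like:", sum(x$truth_genes$cdk1_like), "\n")
  invisible(x)
}
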