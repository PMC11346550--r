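#' Build a gene annotation object
#'
#' Assembles the package's central annotation container from a gene table and
#' an exon table. Exon ordinals are assigned in transcription order (genomic
#' order on "+" genes, reversed on "-" genes), introns are derived as the gaps
#' between consecutive exons, and the gene span/length is computed from the
#' exons. All coordinates are 0-based half-open.
#'
#' @param genes data.frame with columns gene_id, chrom, strand and optionally
#'   name, biotype ("coding"/"noncoding"), transcript_id, cds_start, cds_end.
#' @param exons data.frame with columns gene_id, chrom, strand, start, end and
#'   optionally transcript_id.
#' @return an object of class \code{gene_annotation}: a list with data.frames
#'   \code{$genes} (incl. start, end, length), \code{$exons} (incl. ordinal)
#'   and \code{$introns} (incl. upstream_exon_ordinal, the transcription-order
#'   ordinal of the exon immediately 5' of the intron).
#' @export
gene_annotation <- function(genes, exons) {
  stopifnot(is.data.frame(genes), is.data.frame(exons))
  need <- c("gene_id", "chrom", "strand")
  if (!all(need %in% names(genes))) stop("genes: missing columns")
  if (!all(c(need, "start", "end") %in% names(exons))) stop("exons: missing columns")
  check_intervals(exons, "exon")
  if (is.null(genes$name)) genes$name <- genes$gene_id
  if (is.null(genes$biotype)) genes$biotype <- "coding"
  if (is.null(genes$cds_start)) genes$cds_start <- NA_integer_
  if (is.null(genes$cds_end)) genes$cds_end <- NA_integer_
  if (is.null(exons$transcript_id)) exons$transcript_id <- paste0(exons$gene_id, ".t1")

  ord <- order(exons$gene_id, exons$start)
  exons <- exons[ord, , drop = FALSE]
  by_gene <- split(seq_len(nrow(exons)), exons$gene_id)

  exons$ordinal <- NA_integer_
  intron_list <- vector("list", length(by_gene))
  for (i in seq_along(by_gene)) {
    idx <- by_gene[[i]]
    n <- length(idx)
    strand <- exons$strand[idx[1]]
    if (n > 1 && any(exons$start[idx][-1] < exons$end[idx][-n])) {
      stop("overlapping exons in gene ", exons$gene_id[idx[1]])
    }
    # genomic ascending; transcription order flips on the minus strand
    exons$ordinal[idx] <- if (strand == "+") seq_len(n) else rev(seq_len(n))
    intron_list[[i]] <- derive_introns(exons[idx, , drop = FALSE])
  }
  introns <- do.call(rbind, intron_list)
  rownames(introns) <- NULL

  span <- do.call(rbind, lapply(by_gene, function(idx) {
    data.frame(gene_id = exons$gene_id[idx[1]],
               start = min(exons$start[idx]),
               end = max(exons$end[idx]))
  }))
  genes$start <- span$start[match(genes$gene_id, span$gene_id)]
  genes$end <- span$end[match(genes$gene_id, span$gene_id)]
  if (anyNA(genes$start)) stop("gene(s) without exons: ",
                               paste(genes$gene_id[is.na(genes$start)], collapse = ", "))
  genes$length <- genes$end - genes$start
  rownames(genes) <- NULL
  rownames(exons) <- NULL

  structure(list(genes = genes, exons = exons, introns = introns),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes,",
      nrow(x$exons), "exons,", nrow(x$introns), "introns\n")
  cat("  chromosomes:", paste(sort(unique(x$genes$chrom)), collapse = ", "), "\n")
  cat("  biotypes:", paste(names(table(x$genes$biotype)),
                           table(x$genes$biotype), collapse = ", "), "\n")
  invisible(x)
}

#' Derive introns from the exons of one transcript
#'
#' Introns are the gaps between consecutive exons in genomic order. Each
#' intron is labelled with the transcription-order ordinal of the exon
#' immediately upstream (5') of it, so intron k separates transcription-order
#' exons k and k+1.
#'
#' @param exons data.frame of one transcript's exons (gene_id, chrom, strand,
#'   start, end); must be non-overlapping.
#' @return data.frame with gene_id, chrom, strand, start, end,
#'   upstream_exon_ordinal; zero rows for single-exon transcripts.
#' @export
derive_introns <- function(exons) {
  check_intervals(exons, "exon")
  if (length(unique(exons$strand)) > 1) stop("exons from multiple strands")
  exons <- exons[order(exons$start), , drop = FALSE]
  n <- nrow(exons)
  empty <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer(),
                      upstream_exon_ordinal = integer())
  if (n < 2) return(empty)
  if (any(exons$start[-1] < exons$end[-n])) stop("overlapping exons")
  strand <- exons$strand[1]
  # gap i sits between genomic exons i and i+1; its transcriptionally
  # upstream exon is i on "+", and genomic exon i+1 (ordinal n-i) on "-"
  up_ord <- if (strand == "+") seq_len(n - 1L) else (n - seq_len(n - 1L))
  data.frame(
    gene_id = exons$gene_id[1],
    chrom = exons$chrom[1],
    strand = strand,
    start = exons$end[-n],
    end = exons$start[-1],
    upstream_exon_ordinal = as.integer(up_ord)
  )
}

#' Read gene models from a GTF file
#'
#' Parses an Ensembl-dialect GTF (attributes gene_id/transcript_id; features
#' gene/transcript/exon and optionally CDS) into a \code{gene_annotation}.
#' GTF's 1-based inclusive coordinates are converted to the internal 0-based
#' half-open convention at this boundary. One representative transcript is
#' kept per gene: the one with the largest summed exon length, ties broken by
#' lexicographically smallest transcript_id. A gene is "coding" when its
#' representative transcript carries CDS features (or a gene_biotype
#' attribute says so).
#'
#' @param path path to a GTF file.
#' @return a \code{gene_annotation}.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF not found: ", path)
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9)) {
    stop("malformed GTF line ", which(body)[which(nf < 9)[1]], " in ", path)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,     # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type,
    gene_id = as.character(meta$gene_id),
    transcript_id = if ("transcript_id" %in% names(meta))
      as.character(meta$transcript_id) else NA_character_
  )

  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) stop("GTF contains no exon features")
  if (anyNA(ex$transcript_id)) stop("exon feature without transcript_id")

  # representative transcript per gene: longest summed exon length, then id
  exlen <- tapply(ex$end - ex$start, ex$transcript_id, sum)
  tx2gene <- ex$gene_id[match(names(exlen), ex$transcript_id)]
  pick <- vapply(split(seq_along(exlen), tx2gene), function(i) {
    i <- i[order(-exlen[i], names(exlen)[i])]
    names(exlen)[i[1]]
  }, character(1))
  ex <- ex[ex$transcript_id %in% pick, , drop = FALSE]

  gtab <- df[df$type == "gene", , drop = FALSE]
  if (nrow(gtab) == 0) {
    gtab <- unique(ex[, c("chrom", "strand", "gene_id")])
  }
  # exons must lie within the declared gene span
  gi <- match(ex$gene_id, gtab$gene_id)
  if ("start" %in% names(gtab) && nrow(df[df$type == "gene", ]) > 0) {
    bad <- ex$start < gtab$start[gi] | ex$end > gtab$end[gi]
    if (any(bad)) stop("exon outside gene span for gene ",
                       ex$gene_id[which(bad)[1]])
  }

  cds <- df[df$type == "CDS" & df$transcript_id %in% pick, , drop = FALSE]
  cds_start <- tapply(cds$start, cds$gene_id, min)
  cds_end <- tapply(cds$end, cds$gene_id, max)

  genes <- data.frame(
    gene_id = gtab$gene_id,
    name = if ("gene_name" %in% names(meta))
      as.character(meta$gene_name[match(gtab$gene_id, meta$gene_id)])
    else gtab$gene_id,
    chrom = gtab$chrom,
    strand = gtab$strand,
    biotype = ifelse(gtab$gene_id %in% names(cds_start), "coding", "noncoding"),
    cds_start = as.integer(cds_start[gtab$gene_id]),
    cds_end = as.integer(cds_end[gtab$gene_id])
  )
  if ("gene_biotype" %in% names(meta)) {
    bt <- as.character(meta$gene_biotype[match(genes$gene_id, meta$gene_id)])
    genes$biotype <- ifelse(!is.na(bt) & bt != "protein_coding" &
                              is.na(genes$cds_start), "noncoding", genes$biotype)
  }
  genes$name[is.na(genes$name)] <- genes$gene_id[is.na(genes$name)]
  gene_annotation(genes, ex[, c("gene_id", "transcript_id", "chrom",
                                "strand", "start", "end")])
}

#' Write a gene annotation to GTF
#'
#' Emits gene/transcript/exon (and CDS, where the gene is coding) features in
#' Ensembl dialect, converting the internal 0-based half-open coordinates back
#' to GTF's 1-based inclusive ones. \code{read_gtf(write_gtf(ann, f))}
#' round-trips coordinates, strands and ordinals.
#'
#' @param ann a \code{gene_annotation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "gene_annotation"))
  g <- ann$genes
  e <- ann$exons
  attr_gene <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                       g$gene_id, g$name,
                       ifelse(g$biotype == "coding", "protein_coding", "lncRNA"))
  tx_of <- tapply(e$transcript_id, e$gene_id, function(x) x[1])
  attr_tx <- sprintf('gene_id "%s"; transcript_id "%s";',
                     g$gene_id, tx_of[g$gene_id])
  lines <- c(
    sprintf("%s\tcircbalance\tgene\t%d\t%d\t.\t%s\t.\t%s",
            g$chrom, g$start + 1L, g$end, g$strand, attr_gene),
    sprintf("%s\tcircbalance\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
            g$chrom, g$start + 1L, g$end, g$strand, attr_tx),
    sprintf("%s\tcircbalance\texon\t%d\t%d\t.\t%s\t.\t%s",
            e$chrom, e$start + 1L, e$end, e$strand,
            sprintf('gene_id "%s"; transcript_id "%s"; exon_number "%d";',
                    e$gene_id, e$transcript_id, e$ordinal))
  )
  # CDS: per-exon intersection with the gene's CDS span
  coding <- g[g$biotype == "coding" & !is.na(g$cds_start), , drop = FALSE]
  if (nrow(coding) > 0) {
    ce <- e[e$gene_id %in% coding$gene_id, , drop = FALSE]
    gi <- match(ce$gene_id, coding$gene_id)
    cs <- pmax(ce$start, coding$cds_start[gi])
    cn <- pmin(ce$end, coding$cds_end[gi])
    keep <- cn > cs
    if (any(keep)) {
      lines <- c(lines, sprintf(
        "%s\tcircbalance\tCDS\t%d\t%d\t.\t%s\t0\t%s",
        ce$chrom[keep], cs[keep] + 1L, cn[keep], ce$strand[keep],
        sprintf('gene_id "%s"; transcript_id "%s";',
                ce$gene_id[keep], ce$transcript_id[keep])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read binding sites from a BED6+2 file
#'
#' BED columns: chrom, start, end, name (site_id), score, strand, plus two
#' extra columns \code{reads} (integer crosslink read count) and
#' \code{p_value}. BED is already 0-based half-open, so coordinates are taken
#' as-is.
#'
#' @param path path to the BED6+2 file.
#' @return data.frame with site_id, chrom, start, end, strand, reads, p_value.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("sites BED not found: ", path)
  gr <- rtracklayer::import(path, format = "BED",
                            extraCols = c(reads = "integer", p_value = "numeric"))
  df <- data.frame(
    site_id = if (!is.null(gr$name)) as.character(gr$name)
              else sprintf("site_%06d", seq_along(gr)),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    reads = gr$reads,
    p_value = gr$p_value
  )
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  validate_sites(df)
}

#' Write binding sites as BED6+2
#' @param sites data.frame as returned by \code{read_sites}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_sites <- function(sites, path) {
  validate_sites(sites)
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%g",
                   sites$chrom, sites$start, sites$end, sites$site_id,
                   sites$strand, sites$reads, sites$p_value)
  writeLines(lines, path)
  invisible(path)
}

validate_sites <- function(sites) {
  check_intervals(sites, "binding site")
  if (any(sites$reads < 0)) stop("binding site with negative read count")
  if (anyNA(sites$p_value) || any(sites$p_value < 0 | sites$p_value > 1)) {
    stop("binding site p-values must lie in [0, 1]")
  }
  sites
}

#' Read a circRNA (BSJ) count table
#'
#' TSV dialect: columns circ_id, chrom, start, end, strand, gene_id followed
#' by one \code{count_<sample>} column per library.
#' @param path TSV path.
#' @return data.frame; sample count columns keep the \code{count_} prefix.
#' @export
read_circ_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("circ_id", "chrom", "start", "end", "strand", "gene_id")
  if (!all(need %in% names(df))) stop("circ table missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  check_intervals(df, "circRNA")
  df
}

#' Extract the sample count matrix from a count table
#' @param df a table read by \code{read_circ_table} (or any data.frame with
#'   \code{count_<sample>} columns) with an id column.
#' @param id_col column holding row identifiers.
#' @return integer matrix, rows named by id, columns by sample.
#' @export
count_matrix <- function(df, id_col = "circ_id") {
  cc <- grep("^count_", names(df), value = TRUE)
  if (length(cc) == 0) stop("no count_<sample> columns found")
  m <- as.matrix(df[, cc, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[id_col]]
  colnames(m) <- sub("^count_", "", cc)
  if (any(m < 0)) stop("negative counts")
  m
}

#' Write a TSV with the package's conventions (tab, no quotes, no rownames)
#' @param df data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
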