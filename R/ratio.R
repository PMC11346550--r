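#' circRNA:mRNA ratio
#'
#' \code{(circ + pc) / (mrna + pc)} on normalized (RPM) values; genes with
#' several circRNAs use the summed circRNA RPM. The pseudocount keeps the
#' ratio finite at zero mRNA and returns 1 for the fully degenerate 0/0
#' case.
#'
#' @param circ_norm,mrna_norm non-negative numeric vectors.
#' @param pseudocount default 0.5, shared with \code{de_config}.
#' @return numeric vector of ratios.
#' @export
circ_mrna_ratio <- function(circ_norm, mrna_norm, pseudocount = 0.5) {
  if (any(circ_norm < 0) || any(mrna_norm < 0)) stop("negative normalized values")
  (circ_norm + pseudocount) / (mrna_norm + pseudocount)
}

#' Classify the KO/WT shift of the circRNA:mRNA ratio
#'
#' \code{ratio_fc = ratio_ko / ratio_wt}; the label is \code{increased} when
#' the fold change is > 2, \code{decreased} when < 1 and \code{unchanged}
#' when in [1, 2] — the printed inequalities taken literally, so fc = 2 is
#' unchanged and fc = 1 is unchanged.
#'
#' @param ratio_wt,ratio_ko positive numeric vectors.
#' @return data.frame with ratio_fc and label.
#' @export
classify_ratio_fc <- function(ratio_wt, ratio_ko) {
  if (any(ratio_wt <= 0) || any(ratio_ko <= 0)) stop("ratios must be positive")
  fc <- ratio_ko / ratio_wt
  label <- ifelse(fc > 2, "increased", ifelse(fc < 1, "decreased", "unchanged"))
  data.frame(ratio_fc = fc, label = label,
             row.names = names(ratio_wt), stringsAsFactors = FALSE)
}

#' Per-gene circRNA:mRNA ratio records
#'
#' Builds the full per-gene record: both conditions' normalized circRNA and
#' mRNA levels, their ratios, the KO/WT ratio fold change and its class.
#' Replicates should be averaged before calling.
#'
#' @param gene_id character vector.
#' @param circ_wt,circ_ko,mrna_wt,mrna_ko numeric RPM vectors aligned with
#'   \code{gene_id} (circ values already summed over the gene's circRNAs).
#' @param pseudocount shared pseudocount.
#' @return data.frame, one row per gene.
#' @export
ratio_records <- function(gene_id, circ_wt, circ_ko, mrna_wt, mrna_ko,
                          pseudocount = 0.5) {
  rw <- circ_mrna_ratio(circ_wt, mrna_wt, pseudocount)
  rk <- circ_mrna_ratio(circ_ko, mrna_ko, pseudocount)
  cl <- classify_ratio_fc(rw, rk)
  data.frame(gene_id = gene_id,
             circ_norm_wt = circ_wt, mrna_norm_wt = mrna_wt,
             circ_norm_ko = circ_ko, mrna_norm_ko = mrna_ko,
             ratio_wt = rw, ratio_ko = rk,
             ratio_fc = cl$ratio_fc, label = cl$label,
             stringsAsFactors = FALSE)
}

#' Row-wise Z-score normalization
#'
#' Centers and scales each row to mean 0 and (sample, n-1 denominator)
#' standard deviation 1, the normalization used for expression heatmaps.
#'
#' @param mat numeric matrix; every row must have positive variance.
#' @return matrix of the same shape.
#' @export
zscore_rows <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)[1]
    stop("zero-variance row: ",
         if (!is.null(rownames(mat))) rownames(mat)[bad] else bad)
  }
  t(scale(t(mat)))[, , drop = FALSE]
}
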