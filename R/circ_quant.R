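#' Differential-expression configuration for circRNA fold-change calls
#'
#' The defaults mirror the study design for steady-state BSJ libraries:
#' circRNAs need at least 2 BSJ reads to count as detected, a KO/WT fold
#' change >= 2 is called up and <= 0.5 down (both boundaries inclusive), and
#' a pseudocount of 0.5 RPM guards zero denominators.
#'
#' @param min_bsj_reads detection threshold on raw BSJ reads.
#' @param fc_up,fc_down inclusive fold-change boundaries for up/down calls.
#' @param pseudocount added to both conditions before the ratio.
#' @return a list of class \code{de_config}.
#' @export
de_config <- function(min_bsj_reads = 2, fc_up = 2, fc_down = 0.5,
                      pseudocount = 0.5) {
  stopifnot(fc_up > 1, fc_down < 1, fc_down > 0, min_bsj_reads >= 1,
            pseudocount >= 0)
  structure(list(min_bsj_reads = min_bsj_reads, fc_up = fc_up,
                 fc_down = fc_down, pseudocount = pseudocount),
            class = "de_config")
}

#' Reads-per-million normalization
#'
#' \code{rpm = count / library_size * 1e6}, the library-size correction used
#' for every count table in the pipeline. Library sizes are total mapped
#' reads per sample, not column sums of the (sparse) feature table.
#'
#' @param counts numeric matrix (features x samples) or vector.
#' @param library_sizes numeric vector of totals; when \code{counts} is a
#'   matrix it is matched to columns by name if named.
#' @return object of the same shape as \code{counts}, in RPM.
#' @export
normalize_rpm <- function(counts, library_sizes) {
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (is.matrix(counts)) {
    ls <- if (!is.null(names(library_sizes)) && !is.null(colnames(counts))) {
      if (!all(colnames(counts) %in% names(library_sizes))) {
        stop("library size missing for sample(s): ",
             paste(setdiff(colnames(counts), names(library_sizes)), collapse = ", "))
      }
      library_sizes[colnames(counts)]
    } else {
      if (length(library_sizes) != ncol(counts)) stop("library size length mismatch")
      library_sizes
    }
    sweep(counts, 2, ls, "/") * 1e6
  } else {
    counts / library_sizes * 1e6
  }
}

#' Detected circRNA set for one sample
#'
#' A circRNA is detected when its raw BSJ read count reaches
#' \code{min_reads} (default 2, inclusive) in the sample.
#'
#' @param counts matrix from \code{count_matrix} (rows = circ_id).
#' @param sample column name.
#' @param min_reads inclusive detection threshold.
#' @return character vector of detected circ_ids.
#' @export
detected_set <- function(counts, sample, min_reads = 2) {
  if (!sample %in% colnames(counts)) stop("unknown sample: ", sample)
  rownames(counts)[counts[, sample] >= min_reads]
}

#' Overlap of two detected sets
#'
#' Splits WT- and KO-detected circRNAs into shared / WT-only / KO-only, the
#' partition behind a two-set Venn diagram.
#'
#' @param wt,ko character vectors of ids.
#' @return list with \code{shared}, \code{wt_only}, \code{ko_only}.
#' @export
overlap_sets <- function(wt, ko) {
  wt <- unique(wt); ko <- unique(ko)
  list(shared = intersect(wt, ko),
       wt_only = setdiff(wt, ko),
       ko_only = setdiff(ko, wt))
}

#' Fold-change classification of circRNAs
#'
#' For each circRNA, \code{fold_change = (ko + pc) / (wt + pc)} on
#' replicate-averaged RPM values; the label is \code{up} when the fold change
#' is >= \code{fc_up}, \code{down} when <= \code{fc_down}, otherwise
#' \code{unchanged}. Both boundaries are inclusive. \code{mean_expr} is the
#' log2 of the cross-condition mean RPM (the MA-plot abscissa) and
#' \code{log2fc} its ordinate.
#'
#' @param norm_wt,norm_ko named numeric vectors of RPM values (replicates
#'   already averaged), same ids in both.
#' @param config a \code{de_config}.
#' @return data.frame with circ_id, norm_wt, norm_ko, fold_change, log2fc,
#'   mean_expr, label.
#' @export
classify_de <- function(norm_wt, norm_ko, config = de_config()) {
  if (any(norm_wt < 0) || any(norm_ko < 0)) stop("negative normalized values")
  ids <- names(norm_wt)
  if (is.null(ids)) ids <- as.character(seq_along(norm_wt))
  if (!is.null(names(norm_ko))) {
    if (!setequal(ids, names(norm_ko))) stop("WT/KO id sets differ")
    norm_ko <- norm_ko[ids]
  }
  pc <- config$pseudocount
  fc <- (norm_ko + pc) / (norm_wt + pc)
  label <- ifelse(fc >= config$fc_up, "up",
                  ifelse(fc <= config$fc_down, "down", "unchanged"))
  data.frame(
    circ_id = ids,
    norm_wt = unname(norm_wt),
    norm_ko = unname(norm_ko),
    fold_change = unname(fc),
    log2fc = unname(log2(fc)),
    mean_expr = unname(log2((norm_wt + norm_ko) / 2 + pc)),
    label = label,
    stringsAsFactors = FALSE
  )
}

#' Summary of a fold-change classification
#'
#' Counts of up/down calls and their percentages of all differentially
#' expressed circRNAs, rounded to one decimal. With no DE circRNAs the
#' percentages are undefined (NA), not zero.
#'
#' @param results data.frame from \code{classify_de}.
#' @return list with n_tested, n_de, n_up, n_down, pct_up, pct_down.
#' @export
summarize_de <- function(results) {
  stopifnot(is.data.frame(results), "label" %in% names(results))
  n_up <- sum(results$label == "up")
  n_down <- sum(results$label == "down")
  n_de <- n_up + n_down
  list(n_tested = nrow(results),
       n_de = n_de,
       n_up = n_up,
       n_down = n_down,
       pct_up = if (n_de > 0) round(100 * n_up / n_de, 1) else NA_real_,
       pct_down = if (n_de > 0) round(100 * n_down / n_de, 1) else NA_real_)
}

#' Cumulative fraction curve
#'
#' The empirical CDF evaluated at the sorted unique values: a non-decreasing
#' step function ending at 1, as plotted in cumulative-fraction comparisons
#' of expression levels.
#'
#' @param values finite numeric vector.
#' @return data.frame with \code{value} and \code{fraction} (P(X <= value)).
#' @export
cumulative_fraction <- function(values) {
  if (length(values) == 0) stop("empty input")
  if (any(!is.finite(values))) stop("non-finite values")
  x <- sort(unique(values))
  data.frame(value = x, fraction = stats::ecdf(values)(x))
}
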