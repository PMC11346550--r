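#' Nascent differential configuration
#'
#' Nascent libraries are shallower than steady-state ones, so the up-call
#' uses a single, lower boundary: fold change >= 1.4 (inclusive) is "up",
#' everything else "non-up".
#'
#' @param fc_up_nascent inclusive up boundary (> 1).
#' @return list of class \code{nascent_de_config}.
#' @export
nascent_de_config <- function(fc_up_nascent = 1.4) {
  stopifnot(fc_up_nascent > 1)
  structure(list(fc_up_nascent = fc_up_nascent), class = "nascent_de_config")
}

#' Per-gene nascent circRNA fraction
#'
#' The fraction of a gene's nascent reads that are backsplice-junction reads:
#' sum of the gene's nascent BSJ counts divided by all nascent reads assigned
#' to the gene (linear + BSJ). Genes with zero total nascent reads are
#' undefined and returned as NA (with a message), never as 0.
#'
#' @param circ_reads numeric vector of summed nascent BSJ reads per gene.
#' @param total_reads numeric vector of total nascent reads per gene.
#' @return numeric vector of fractions in [0, 1] (NA where total is 0).
#' @export
nascent_circ_fraction <- function(circ_reads, total_reads) {
  if (any(circ_reads < 0) || any(total_reads < 0)) stop("negative read counts")
  if (any(circ_reads > total_reads, na.rm = TRUE)) {
    stop("circ reads exceed the gene's total nascent reads")
  }
  zero <- total_reads == 0
  if (any(zero)) {
    message(sum(zero), " gene(s) with zero nascent total excluded (fraction undefined)")
  }
  frac <- ifelse(zero, NA_real_, circ_reads / total_reads)
  names(frac) <- names(total_reads)
  frac
}

#' Compare nascent circRNA fractions between conditions
#'
#' Restricts to genes present (finite fraction) in both conditions and runs a
#' two-tailed paired t-test on the per-gene fraction pairs. The pairing
#' reflects the design: both conditions measure the same genes, whose
#' backsplicing propensities differ far more between genes than between
#' conditions, so an unpaired test would be drastically conservative. Genes
#' must show both linear splicing and backsplicing to carry a defined
#' fraction. Degenerate difference vectors (all zero, or constant) are
#' handled as the limiting p-values 1 and 0.
#'
#' @param wt_fracs,ko_fracs named numeric vectors of per-gene fractions.
#' @param min_genes minimum shared genes required (default 3).
#' @return list with p_value, mean_wt, mean_ko, mean_diff (KO - WT), n,
#'   method, and the \code{pairs} data.frame.
#' @export
compare_fractions <- function(wt_fracs, ko_fracs, min_genes = 3) {
  if (is.null(names(wt_fracs)) || is.null(names(ko_fracs))) {
    stop("fraction vectors must be named by gene")
  }
  shared <- intersect(names(wt_fracs)[is.finite(wt_fracs)],
                      names(ko_fracs)[is.finite(ko_fracs)])
  if (length(shared) < min_genes) {
    stop("fewer than ", min_genes, " genes shared between conditions")
  }
  w <- wt_fracs[shared]; k <- ko_fracs[shared]
  d <- k - w
  limit_p <- function() if (isTRUE(all.equal(mean(d), 0))) 1 else 0
  p <- if (stats::sd(d) == 0) {
    limit_p()
  } else {
    # t.test refuses essentially-constant differences; use the limiting p
    tryCatch(stats::t.test(k, w, paired = TRUE,
                           alternative = "two.sided")$p.value,
             error = function(e) limit_p())
  }
  list(
    p_value = p,
    mean_wt = mean(w),
    mean_ko = mean(k),
    mean_diff = mean(k) - mean(w),
    n = length(shared),
    method = "two-tailed paired t-test",
    pairs = data.frame(gene_id = shared, frac_wt = unname(w),
                       frac_ko = unname(k))
  )
}

#' Two-class nascent up-call
#'
#' Labels each fold change \code{up} when >= the nascent boundary (1.4 by
#' default, inclusive) and \code{non-up} otherwise; decreased and unaltered
#' circRNAs share the non-up class.
#'
#' @param fc numeric vector of nascent KO/WT fold changes (computed as in
#'   \code{classify_de}).
#' @param config a \code{nascent_de_config}.
#' @return character vector of "up"/"non-up", names kept from \code{fc}.
#' @export
classify_nascent_up <- function(fc, config = nascent_de_config()) {
  out <- ifelse(fc >= config$fc_up_nascent, "up", "non-up")
  names(out) <- names(fc)
  out
}
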