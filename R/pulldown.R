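# Biotinylated pull-down enrichment-ratio analysis.
#
# The central statistic is the per-gene enrichment ratio
#   ER = (bait_pd / ctrl_pd) / (bait_input / ctrl_input)
# computed on abundance (FPKM/CPM) tables, with an expression filter
# (abundance > 0.1 in at least one library), a candidate call at ER above
# 1.2 (strict), and a potential-target definition combining enrichment
# with depletion upon miRNA overexpression. Distributional shifts of the
# target set are assessed with the Kolmogorov-Smirnov test on CDFs.

#' Drop genes not expressed in any library
#'
#' Retains exactly the genes whose abundance exceeds \code{min_level} in at
#' least one library column; everything else is considered not expressed.
#' Idempotent.
#'
#' @param table data frame with a \code{gene_id} column and one numeric
#'   column per library.
#' @param min_level expression floor (default 0.1, the usual FPKM cutoff).
#' @return the filtered table (a subset of the input rows).
#' @export
filter_expressed <- function(table, min_level = 0.1) {
  if (min_level < 0) stop_mirarm("min_level must be non-negative")
  if (nrow(table) == 0) stop_mirarm("empty expression table")
  num <- vapply(table, is.numeric, TRUE)
  if (!any(num)) stop_mirarm("no abundance columns found")
  keep <- apply(table[, num, drop = FALSE], 1, function(v) any(v > min_level))
  table[keep, , drop = FALSE]
}

#' Per-gene pull-down enrichment ratio
#'
#' \code{ER = ((bait_pd + eps) / (ctrl_pd + eps)) /
#' ((bait_input + eps) / (ctrl_input + eps))}. The pseudocount guards
#' against zero abundances; with \code{pseudocount = 0} all control and
#' input values must be positive. Genes with ER strictly above
#' \code{er_cutoff} are flagged as candidates.
#'
#' @param abundance data frame with columns gene_id, bait_pd, ctrl_pd,
#'   bait_input, ctrl_input (additional columns are carried along).
#' @param pseudocount abundance pseudocount (default 0.01).
#' @param er_cutoff candidate threshold (default 1.2, strict inequality).
#' @return data frame: gene_id, er, candidate.
#' @export
enrichment_ratio <- function(abundance, pseudocount = 0.01, er_cutoff = 1.2) {
  need <- c("gene_id", "bait_pd", "ctrl_pd", "bait_input", "ctrl_input")
  if (!all(need %in% names(abundance)))
    stop_mirarm("abundance table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(abundance$gene_id))
    stop_mirarm("duplicated gene ids")
  vals <- abundance[, need[-1]]
  if (any(vals < 0)) stop_mirarm("abundances must be non-negative")
  if (pseudocount < 0) stop_mirarm("pseudocount must be non-negative")
  if (pseudocount == 0 &&
      any(vals$ctrl_pd == 0 | vals$bait_input == 0 | vals$ctrl_input == 0))
    stop_mirarm("zero denominators require a positive pseudocount")
  e <- pseudocount
  er <- ((vals$bait_pd + e) / (vals$ctrl_pd + e)) /
    ((vals$bait_input + e) / (vals$ctrl_input + e))
  data.frame(gene_id = abundance$gene_id, er = er,
             candidate = er > er_cutoff, stringsAsFactors = FALSE)
}

#' Overexpression log2 fold changes and differential-expression flags
#'
#' \code{log2fc_table} computes \code{log2((oe + pseudo) / (ctrl + pseudo))}
#' per gene. \code{flag_de} applies the candidate rule
#' \code{|log2FC| > lfc_cutoff & FDR < fdr_cutoff}. When no FDR column is
#' supplied, a simple two-sided conditional binomial test on the rounded
#' per-gene counts (each gene's oe count against the oe + control total)
#' with Benjamini-Hochberg adjustment serves as a stand-in; it is a generic
#' count-model test, not a reimplementation of any particular
#' differential-expression tool.
#'
#' @param oe,ctrl numeric abundance vectors (paired by gene).
#' @param pseudo pseudocount (default 1).
#' @param gene_id optional gene ids carried into the output.
#' @return \code{log2fc_table}: data frame gene_id, oe, ctrl, log2fc.
#' @export
log2fc_table <- function(oe, ctrl, pseudo = 1, gene_id = NULL) {
  if (length(oe) != length(ctrl)) stop_mirarm("oe and ctrl must be paired")
  if (any(oe < 0) || any(ctrl < 0)) stop_mirarm("abundances must be non-negative")
  data.frame(gene_id = gene_id %||% seq_along(oe),
             oe = oe, ctrl = ctrl,
             log2fc = log2((oe + pseudo) / (ctrl + pseudo)),
             stringsAsFactors = FALSE)
}

#' @rdname log2fc_table
#' @param lfc data frame from \code{log2fc_table}.
#' @param fdr optional per-gene FDR values (e.g. from an external DE run).
#' @param lfc_cutoff,fdr_cutoff thresholds; both strict on the fold-change
#'   side (\code{|log2FC| > lfc_cutoff}).
#' @return \code{flag_de}: the input with columns fdr and de_flag added.
#' @export
flag_de <- function(lfc, fdr = NULL, lfc_cutoff = 1, fdr_cutoff = 0.001) {
  if (is.null(fdr)) {
    x <- round(lfc$oe); n <- round(lfc$oe) + round(lfc$ctrl)
    p <- vapply(seq_along(x), function(i) {
      if (n[i] == 0) return(1)
      stats::binom.test(x[i], n[i], p = 0.5)$p.value
    }, 1.0)
    fdr <- p.adjust(p, method = "BH")
  }
  lfc$fdr <- fdr
  lfc$de_flag <- abs(lfc$log2fc) > lfc_cutoff & lfc$fdr < fdr_cutoff
  lfc
}

#' Define potential targets from enrichment and depletion
#'
#' A potential target is a pull-down candidate (ER above the cutoff) whose
#' expression decreases upon miRNA overexpression (log2FC < 0). With
#' \code{require_de = TRUE} the stricter gate additionally requires the
#' differential-expression flag with negative sign.
#'
#' @param records data frame containing er, candidate and log2fc columns
#'   (merge of \code{\link{enrichment_ratio}} and
#'   \code{\link{log2fc_table}} output), optionally de_flag.
#' @param require_de use the strict DE gate.
#' @return the input with a logical \code{potential_target} column.
#' @export
define_potential_targets <- function(records, require_de = FALSE) {
  need <- c("candidate", "log2fc")
  if (!all(need %in% names(records)))
    stop_mirarm("records need columns: ", paste(need, collapse = ", "))
  pt <- records$candidate & records$log2fc < 0
  if (require_de) {
    if (!"de_flag" %in% names(records))
      stop_mirarm("require_de = TRUE needs a de_flag column")
    pt <- pt & records$de_flag
  }
  records$potential_target <- pt
  records
}

#' Kolmogorov-Smirnov CDF-shift test between a target set and background
#'
#' @param target,background numeric vectors (at least 5 values each).
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"}, as in \code{stats::ks.test} with the target sample
#'   first.
#' @return list of class \code{cdf_comparison}: statistic D, p_value,
#'   direction (sign of the median difference target - background), sample
#'   sizes.
#' @export
cdf_shift_test <- function(target, background,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(target) < 5 || length(background) < 5)
    stop_mirarm("both samples need at least 5 values")
  kt <- suppressWarnings(ks.test(target, background,
                                 alternative = alternative))
  structure(list(statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value),
                 direction = sign(median(target) - median(background)),
                 n_target = length(target), n_background = length(background),
                 alternative = alternative),
            class = "cdf_comparison")
}

#' @export
print.cdf_comparison <- function(x, ...) {
  cat(sprintf("<cdf_comparison> D = %.4f, p = %.3g, shift %s (n = %d vs %d)\n",
              x$statistic, x$p_value,
              c("down", "none", "up")[x$direction + 2],
              x$n_target, x$n_background))
  invisible(x)
}

#' Sweep the enrichment-ratio cutoff
#'
#' For each cutoff (ascending) returns the candidate set at that cutoff,
#' its size, median log2 fold change, and the CDF-shift test of the set's
#' fold changes against all genes. Higher cutoffs give nested subsets.
#'
#' @param records data frame with gene_id, er and log2fc columns.
#' @param cutoffs ascending numeric vector of ER cutoffs.
#' @return list with \code{summary} (data frame: cutoff, n, median_log2fc,
#'   ks_d, ks_p) and \code{sets} (list of gene-id vectors per cutoff).
#' @export
cutoff_sweep <- function(records, cutoffs = c(1.2, 2, 3)) {
  if (is.unsorted(cutoffs)) stop_mirarm("cutoffs must be ascending")
  sets <- lapply(cutoffs, function(co) records$gene_id[records$er > co])
  names(sets) <- as.character(cutoffs)
  summ <- lapply(seq_along(cutoffs), function(i) {
    sel <- records$er > cutoffs[i]
    ks <- if (sum(sel) >= 5 && sum(!sel) >= 5)
      cdf_shift_test(records$log2fc[sel], records$log2fc)
    else list(statistic = NA_real_, p_value = NA_real_)
    data.frame(cutoff = cutoffs[i], n = sum(sel),
               median_log2fc = if (any(sel)) median(records$log2fc[sel])
                               else NA_real_,
               ks_d = ks$statistic, ks_p = ks$p_value)
  })
  list(summary = do.call(rbind, summ), sets = sets)
}
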