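# qPCR quantification: relative (2^-ddCt) and absolute (standard curve).

#' Relative expression by the 2^-ddCt method
#'
#' For each sample, replicate Ct values are summarized by the median, then
#' \code{dCt = Ct(target) - Ct(reference)} within each condition,
#' \code{ddCt = dCt(case) - dCt(calibrator)} and
#' \code{ratio = 2^-ddCt}. A ratio below \code{low_threshold} is called
#' \code{"low"}, anything else (including exactly the threshold) is
#' \code{"high"}.
#'
#' @param ct data frame with columns sample, gene, condition, ct (one row
#'   per replicate well).
#' @param target,reference gene ids; the reference (e.g. U6) must be
#'   measured in both conditions.
#' @param case,calibrator condition labels, by default tumor vs normal.
#' @param low_threshold ratio below which expression is called low.
#' @return data frame with one row per sample: sample, gene, dCt for both
#'   conditions, delta_delta_ct, ratio, call.
#' @export
#' @examples
#' ct <- data.frame(sample = "s1",
#'                  gene = rep(c("miR", "U6"), each = 2),
#'                  condition = rep(c("tumor", "normal"), 2),
#'                  ct = c(20, 22, 15, 15))
#' ddct_relative_expression(ct, "miR", "U6")  # ddCt = -2, ratio = 4
ddct_relative_expression <- function(ct, target, reference,
                                     case = "tumor", calibrator = "normal",
                                     low_threshold = 1.0) {
  need <- c("sample", "gene", "condition", "ct")
  if (!all(need %in% names(ct)))
    stop_mirarm("ct table needs columns: ", paste(need, collapse = ", "))
  if (!reference %in% ct$gene)
    stop_mirarm("reference gene '", reference, "' not present in Ct table")
  if (!target %in% ct$gene)
    stop_mirarm("target gene '", target, "' not present in Ct table")
  if (any(ct$ct <= 0 | ct$ct >= 50))
    stop_mirarm("Ct values must lie in (0, 50)")
  med <- stats::aggregate(ct ~ sample + gene + condition,
                          data = ct[ct$gene %in% c(target, reference), ],
                          FUN = median)
  samples <- unique(med$sample)
  pick <- function(s, g, cond) {
    v <- med$ct[med$sample == s & med$gene == g & med$condition == cond]
    if (length(v) != 1) NA_real_ else v
  }
  out <- lapply(samples, function(s) {
    d_case <- pick(s, target, case) - pick(s, reference, case)
    d_cal <- pick(s, target, calibrator) - pick(s, reference, calibrator)
    dd <- d_case - d_cal
    data.frame(sample = s, gene = target,
               delta_ct_case = d_case, delta_ct_calibrator = d_cal,
               delta_delta_ct = dd, ratio = 2^(-dd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[complete.cases(out), , drop = FALSE]
  if (nrow(out) == 0)
    stop_mirarm("no sample had ", target, " and ", reference,
                " measured in both conditions")
  out$call <- ifelse(out$ratio < low_threshold, "low", "high")
  out
}

#' Absolute copy number from nucleic-acid mass
#'
#' Applies \code{copies = 6.02e23 * amount / (length * 308.95 * 2)} for
#' double-stranded input (average molar mass 308.95 g/mol per nucleotide,
#' factor 2 for two strands); single-stranded input drops the factor 2.
#'
#' @param amount_g mass in grams.
#' @param length_bp length in base pairs (nucleotides when
#'   single-stranded).
#' @param strandedness \code{"double"} or \code{"single"}.
#' @return copy number (numeric).
#' @export
#' @examples
#' copy_number_from_mass(1e-6, 1000)  # ~9.743e11 copies per ug of 1-kb dsDNA
copy_number_from_mass <- function(amount_g, length_bp,
                                  strandedness = c("double", "single")) {
  strandedness <- match.arg(strandedness)
  if (any(length_bp <= 0)) stop_mirarm("length must be positive")
  if (any(amount_g < 0)) stop_mirarm("amount must be non-negative")
  strands <- if (strandedness == "double") 2 else 1
  6.02e23 * amount_g / (length_bp * 308.95 * strands)
}

#' Fit a qPCR standard curve and quantify absolutely
#'
#' Fits the least-squares line of Ct on log10(copies) over a dilution
#' series (at least 3 distinct points spanning at least 2 log10 units).
#' Amplification efficiency is \code{10^(-1/slope) - 1}, i.e. 1.0 for the
#' theoretical slope of -log2(10) = -3.3219 cycles per decade.
#' \code{absolute_quantify} inverts the fitted line to convert observed Ct
#' values into copy numbers.
#'
#' @param copies,ct numeric vectors: known template copies and measured Ct
#'   for each dilution point.
#' @return \code{fit_standard_curve}: object of class
#'   \code{standard_curve} with slope, intercept, r_squared, efficiency.
#' @export
fit_standard_curve <- function(copies, ct) {
  if (length(copies) != length(ct))
    stop_mirarm("copies and ct must have equal length")
  x <- log10(copies)
  if (length(unique(x)) < 3)
    stop_mirarm("need at least 3 distinct dilution points")
  if (diff(range(x)) < 2)
    stop_mirarm("dilution series must span at least 2 log10 units")
  fit <- lm(ct ~ x)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 points = data.frame(copies = copies, ct = ct)),
            class = "standard_curve")
}

#' @rdname fit_standard_curve
#' @param ct_values Ct values to convert to copies.
#' @param curve a fitted \code{standard_curve}.
#' @export
absolute_quantify <- function(ct_values, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct_values - curve$intercept) / curve$slope)
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> slope %.4f, intercept %.3f, R^2 %.4f, efficiency %.3f\n",
              x$slope, x$intercept, x$r_squared, x$efficiency))
  invisible(x)
}
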