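# Arm-pair trend classification across paired tumor/normal cohorts.

#' Classify the tumor/normal trend of one 5p/3p arm pair
#'
#' Each arm's direction is called from its paired tumor/normal log2 ratios:
#' \code{up} (or \code{down}) when the two-sided paired Wilcoxon signed-rank
#' test rejects at \code{alpha} and the median log2 ratio exceeds
#' \code{min_abs_log2fc} in magnitude; \code{unchanged} otherwise. The pair
#' trend follows: \code{same} when both arms move in the same direction,
#' \code{opposite} when they move in different directions, \code{single}
#' when exactly one moves, \code{none} when neither does.
#'
#' @param pair data frame for one precursor with columns arm
#'   (\code{"5p"}/\code{"3p"}), normal, tumor (paired per patient).
#' @param alpha significance level of the per-arm signed-rank gate.
#' @param min_abs_log2fc minimum absolute median log2 tumor/normal ratio
#'   for an arm to be called moved (an effect-size gate alongside the
#'   test, as in standard differential-expression calling).
#' @return list with \code{trend}, per-arm \code{direction}, median log2
#'   ratios and p-values.
#' @export
classify_arm_trend <- function(pair, alpha = 0.05, min_abs_log2fc = 1) {
  if (!all(c("arm", "normal", "tumor") %in% names(pair)))
    stop_mirarm("pair needs columns arm, normal, tumor")
  arm_dir <- function(arm) {
    d <- pair[pair$arm == arm, , drop = FALSE]
    if (nrow(d) < 3) stop_mirarm("need >= 3 paired samples per arm")
    if (any(!is.finite(d$normal)) || any(!is.finite(d$tumor)) ||
        length(d$normal) != length(d$tumor))
      stop_mirarm("unequal or non-finite tumor/normal pairing")
    lr <- log2(d$tumor / d$normal)
    p <- suppressWarnings(wilcox.test(lr, mu = 0, exact = FALSE)$p.value)
    m <- median(lr)
    dir <- if (p < alpha && abs(m) > min_abs_log2fc)
      if (m > 0) "up" else "down" else "unchanged"
    list(direction = dir, median_log2fc = m, p = p)
  }
  a5 <- arm_dir("5p"); a3 <- arm_dir("3p")
  moved <- c(a5$direction, a3$direction) != "unchanged"
  trend <- if (all(moved)) {
    if (a5$direction == a3$direction) "same" else "opposite"
  } else if (any(moved)) "single" else "none"
  list(trend = trend,
       direction_5p = a5$direction, direction_3p = a3$direction,
       median_log2fc_5p = a5$median_log2fc, median_log2fc_3p = a3$median_log2fc,
       p_5p = a5$p, p_3p = a3$p)
}

#' Classify every arm pair in a cohort table
#'
#' @param cohort long data frame as produced by \code{\link{gen_cohort}}
#'   (columns precursor_id, arm, normal, tumor).
#' @inheritParams classify_arm_trend
#' @return data frame with one row per precursor: trend, per-arm
#'   directions, median log2 fold changes and p-values.
#' @export
classify_cohort_trends <- function(cohort, alpha = 0.05, min_abs_log2fc = 1) {
  ids <- unique(cohort$precursor_id)
  out <- lapply(ids, function(id) {
    r <- classify_arm_trend(cohort[cohort$precursor_id == id, , drop = FALSE],
                            alpha = alpha, min_abs_log2fc = min_abs_log2fc)
    data.frame(precursor_id = id, trend = r$trend,
               direction_5p = r$direction_5p, direction_3p = r$direction_3p,
               median_log2fc_5p = r$median_log2fc_5p,
               median_log2fc_3p = r$median_log2fc_3p,
               p_5p = r$p_5p, p_3p = r$p_3p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize trend classes over a set of arm pairs
#'
#' @param trends data frame with a \code{trend} column (output of
#'   \code{\link{classify_cohort_trends}}) or a character vector of trend
#'   labels.
#' @return data frame: trend, count, proportion (proportions sum to 1).
#' @export
arm_trend_summary <- function(trends) {
  labels <- if (is.data.frame(trends)) trends$trend else trends
  if (length(labels) == 0) stop_mirarm("no arm pairs to summarize")
  lv <- c("same", "opposite", "single", "none")
  tab <- table(factor(labels, levels = lv))
  data.frame(trend = lv, count = as.integer(tab),
             proportion = as.numeric(tab) / length(labels),
             stringsAsFactors = FALSE)
}
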