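# Per-patient risk profiles from the two miR arms, and Kaplan-Meier /
# log-rank stratification.

#' Per-patient risk factors and linear risk score
#'
#' A risk factor is counted for 5p upregulation (relative-expression ratio
#' strictly above 1) and for 3p downregulation (ratio strictly below 1), so
#' \code{rf_count} is 0, 1 or 2; a ratio of exactly 1 contributes no risk
#' factor on either arm. The risk score is a linear combination of the two
#' arm expression levels on the cohort-standardized log2 scale:
#' \code{score = w5 * z(log2 ratio_5p) - w3 * z(log2 ratio_3p)}, so it
#' increases with 5p expression and decreases with 3p expression. When a
#' survival table is supplied the weights are instead estimated from a
#' proportional-hazards fit of the two standardized arm levels.
#'
#' @param rel_5p,rel_3p per-sample relative-expression tables for the two
#'   arms (columns sample, ratio), e.g. from
#'   \code{\link{ddct_relative_expression}}.
#' @param w5,w3 non-negative weights of the 5p and 3p components.
#' @param survival optional data frame (patient_id or sample, time, event);
#'   when given, weights come from \code{survival::coxph}.
#' @return data frame: sample, ratio_5p, ratio_3p, rf_count, risk_score,
#'   group (factor over rf_count).
#' @export
call_risk_profile <- function(rel_5p, rel_3p, w5 = 1, w3 = 1,
                              survival = NULL) {
  for (d in list(rel_5p, rel_3p))
    if (!all(c("sample", "ratio") %in% names(d)))
      stop_mirarm("relative-expression tables need columns sample, ratio")
  m <- merge(rel_5p[, c("sample", "ratio")], rel_3p[, c("sample", "ratio")],
             by = "sample", suffixes = c("_5p", "_3p"))
  if (nrow(m) == 0) stop_mirarm("no sample has both arms measured")
  miss <- setdiff(union(rel_5p$sample, rel_3p$sample), m$sample)
  if (length(miss))
    stop_mirarm("missing arm measurement for: ", paste(miss, collapse = ", "))
  z <- function(x) {
    lx <- log2(x)
    s <- sd(lx)
    if (!is.finite(s) || s == 0) lx - mean(lx) else (lx - mean(lx)) / s
  }
  z5 <- z(m$ratio_5p); z3 <- z(m$ratio_3p)
  if (!is.null(survival)) {
    key <- if ("patient_id" %in% names(survival)) "patient_id" else "sample"
    sv <- survival[match(m$sample, survival[[key]]), , drop = FALSE]
    if (any(is.na(sv$time)))
      stop_mirarm("survival table does not cover every sample")
    fit <- survival::coxph(survival::Surv(sv$time, sv$event) ~ z5 + z3)
    w5 <- unname(coef(fit)["z5"]); w3 <- -unname(coef(fit)["z3"])
  }
  rf <- as.integer(m$ratio_5p > 1) + as.integer(m$ratio_3p < 1)
  data.frame(sample = m$sample, ratio_5p = m$ratio_5p, ratio_3p = m$ratio_3p,
             rf_count = rf, risk_score = w5 * z5 - w3 * z3,
             group = factor(paste0("RF", rf), levels = c("RF0", "RF1", "RF2")),
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' Product-limit survival estimates per group (survival::survfit) and the
#' two-sided log-rank test (survival::survdiff). With a single group only
#' the curve is returned and the p-value is NA.
#'
#' @param surv data frame with columns time, event and a grouping column.
#' @param group name of the grouping column (default \code{"group"}).
#' @return list with \code{curves} (data frame: group, time, surv, n_risk,
#'   n_event; step functions starting at 1), \code{chisq}, \code{df},
#'   \code{p_value}.
#' @export
km_logrank <- function(surv, group = "group") {
  need <- c("time", "event", group)
  if (!all(need %in% names(surv)))
    stop_mirarm("survival table needs columns: ", paste(need, collapse = ", "))
  g <- factor(surv[[group]])
  if (any(table(g) == 0) || nlevels(droplevels(g)) < 1)
    stop_mirarm("every group must contain at least one subject")
  if (sum(surv$event) < 1 && nlevels(droplevels(g)) > 1)
    stop_mirarm("need at least one event overall")
  df <- data.frame(time = surv$time, event = surv$event, g = droplevels(g))
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = df)
  strata <- if (is.null(fit$strata)) setNames(length(fit$time),
                                              levels(df$g)[1]) else fit$strata
  curves <- data.frame(group = rep(sub("^g=", "", names(strata)), strata),
                       time = fit$time, surv = fit$surv,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       stringsAsFactors = FALSE)
  if (nlevels(df$g) < 2)
    return(list(curves = curves, chisq = NA_real_, df = 0, p_value = NA_real_))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  df_free <- length(sd_$n) - 1
  list(curves = curves, chisq = sd_$chisq, df = df_free,
       p_value = pchisq(sd_$chisq, df_free, lower.tail = FALSE))
}
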