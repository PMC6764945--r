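# Configuration-driven orchestration: one reproducible run tying the
# simulation and analysis stages together, with a machine-readable report.

RUN_STAGES <- c("simulate", "arms", "trends", "pulldown", "isomir", "duplex")

RUN_DEFAULTS <- list(
  seed = 1L,
  stages = RUN_STAGES,
  out_dir = ".",
  # analysis thresholds at their conventional values
  min_fpkm = 0.1, er_cutoff = 1.2, pseudocount = 0.01,
  lfc_cutoff = 1, fdr_cutoff = 0.001, lfc_pseudo = 1,
  trend_alpha = 0.05, trend_min_abs_log2fc = 1,
  min_read_len = 14, entropy_cutoff = 0.5, max_mm = 2, max_hits = 100,
  ddct_low_threshold = 1.0
)

#' Validate a run configuration
#'
#' Fills defaults and rejects unknown keys and invalid parameter values
#' before any stage executes.
#'
#' @param config named list of run parameters; see \code{RUN_DEFAULTS} in
#'   the package source for the full set. Simulation parameters are
#'   supplied through \code{config$sim}, a list passed to
#'   \code{\link{sim_config}} (its seed defaults to the run seed).
#' @return the fully resolved configuration (class \code{run_config}).
#' @export
run_config <- function(config = list()) {
  sim_args <- config$sim %||% list()
  config$sim <- NULL
  unknown <- setdiff(names(config), names(RUN_DEFAULTS))
  if (length(unknown))
    stop_mirarm("unknown configuration keys: ", paste(unknown, collapse = ", "),
                class = "mirarmkit_config_error")
  cfg <- utils::modifyList(RUN_DEFAULTS, config)
  if (!all(cfg$stages %in% RUN_STAGES))
    stop_mirarm("unknown stage(s): ",
                paste(setdiff(cfg$stages, RUN_STAGES), collapse = ", "),
                class = "mirarmkit_config_error")
  if (cfg$er_cutoff <= 0 || cfg$min_fpkm < 0 || cfg$trend_alpha <= 0 ||
      cfg$trend_alpha >= 1 || cfg$min_read_len < 1)
    stop_mirarm("invalid threshold value", class = "mirarmkit_config_error")
  if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
  cfg$sim <- do.call(sim_config, sim_args)
  structure(cfg, class = "run_config")
}

#' Execute a configured run
#'
#' Runs the selected stages in dependency order (simulate first, then the
#' analysis stages on the simulated inputs), logging each stage's in/out
#' counts to stderr and collecting per-stage summaries into a run report.
#' Outputs are written under \code{config$out_dir}.
#'
#' @param config a \code{\link{run_config}} (or a plain list passed to
#'   it).
#' @return the run report (class \code{run_report}), invisibly; also
#'   written as JSON to \code{out_dir/report.json}.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, ...)
    message(sprintf("[mirarmkit:%s] %s", stage, paste0(...)))
  stages <- list()
  sim <- cfg$sim
  log_stage("simulate", "seed ", sim$seed)
  write_simulated_inputs(sim, cfg$out_dir)
  stages$simulate <- list(n_arm_pairs = sim$n_arm_pairs,
                          n_genes = sim$n_genes, n_reads = sim$n_reads)
  cohort <- gen_cohort(sim)
  if ("arms" %in% cfg$stages) {
    qpcr <- gen_qpcr(sim, c("miR-574-5p" = sim$fold_effect,
                            "miR-574-3p" = 1 / sim$fold_effect))
    rel5 <- ddct_relative_expression(qpcr, "miR-574-5p", "U6",
                                     low_threshold = cfg$ddct_low_threshold)
    rel3 <- ddct_relative_expression(qpcr, "miR-574-3p", "U6",
                                     low_threshold = cfg$ddct_low_threshold)
    prof <- call_risk_profile(rel5, rel3)
    write_tsv(prof, file.path(cfg$out_dir, "risk_profiles.tsv"))
    surv <- gen_survival(sim, prof$risk_score)
    surv$group <- ifelse(prof$risk_score > median(prof$risk_score),
                         "high", "low")
    km <- km_logrank(surv)
    write_tsv(km$curves, file.path(cfg$out_dir, "km_curves.tsv"))
    stages$arms <- list(n_patients = nrow(prof),
                        mean_rf = mean(prof$rf_count),
                        logrank_p = km$p_value)
    log_stage("arms", nrow(prof), " patients, log-rank p = ",
              signif(km$p_value, 3))
  }
  if ("trends" %in% cfg$stages) {
    trends <- classify_cohort_trends(cohort$expression,
                                     alpha = cfg$trend_alpha,
                                     min_abs_log2fc = cfg$trend_min_abs_log2fc)
    summ <- arm_trend_summary(trends)
    write_tsv(summ, file.path(cfg$out_dir, "trend_summary.tsv"))
    stages$trends <- list(n_pairs = nrow(trends),
                          proportions = setNames(as.list(summ$proportion),
                                                 summ$trend))
    log_stage("trends", nrow(trends), " pairs in, ",
              sum(summ$count[summ$trend != "none"]), " dysregulated")
  }
  if ("pulldown" %in% cfg$stages) {
    pd <- gen_pulldown(sim)
    expressed <- filter_expressed(pd$abundance, cfg$min_fpkm)
    er <- enrichment_ratio(expressed, pseudocount = cfg$pseudocount,
                           er_cutoff = cfg$er_cutoff)
    lfc <- log2fc_table(expressed$oe, expressed$oe_ctrl,
                        pseudo = cfg$lfc_pseudo, gene_id = expressed$gene_id)
    rec <- define_potential_targets(cbind(er, log2fc = lfc$log2fc))
    write_tsv(rec, file.path(cfg$out_dir, "enrichment_records.tsv"))
    ks <- cdf_shift_test(rec$log2fc[rec$potential_target], rec$log2fc)
    stages$pulldown <- list(n_in = nrow(pd$abundance),
                            n_expressed = nrow(expressed),
                            n_candidates = sum(rec$candidate),
                            n_potential_targets = sum(rec$potential_target),
                            ks_d = ks$statistic, ks_p = ks$p_value)
    log_stage("pulldown", nrow(pd$abundance), " genes in, ",
              nrow(expressed), " expressed, ", sum(rec$candidate),
              " candidates, ", sum(rec$potential_target), " targets")
  }
  refs <- gen_references(sim)
  if ("isomir" %in% cfg$stages) {
    reads <- gen_small_rna_reads(sim, refs)
    filt <- filter_reads(reads$reads, min_len = cfg$min_read_len,
                         entropy_cutoff = cfg$entropy_cutoff)
    calls <- assign_reads(filt$reads, refs$mirnas, max_mm = cfg$max_mm,
                          max_hits = cfg$max_hits)
    calls <- classify_isoform(calls, refs$mirnas)
    prof <- build_profile(calls)
    write_tsv(prof, file.path(cfg$out_dir, "isomir_profile.tsv"))
    cls_prop <- tapply(prof$count, prof$class, sum) / sum(prof$count)
    stages$isomir <- list(n_reads_in = nrow(reads$reads),
                          n_filtered = filt$n_removed,
                          n_assigned = length(unique(calls$read_id)),
                          class_proportions = as.list(cls_prop))
    log_stage("isomir", nrow(reads$reads), " reads in, ", filt$n_removed,
              " filtered, ", length(unique(calls$read_id)), " assigned")
  }
  if ("duplex" %in% cfg$stages) {
    mirs <- setNames(refs$mirnas$mature, refs$mirnas$mirna_id)
    txs <- setNames(refs$transcripts$sequence, refs$transcripts$transcript_id)
    sites <- scan_transcripts(mirs, txs)
    write_tsv(sites, file.path(cfg$out_dir, "site_table.tsv"))
    sponge <- design_sponge(mirs[[1]], names(mirs)[1], seed = cfg$seed)
    write_fasta(setNames(sponge$construct, paste0(sponge$mirna_id, "_sponge")),
                file.path(cfg$out_dir, "sponge.fa"))
    stages$duplex <- list(n_sites = nrow(sites),
                          site_classes = as.list(table(sites$label)),
                          sponge_len = nchar(sponge$construct))
    log_stage("duplex", nrow(sites), " sites called")
  }
  report <- build_run_report(cfg, stages)
  write_report(report, cfg$out_dir)
  invisible(report)
}

build_run_report <- function(cfg, stages) {
  resolved <- unclass(cfg)
  resolved$sim <- unclass(resolved$sim)
  hashable <- list(config = resolved, stages = stages)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(hashable, auto_unbox = TRUE, digits = NA), tmp)
  structure(list(package_version = as.character(utils::packageVersion("mirarmkit")),
                 config = resolved, stages = stages,
                 config_hash = unname(tools::md5sum(tmp)),
                 timestamp = format(Sys.time(), tz = "UTC")),
            class = "run_report")
}

#' Write a run report
#'
#' Machine-readable JSON is always written; TSV and markdown summaries are
#' optional human-readable views. The config hash excludes timestamps, so
#' identical inputs and configuration yield an identical hash.
#'
#' @param report a \code{run_report} from \code{\link{run_pipeline}}.
#' @param out_dir output directory.
#' @param formats subset of \code{c("json", "tsv", "markdown")}.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, out_dir, formats = "json") {
  stopifnot(inherits(report, "run_report"))
  formats <- union("json", formats)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  jp <- file.path(out_dir, "report.json")
  jsonlite::write_json(unclass(report), jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, jp)
  if ("tsv" %in% formats) {
    tp <- file.path(out_dir, "report_summary.tsv")
    rows <- do.call(rbind, lapply(names(report$stages), function(s)
      data.frame(stage = s,
                 summary = jsonlite::toJSON(report$stages[[s]],
                                            auto_unbox = TRUE, digits = NA),
                 stringsAsFactors = FALSE)))
    write_tsv(rows, tp)
    paths <- c(paths, tp)
  }
  if ("markdown" %in% formats) {
    mp <- file.path(out_dir, "report.md")
    thr <- report$config[c("min_fpkm", "er_cutoff", "lfc_cutoff",
                           "fdr_cutoff", "min_read_len", "max_mm",
                           "max_hits", "trend_alpha")]
    lines <- c("# mirarmkit run report", "",
               paste0("- config hash: ", report$config_hash),
               paste0("- ", names(thr), ": ", unlist(thr)), "",
               paste0("## ", names(report$stages)))
    writeLines(lines, mp)
    paths <- c(paths, mp)
  }
  invisible(paths)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$config_hash, "stages:",
      paste(names(x$stages), collapse = ", "), "\n")
  invisible(x)
}
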