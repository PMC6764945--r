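# Synthetic-data generators.
#
# Every input the analysis modules consume can be generated here with
# planted, machine-readable ground truth: a paired tumor/normal cohort with
# known arm-trend classes, qPCR Ct tables with known fold changes, a
# four-library pull-down experiment with spiked bound genes, reference
# miRNAs/precursors/transcripts with designed binding sites, small-RNA read
# sets with a known isoform mixture, and survival times driven by a linear
# risk score. All randomness flows through the single seed in `sim_config`.

TREND_CLASSES <- c("same_up", "same_down", "opposite_5p_up",
                   "opposite_3p_up", "single", "null")
ISO_CLASSES <- c("canonical", "trimmed", "tailed_nt", "tailed_t")

#' Generate a paired tumor/normal arm-expression cohort
#'
#' Simulates paired expression of both arms (5p/3p) of each precursor over
#' a cohort of patients. Expression noise is lognormal (multiplicative), a
#' per-patient factor shared by tumor and normal tissue models
#' between-patient variability, and dysregulated arms are multiplied or
#' divided by \code{fold_effect} in tumor tissue according to the planted
#' trend class. Class counts follow \code{trend_fractions} exactly
#' (largest-remainder apportionment), so the planted composition is the
#' configured one rather than a multinomial draw around it.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{expression} (long data frame: precursor_id,
#'   patient_id, arm, normal, tumor) and \code{truth} (precursor_id,
#'   trend_label, expected_call).
#' @export
gen_cohort <- function(config) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, 11), {
    n <- config$n_arm_pairs
    np <- config$n_patients
    counts <- apportion(n, config$trend_fractions[TREND_CLASSES])
    labels <- sample(rep(TREND_CLASSES, counts))
    eff5 <- rep(1, n); eff3 <- rep(1, n)
    f <- config$fold_effect
    eff5[labels == "same_up"] <- f;   eff3[labels == "same_up"] <- f
    eff5[labels == "same_down"] <- 1 / f; eff3[labels == "same_down"] <- 1 / f
    eff5[labels == "opposite_5p_up"] <- f; eff3[labels == "opposite_5p_up"] <- 1 / f
    eff5[labels == "opposite_3p_up"] <- 1 / f; eff3[labels == "opposite_3p_up"] <- f
    single <- which(labels == "single")
    if (length(single)) {
      arm5 <- runif(length(single)) < 0.5
      up <- runif(length(single)) < 0.5
      fac <- ifelse(up, f, 1 / f)
      eff5[single[arm5]] <- fac[arm5]
      eff3[single[!arm5]] <- fac[!arm5]
    }
    pid <- sprintf("pair_%04d", seq_len(n))
    patient <- sprintf("pt_%03d", seq_len(np))
    sd <- config$lognormal_sd
    rows <- vector("list", 2L * n)
    for (j in seq_len(n)) {
      # patient factor shared across arms and tissues (cancels in pairing)
      pfac <- exp(rnorm(np, 0, 0.5))
      for (arm in c("5p", "3p")) {
        base <- rlnorm(1, log(100), 1)
        eff <- if (arm == "5p") eff5[j] else eff3[j]
        normal <- base * pfac * exp(rnorm(np, 0, sd))
        tumor <- base * pfac * eff * exp(rnorm(np, 0, sd))
        rows[[2L * (j - 1L) + (arm == "3p") + 1L]] <-
          data.frame(precursor_id = pid[j], patient_id = patient,
                     arm = arm, normal = normal, tumor = tumor,
                     stringsAsFactors = FALSE)
      }
    }
    expected <- c(same_up = "same", same_down = "same",
                  opposite_5p_up = "opposite", opposite_3p_up = "opposite",
                  single = "single", null = "none")
    list(expression = do.call(rbind, rows),
         truth = data.frame(precursor_id = pid, trend_label = labels,
                            expected_call = unname(expected[labels]),
                            stringsAsFactors = FALSE))
  })
}

#' Generate a qPCR Ct table with known fold changes
#'
#' Ct values follow \code{Ct = baseline - log2(abundance) + N(0, replicate_sd)}.
#' Target genes have abundance 1 in normal tissue and \code{true_ratios[gene]}
#' in tumor; the reference gene is constant across conditions.
#'
#' @param config a \code{\link{sim_config}} (uses \code{replicate_sd},
#'   \code{n_replicates}, \code{n_patients}).
#' @param true_ratios named numeric vector, gene id to tumor/normal fold
#'   change; all folds must be positive.
#' @param reference_gene id of the constant reference gene.
#' @return data frame: sample, gene, condition, replicate, ct.
#' @export
gen_qpcr <- function(config, true_ratios, reference_gene = "U6") {
  validate_sim_config(config)
  if (is.null(names(true_ratios)) || any(!nzchar(names(true_ratios))))
    stop_mirarm("true_ratios must be a named vector")
  if (any(true_ratios <= 0))
    stop_mirarm("true fold changes must be positive")
  with_seed(child_seed(config$seed, 23), {
    genes <- c(names(true_ratios), reference_gene)
    baseline <- setNames(c(rep(25, length(true_ratios)), 18), genes)
    abund <- rbind(normal = rep(1, length(genes)),
                   tumor = c(unname(true_ratios), 1))
    colnames(abund) <- genes
    grid <- expand.grid(sample = sprintf("pt_%03d", seq_len(config$n_patients)),
                        gene = genes, condition = c("tumor", "normal"),
                        replicate = seq_len(config$n_replicates),
                        stringsAsFactors = FALSE)
    grid$ct <- baseline[grid$gene] -
      log2(abund[cbind(grid$condition, grid$gene)]) +
      rnorm(nrow(grid), 0, config$replicate_sd)
    grid[order(grid$sample, grid$gene, grid$condition, grid$replicate), ,
         drop = FALSE]
  })
}

#' Generate a biotinylated pull-down experiment with spiked bound genes
#'
#' Models the standard four-library design (bait pull-down, control
#' pull-down, bait input, control input) plus an overexpression pair
#' (oe, oe_ctrl). Per-gene true abundances are lognormal across genes; each
#' library measures the same RNA pool through Poisson sequencing counts at
#' the configured depth, so measurement noise is counting noise.
#' Spiked genes have their expected bait pull-down abundance multiplied by
#' \code{er_effect}; the same genes are the true targets and are depleted
#' by \code{depletion_log2fc} log2 units in the overexpression library.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{abundance} (data frame of CPM-scaled abundances,
#'   one column per library role), \code{counts} (raw Poisson counts) and
#'   \code{truth} (enriched/true-target flags per gene).
#' @export
gen_pulldown <- function(config) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, 37), {
    ng <- config$n_genes
    genes <- sprintf("gene_%05d", seq_len(ng))
    enriched <- sort(sample(ng, config$n_enriched))
    is_enr <- seq_len(ng) %in% enriched
    a <- rlnorm(ng, log(100), 1)
    rel <- a / sum(a)
    libs <- c("bait_pd", "ctrl_pd", "bait_input", "ctrl_input", "oe", "oe_ctrl")
    sizes <- rep_len(config$library_sizes, length(libs))
    eff <- matrix(1, ng, length(libs), dimnames = list(NULL, libs))
    eff[is_enr, "bait_pd"] <- config$er_effect
    eff[is_enr, "oe"] <- 2^config$depletion_log2fc
    counts <- sapply(seq_along(libs), function(l)
      rpois(ng, rel * eff[, l] * sizes[l]))
    colnames(counts) <- libs
    cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
    list(abundance = data.frame(gene_id = genes, cpm, stringsAsFactors = FALSE),
         counts = data.frame(gene_id = genes, counts, stringsAsFactors = FALSE),
         truth = data.frame(gene_id = genes, enriched = is_enr,
                            true_target = is_enr, stringsAsFactors = FALSE))
  })
}

## -- reference sequences ----------------------------------------------------

# Remove every occurrence of the given 6-mers from `seq` by point mutation,
# leaving protected ranges (planted sites) untouched. Ranges are 1-based
# inclusive [start, end] pairs.
scrub_seeds <- function(seq, kmers, protect = NULL) {
  ch <- seq_chars(seq)
  protected <- rep(FALSE, length(ch))
  if (!is.null(protect))
    for (r in protect) protected[r[1]:r[2]] <- TRUE
  for (iter in 1:200) {
    s <- chars_to_seq(ch)
    hit <- NULL
    for (k in kmers) {
      m <- gregexpr(k, s, fixed = TRUE)[[1]]
      m <- m[m > 0]
      for (p in m) {
        span <- p:(p + nchar(k) - 1)
        free <- span[!protected[span]]
        if (length(free)) { hit <- free[ceiling(length(free) / 2)]; break }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) return(s)
    ch[hit] <- sample(setdiff(BASES_DNA, ch[hit]), 1)
  }
  stop_mirarm("could not scrub seed matches from background sequence")
}

# Build one binding site (5'->3' on the transcript) for `mature` (DNA,
# 5'->3'). Classes:
#   extensive      - full reverse complement, length L
#   seed_only      - complement of positions 1..8 only; the rest of the
#                    site cannot pair (no WC, no wobble), length L
#   tdmd_competent - complement everywhere except a central internal loop:
#                    the 4 bases opposite miRNA 9..12 are replaced by
#                    `loop_insert` + 4 random bases (net insertion), so the
#                    seed and the 3'-adjacent region pair fully while the
#                    center loops out; length L + loop_insert
build_site <- function(mature, class, loop_start = 9L, loop_end = 12L,
                       loop_insert = 4L) {
  m <- seq_chars(norm_t(mature))
  L <- length(m)
  comp <- unname(comp_base[m])
  site_rev <- switch(class,
    extensive = comp,
    seed_only = {
      s <- comp
      for (i in 9:L) s[i] <- noncomp_base(m[i])
      s
    },
    tdmd_competent = {
      loop <- replicate(loop_end - loop_start + 1 + loop_insert,
                        noncomp_base(sample(m[loop_start:loop_end], 1)))
      c(comp[1:(loop_start - 1)], loop, comp[(loop_end + 1):L])
    },
    stop_mirarm("unknown site class: ", class))
  # site_rev[i] faces miRNA position i; the transcript site runs antiparallel
  chars_to_seq(rev(site_rev))
}

#' Generate reference miRNAs, precursors and target transcripts
#'
#' Mature miRNA sequences are random with mutually distinct seed 6-mers.
#' Each precursor embeds its mature sequence between flanks, giving the
#' downstream context needed to call templated versus non-templated tails.
#' For every miRNA one transcript per site class (seed-only,
#' TDMD-competent, extensive, none) is produced; backgrounds and flanks are
#' scrubbed of chance seed matches so planted sites are the only ones a
#' scanner can find. Site coordinates are recorded 0-based half-open.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with data frames \code{mirnas} (mirna_id, mature,
#'   precursor, mature_start (1-based)), \code{transcripts} (transcript_id,
#'   sequence), and \code{truth} (transcript_id, mirna_id, site_class,
#'   start, end).
#' @export
gen_references <- function(config) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, 53), {
    n <- config$n_mirnas
    L <- config$mirna_len
    mats <- character(n)
    seeds6 <- character(0)
    for (i in seq_len(n)) {
      repeat {
        cand <- random_seq(L)
        s6 <- substr(cand, 2, 7)
        if (s6 %in% seeds6) next
        # the full complement must contain the seed complement exactly
        # once, or planted extensive sites would carry two seed anchors
        if (lengths(gregexpr(revcomp(s6), revcomp(cand), fixed = TRUE)) != 1)
          next
        mats[i] <- cand; seeds6 <- c(seeds6, s6); break
      }
    }
    seed_rc <- vapply(mats, function(m) revcomp(substr(m, 2, 7)), "")
    ids <- sprintf("mir_%02d", seq_len(n))
    fl <- config$flank_len
    pre <- vapply(seq_len(n), function(i) {
      up <- scrub_seeds(random_seq(fl), seed_rc)
      dn <- scrub_seeds(random_seq(fl), seed_rc)
      paste0(up, mats[i], dn)
    }, "")
    tx_rows <- list(); truth_rows <- list()
    classes <- c("seed_only", "tdmd_competent", "extensive", "none")
    for (i in seq_len(n)) {
      for (cl in classes) {
        txid <- paste0(ids[i], "_", cl)
        bg <- scrub_seeds(random_seq(config$transcript_len), seed_rc)
        if (cl == "none") {
          tx_rows[[txid]] <- data.frame(transcript_id = txid, sequence = bg)
          truth_rows[[txid]] <- data.frame(
            transcript_id = txid, mirna_id = ids[i], site_class = "none",
            start = NA_integer_, end = NA_integer_,
            seed_start = NA_integer_, seed_end = NA_integer_)
          next
        }
        # plant the site and verify the round trip: the scanner must
        # recover the designed label at the planted seed anchor (and the
        # full extent for the structured classes), with no incidental
        # complementarity in the flanks; otherwise regenerate
        ok <- FALSE
        for (attempt in 1:40) {
          site <- build_site(mats[i], cl)
          if (lengths(gregexpr(seed_rc[i], site, fixed = TRUE)) != 1) next
          pos <- sample(50:(config$transcript_len - nchar(site) - 50), 1)
          seqx <- paste0(substr(bg, 1, pos), site,
                         substr(bg, pos + 1, nchar(bg)))
          seqx <- scrub_seeds(seqx, seed_rc,
                              protect = list(c(pos + 1, pos + nchar(site))))
          tab <- scan_transcript(mats[i], seqx)
          if (nrow(tab) != 1 || tab$label != cl) next
          # the seed complement sits 7 bases from the site 3' end
          seed_start <- pos + nchar(site) - 7L
          if (tab$seed_start != seed_start) next
          if (cl != "seed_only" &&
              (tab$start != pos || tab$end != pos + nchar(site))) next
          ok <- TRUE
          break
        }
        if (!ok)
          stop_mirarm("failed to plant a verifiable ", cl, " site for ",
                      ids[i])
        tx_rows[[txid]] <- data.frame(transcript_id = txid, sequence = seqx)
        truth_rows[[txid]] <- data.frame(
          transcript_id = txid, mirna_id = ids[i], site_class = cl,
          start = pos, end = pos + nchar(site),
          seed_start = seed_start, seed_end = seed_start + 6L)
      }
    }
    list(mirnas = data.frame(mirna_id = ids, mature = mats, precursor = pre,
                             mature_start = fl + 1L, stringsAsFactors = FALSE),
         transcripts = do.call(rbind, c(tx_rows, make.row.names = FALSE)),
         truth = do.call(rbind, c(truth_rows, make.row.names = FALSE)))
  })
}

#' Generate small-RNA reads with a planted isoform mixture
#'
#' Reads are sampled uniformly across the reference miRNAs with classes
#' drawn from \code{isoform_mixture}: canonical (the mature sequence),
#' trimmed (1-3 nt removed from the 3' end), templated tails (1-3 nt
#' copied from the precursor downstream of the mature 3' end) and
#' non-templated tails (1-3 nt each drawn from the three bases differing
#' from the corresponding downstream precursor base, so truth is
#' unambiguous). Substitution errors are applied at
#' \code{read_error_rate} per base.
#'
#' @param config a \code{\link{sim_config}}.
#' @param references output of \code{\link{gen_references}}.
#' @return list with \code{reads} (read_id, sequence) and \code{truth}
#'   (read_id, mirna_id, class, trim_len, tail_len, tail_seq).
#' @export
gen_small_rna_reads <- function(config, references) {
  validate_sim_config(config)
  refs <- references$mirnas
  if (any(nchar(refs$mature) <= 3))
    stop_mirarm("mature sequences must be longer than the maximum trim (3)")
  with_seed(child_seed(config$seed, 71), {
    n <- config$n_reads
    mix <- config$isoform_mixture[ISO_CLASSES]
    ridx <- sample(nrow(refs), n, replace = TRUE)
    cls <- sample(ISO_CLASSES, n, replace = TRUE, prob = mix)
    klen <- sample(1:3, n, replace = TRUE)
    seqs <- character(n); trim <- integer(n); tail_len <- integer(n)
    tails <- character(n)
    for (r in seq_len(n)) {
      m <- refs$mature[ridx[r]]
      pre <- refs$precursor[ridx[r]]
      dn_start <- refs$mature_start[ridx[r]] + nchar(m)
      s <- m; tr <- 0L; tl <- 0L; tseq <- ""
      if (cls[r] == "trimmed") {
        tr <- klen[r]
        s <- substr(m, 1, nchar(m) - tr)
      } else if (cls[r] == "tailed_t") {
        tl <- klen[r]
        tseq <- substr(pre, dn_start, dn_start + tl - 1)
        s <- paste0(m, tseq)
      } else if (cls[r] == "tailed_nt") {
        tl <- klen[r]
        dn <- seq_chars(substr(pre, dn_start, dn_start + tl - 1))
        tseq <- chars_to_seq(vapply(dn, function(b)
          sample(setdiff(BASES_DNA, b), 1), ""))
        s <- paste0(m, tseq)
      }
      if (config$read_error_rate > 0) {
        ch <- seq_chars(s)
        hit <- which(runif(length(ch)) < config$read_error_rate)
        for (h in hit) ch[h] <- sample(setdiff(BASES_DNA, ch[h]), 1)
        s <- chars_to_seq(ch)
      }
      seqs[r] <- s; trim[r] <- tr; tail_len[r] <- tl; tails[r] <- tseq
    }
    rid <- sprintf("read_%06d", seq_len(n))
    list(reads = data.frame(read_id = rid, sequence = seqs,
                            stringsAsFactors = FALSE),
         truth = data.frame(read_id = rid, mirna_id = refs$mirna_id[ridx],
                            class = cls, trim_len = trim,
                            tail_len = tail_len, tail_seq = tails,
                            stringsAsFactors = FALSE))
  })
}

#' Generate survival times driven by a linear risk score
#'
#' Event times are exponential with hazard
#' \code{baseline_hazard * exp(hazard_beta * score)}. Independent censoring
#' marks a \code{censor_rate} fraction of subjects as censored at a uniform
#' fraction of their latent event time.
#'
#' @param config a \code{\link{sim_config}}.
#' @param risk_scores numeric vector of per-patient risk scores.
#' @return data frame: patient_id, time (days), event (0/1), risk_score.
#' @export
gen_survival <- function(config, risk_scores) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, 89), {
    n <- length(risk_scores)
    rate <- config$baseline_hazard * exp(config$hazard_beta * risk_scores)
    t_event <- rexp(n, rate)
    censored <- runif(n) < config$censor_rate
    time <- ifelse(censored, t_event * runif(n), t_event)
    data.frame(patient_id = sprintf("pt_%03d", seq_len(n)),
               time = time, event = as.integer(!censored),
               risk_score = risk_scores, stringsAsFactors = FALSE)
  })
}

## -- file surface -----------------------------------------------------------

#' Write every simulated input to disk with ground-truth sidecars
#'
#' Materializes one full simulated study: cohort and survival TSVs, qPCR Ct
#' table, pull-down abundance tables, reference FASTA files (mature miRNAs
#' as RNA, precursors, transcripts), small-RNA reads as FASTQ (Phred+33,
#' constant quality "I"), a ground-truth TSV next to each file, and a JSON
#' run manifest echoing all paths and parameters.
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest as a list.
#' @export
write_simulated_inputs <- function(config, out_dir) {
  validate_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  cohort <- gen_cohort(config)
  write_tsv(cohort$expression, p("cohort.tsv"))
  write_tsv(cohort$truth, p("cohort.truth.tsv"))
  qpcr <- gen_qpcr(config, c("miR-574-5p" = config$fold_effect,
                             "miR-574-3p" = 1 / config$fold_effect))
  write_tsv(qpcr, p("qpcr_ct.tsv"))
  pd <- gen_pulldown(config)
  write_tsv(pd$abundance, p("pulldown_abundance.tsv"))
  write_tsv(pd$truth, p("pulldown.truth.tsv"))
  refs <- gen_references(config)
  write_fasta(setNames(to_rna(refs$mirnas$mature), refs$mirnas$mirna_id),
              p("mature.fa"))
  write_fasta(setNames(refs$mirnas$precursor, refs$mirnas$mirna_id),
              p("precursor.fa"))
  write_tsv(refs$mirnas[, c("mirna_id", "mature_start")], p("mature_offsets.tsv"))
  write_fasta(setNames(refs$transcripts$sequence,
                       refs$transcripts$transcript_id), p("transcripts.fa"))
  write_tsv(refs$truth, p("sites.truth.tsv"))
  reads <- gen_small_rna_reads(config, refs)
  write_fastq(setNames(reads$reads$sequence, reads$reads$read_id),
              p("reads.fastq"))
  write_tsv(reads$truth, p("reads.truth.tsv"))
  scores <- with_seed(child_seed(config$seed, 97),
                      rnorm(config$n_patients))
  surv <- gen_survival(config, scores)
  write_tsv(surv, p("survival.tsv"))
  manifest <- list(config = unclass(config),
                   files = list(cohort = "cohort.tsv", qpcr = "qpcr_ct.tsv",
                                pulldown = "pulldown_abundance.tsv",
                                mature = "mature.fa", precursor = "precursor.fa",
                                transcripts = "transcripts.fa",
                                reads = "reads.fastq", survival = "survival.tsv"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read and write FASTA/FASTQ sequence sets
#'
#' Thin wrappers over Biostrings I/O returning plain named character
#' vectors, the representation the rest of the package works with.
#'
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @return \code{read_fasta}/\code{read_fastq} return a named character
#'   vector; the writers return \code{path} invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(norm_t(seqs))
  qual <- Biostrings::PhredQuality(vapply(nchar(seqs), function(n)
    strrep("I", n), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname write_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub(" .*", "", names(x)))
}
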