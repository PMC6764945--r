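# isomiR profiling: read filtering, anchored assignment to mature miRNAs,
# canonical/trimmed/tailed classification with templated vs non-templated
# tail typing, and normalized class-proportion profiles.

ISOMIR_CLASSES <- c("canonical", "trimmed", "tailed", "trimmed_tailed")

#' Shannon entropy of a read's dinucleotide composition
#'
#' Entropy (bits) over the frequencies of overlapping dinucleotides; 0 for
#' homopolymers, up to 4 for maximally diverse sequences. Used as a
#' low-complexity filter.
#'
#' @param seq a sequence string.
#' @return entropy in bits.
#' @export
dinucleotide_entropy <- function(seq) {
  ch <- seq_chars(norm_t(seq))
  if (length(ch) < 2) return(0)
  dinuc <- paste0(ch[-length(ch)], ch[-1])
  p <- table(dinuc) / length(dinuc)
  -sum(p * log2(p))
}

#' Filter small-RNA reads by length and complexity
#'
#' Drops reads shorter than \code{min_len} nucleotides and reads whose
#' dinucleotide Shannon entropy falls below \code{entropy_cutoff} bits
#' (low-complexity reads; a homopolymer has entropy 0).
#'
#' @param reads data frame with read_id and sequence columns, or a named
#'   character vector of sequences.
#' @param min_len minimum retained read length (default 14).
#' @param entropy_cutoff minimum dinucleotide entropy in bits
#'   (default 0.5).
#' @return list with \code{reads} (the retained reads, same shape as the
#'   input), \code{n_removed} and \code{fraction_removed}.
#' @export
filter_reads <- function(reads, min_len = 14, entropy_cutoff = 0.5) {
  seqs <- if (is.data.frame(reads)) reads$sequence else unname(reads)
  keep <- nchar(seqs) >= min_len &
    vapply(seqs, dinucleotide_entropy, 1.0) >= entropy_cutoff
  out <- if (is.data.frame(reads)) reads[keep, , drop = FALSE] else reads[keep]
  list(reads = out, n_removed = sum(!keep),
       fraction_removed = if (length(keep)) mean(!keep) else 0)
}

# Mismatches between read and the precursor-extended reference when the
# read's first base sits at mature position `offset + 1`. Only positions
# overlapping the mature sequence count; tail bases beyond the mature 3'
# end are free here and typed later. Returns NA when the overlap is
# invalid.
anchored_mismatches <- function(read_ch, mature_ch, pre_ch, mature_start,
                                offset) {
  n <- length(read_ch); Lm <- length(mature_ch)
  mpos <- offset + seq_len(n)          # mature positions faced by the read
  in_mature <- mpos >= 1 & mpos <= Lm
  if (!any(in_mature)) return(NA_integer_)
  # require the read to reach at least mature position 1 region sensibly:
  # upstream overhang beyond the precursor is disallowed
  ppos <- mature_start - 1 + mpos      # precursor positions
  if (any(ppos < 1) || any(ppos[in_mature] > length(pre_ch)))
    return(NA_integer_)
  sum(read_ch[in_mature] != mature_ch[mpos[in_mature]])
}

#' Assign reads to mature miRNAs by anchored matching
#'
#' Each read is compared, ungapped, against every mature reference over 5'
#' offsets in [-3, +3] with a variable 3' end; mismatches are counted only
#' in the mature-overlapping portion (3' tail bases are typed separately).
#' Assignments with more than \code{max_mm} mismatches are dropped, reads
#' hitting more than \code{max_hits} references are discarded, and a read
#' matching several references is kept with its fewest-mismatch set, each
#' assignment weighted by the equal fractional split. Reads that match
#' some precursor region outside the mature window with fewer mismatches
#' than their best mature assignment are discarded (the stand-in for the
#' usual genome-mismatch filter).
#'
#' @param reads data frame (read_id, sequence) or named character vector.
#' @param refs data frame with mirna_id, mature, precursor, mature_start
#'   (1-based offset of the mature 5' end in the precursor), as produced
#'   by \code{\link{gen_references}}.
#' @param max_mm maximum mismatches in the mature-overlapping portion.
#' @param max_hits maximum assignments per read.
#' @param max_offset maximum absolute 5' offset.
#' @return data frame of isomiR calls: read_id, mirna_id, mismatches,
#'   offset5 (5' offset), trim3 (3' trim length), tail_seq, weight.
#' @export
assign_reads <- function(reads, refs, max_mm = 2, max_hits = 100,
                         max_offset = 3) {
  if (is.data.frame(reads)) {
    ids <- reads$read_id; seqs <- norm_t(reads$sequence)
  } else {
    ids <- names(reads) %||% sprintf("read_%06d", seq_along(reads))
    seqs <- norm_t(unname(reads))
  }
  if (nrow(refs) == 0) stop_mirarm("empty reference set")
  if (anyDuplicated(refs$mirna_id)) stop_mirarm("duplicate reference ids")
  ref_mat <- lapply(refs$mature, function(x) seq_chars(norm_t(x)))
  ref_pre <- lapply(refs$precursor, function(x) seq_chars(norm_t(x)))
  uniq <- unique(seqs)
  per_seq <- lapply(uniq, function(s) {
    rch <- seq_chars(s)
    n <- length(rch)
    hits <- list()
    for (k in seq_len(nrow(refs))) {
      Lm <- length(ref_mat[[k]])
      best <- NULL
      for (off in -max_offset:max_offset) {
        mm <- anchored_mismatches(rch, ref_mat[[k]], ref_pre[[k]],
                                  refs$mature_start[k], off)
        if (is.na(mm) || mm > max_mm) next
        # prefer fewest mismatches, then smallest |offset|, then 3' fit
        if (is.null(best) || mm < best$mm ||
            (mm == best$mm && abs(off) < abs(best$off)))
          best <- list(mm = mm, off = off)
      }
      if (is.null(best)) next
      trim3 <- max(0L, Lm - (best$off + n))
      tail_len <- max(0L, best$off + n - Lm)
      tail_seq <- if (tail_len > 0) substr(s, n - tail_len + 1, n) else ""
      # genome-like filter: a better ungapped match elsewhere in the
      # precursor disqualifies the mature assignment
      pre <- ref_pre[[k]]
      ms <- refs$mature_start[k]
      outside <- setdiff(seq_len(max(0L, length(pre) - n + 1L)),
                         (ms - max_offset):(ms + max_offset))
      better <- FALSE
      for (p in outside) {
        if (sum(rch != pre[p:(p + n - 1)]) < best$mm) { better <- TRUE; break }
      }
      if (better) next
      hits[[length(hits) + 1]] <- data.frame(
        mirna_id = refs$mirna_id[k], mismatches = best$mm,
        offset5 = best$off, trim3 = trim3, tail_seq = tail_seq,
        stringsAsFactors = FALSE)
    }
    if (length(hits) == 0 || length(hits) > max_hits) return(NULL)
    h <- do.call(rbind, hits)
    h <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
    h$weight <- 1 / nrow(h)
    h
  })
  names(per_seq) <- uniq
  out <- lapply(seq_along(seqs), function(r) {
    h <- per_seq[[seqs[r]]]
    if (is.null(h)) return(NULL)
    cbind(read_id = ids[r], h, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0)
    return(data.frame(read_id = character(0), mirna_id = character(0),
                      mismatches = integer(0), offset5 = integer(0),
                      trim3 = integer(0), tail_seq = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Classify isomiR calls and type their tails
#'
#' Classes: \code{canonical} (no 5' offset, no trim, no tail),
#' \code{trimmed} (3' trim only), \code{tailed} (3' tail only),
#' \code{trimmed_tailed} (both), \code{five_prime_variant} (any 5'
#' offset; reported separately and excluded from 3'-isoform proportions
#' by default). Tails are \code{templated} when every tail base matches
#' the precursor immediately downstream of the read's 3' genomic end,
#' \code{non_templated} when no base matches, \code{mixed} otherwise.
#'
#' @param calls output of \code{\link{assign_reads}}.
#' @param refs the reference data frame used for assignment.
#' @return \code{calls} with \code{tail_type} and \code{class} columns.
#' @export
classify_isoform <- function(calls, refs) {
  idx <- match(calls$mirna_id, refs$mirna_id)
  if (any(is.na(idx))) stop_mirarm("calls reference unknown miRNA ids")
  tail_type <- character(nrow(calls))
  class <- character(nrow(calls))
  for (r in seq_len(nrow(calls))) {
    trim <- calls$trim3[r]; tail <- calls$tail_seq[r]
    k <- idx[r]
    if (nzchar(tail)) {
      pre <- refs$precursor[k]
      # genomic 3' end of the read's templated portion
      end <- refs$mature_start[k] + nchar(refs$mature[k]) - 1 - trim
      tmpl <- substr(pre, end + 1, end + nchar(tail))
      if (nchar(tmpl) < nchar(tail))
        stop_mirarm("precursor context too short to type a tail")
      a <- seq_chars(norm_t(tail)); b <- seq_chars(norm_t(tmpl))
      nm <- sum(a == b)
      tail_type[r] <- if (nm == length(a)) "templated"
                      else if (nm == 0) "non_templated" else "mixed"
    } else tail_type[r] <- "none"
    class[r] <- if (calls$offset5[r] != 0) "five_prime_variant"
      else if (trim > 0 && nzchar(tail)) "trimmed_tailed"
      else if (trim > 0) "trimmed"
      else if (nzchar(tail)) "tailed"
      else "canonical"
  }
  calls$tail_type <- tail_type
  calls$class <- class
  calls
}

#' Build per-miRNA isomiR class profiles
#'
#' Aggregates weighted class counts per miRNA, computes class proportions
#' (over the 3'-isoform classes; 5' variants are excluded by default and
#' reported as a separate count), and library-size-normalized expression:
#' \code{normalized = count / library_total * mean(library_totals)}, then
#' \code{log2(normalized + 1)}.
#'
#' @param calls classified calls from \code{\link{classify_isoform}}.
#' @param library_total total read count of this library.
#' @param all_library_totals totals of every library in the comparison
#'   (defaults to \code{library_total}, in which case normalized equals
#'   the raw count).
#' @param include_five_prime count 5' variants as their 3' class instead
#'   of excluding them.
#' @return data frame with one row per miRNA and class: mirna_id, class,
#'   count, proportion, normalized, log2_normalized.
#' @export
build_profile <- function(calls, library_total = NULL,
                          all_library_totals = NULL,
                          include_five_prime = FALSE) {
  if (nrow(calls) == 0) stop_mirarm("no calls to profile")
  keep <- if (include_five_prime) rep(TRUE, nrow(calls))
          else calls$class != "five_prime_variant"
  d <- calls[keep, , drop = FALSE]
  if (include_five_prime && any(d$class == "five_prime_variant")) {
    # re-derive the 3' class for 5' variants
    d$class <- ifelse(d$trim3 > 0 & nzchar(d$tail_seq), "trimmed_tailed",
               ifelse(d$trim3 > 0, "trimmed",
               ifelse(nzchar(d$tail_seq), "tailed", "canonical")))
  }
  library_total <- library_total %||% sum(d$weight)
  if (library_total <= 0) stop_mirarm("library total must be positive")
  totals <- all_library_totals %||% library_total
  grid <- expand.grid(mirna_id = unique(d$mirna_id), class = ISOMIR_CLASSES,
                      stringsAsFactors = FALSE)
  agg <- stats::aggregate(weight ~ mirna_id + class, data = d, FUN = sum)
  out <- merge(grid, agg, by = c("mirna_id", "class"), all.x = TRUE)
  out$weight[is.na(out$weight)] <- 0
  names(out)[names(out) == "weight"] <- "count"
  tot <- tapply(out$count, out$mirna_id, sum)
  out$proportion <- out$count / as.numeric(tot[out$mirna_id])
  out$normalized <- out$count / library_total * mean(totals)
  out$log2_normalized <- log2(out$normalized + 1)
  out$class <- factor(out$class, levels = ISOMIR_CLASSES)
  out <- out[order(out$mirna_id, out$class), , drop = FALSE]
  out$class <- as.character(out$class)
  rownames(out) <- NULL
  out
}

#' Compare two isomiR profiles
#'
#' Per-miRNA, per-class difference in proportions (b minus a) with a
#' two-sided two-proportion z-test, flagging classes whose trimming or
#' tailing proportion increased.
#'
#' @param a,b profiles from \code{\link{build_profile}} over the same
#'   miRNAs and classes.
#' @return data frame: mirna_id, class, prop_a, prop_b, delta, p_value,
#'   increased.
#' @export
compare_profiles <- function(a, b) {
  key <- c("mirna_id", "class")
  if (!identical(a[key], b[key]))
    stop_mirarm("profiles must cover the same miRNAs and classes")
  tot_a <- tapply(a$count, a$mirna_id, sum)
  tot_b <- tapply(b$count, b$mirna_id, sum)
  na <- as.numeric(tot_a[a$mirna_id]); nb <- as.numeric(tot_b[b$mirna_id])
  pa <- a$proportion; pb <- b$proportion
  pool <- (a$count + b$count) / (na + nb)
  se <- sqrt(pool * (1 - pool) * (1 / na + 1 / nb))
  z <- ifelse(se > 0, (pb - pa) / se, 0)
  data.frame(mirna_id = a$mirna_id, class = a$class,
             prop_a = pa, prop_b = pb, delta = pb - pa,
             p_value = 2 * pnorm(-abs(z)),
             increased = (pb - pa) > 0 &
               a$class %in% c("trimmed", "tailed", "trimmed_tailed"),
             stringsAsFactors = FALSE)
}
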