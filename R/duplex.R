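# miRNA:target duplex architecture.
#
# Pairing is score-based complementarity (no thermodynamic model):
# Watson-Crick +2, G:U wobble +1, mismatch 0, bulge open -2 / extend -1.
# The aligner is a three-state affine dynamic program, antiparallel, global
# over the miRNA with free target overhangs, so a site embedded in a longer
# window is located by the alignment itself. Site classes follow TDMD
# logic: a competent site pairs the full seed and the 3'-adjacent region,
# loops out the center (positions 9-12), and tolerates up to two unpaired
# nucleotides at the miRNA 3' extremity.

PAIR_SCORE_WC <- 2
PAIR_SCORE_GU <- 1
GAP_OPEN <- -2
GAP_EXT <- -1

# pair state of miRNA base a vs target base b (both T-normalized)
pair_state <- function(a, b) {
  if (comp_base[a] == b) return("wc")
  if ((a == "G" && b == "T") || (a == "T" && b == "G")) return("gu")
  "mismatch"
}

pair_score_base <- function(a, b) {
  switch(pair_state(a, b), wc = PAIR_SCORE_WC, gu = PAIR_SCORE_GU, 0)
}

#' Align a miRNA against a candidate binding site
#'
#' Antiparallel alignment maximizing the pairing score (WC +2, G:U +1,
#' mismatch 0, bulge open -2 / extend -1). The miRNA is aligned end to
#' end; unaligned target overhangs on either side are free, so the best
#' scoring sub-extent of the site is reported. Ties are broken
#' deterministically (leftmost optimum in the miRNA, pairing preferred
#' over bulges).
#'
#' @param mirna miRNA sequence, 5' to 3', RNA or DNA alphabet, length
#'   18-26.
#' @param site candidate site sequence on the transcript sense strand,
#'   5' to 3'; length may exceed the miRNA by up to 8 nt or fall short by
#'   up to 4.
#' @return object of class \code{duplex_alignment}: per-miRNA-position
#'   states (\code{wc}, \code{gu}, \code{mismatch}, \code{mir_bulge}),
#'   target insertions (looped-out target nucleotides with the miRNA
#'   position they follow), total score, aligned site extent (0-based
#'   half-open in \code{site}), and the architecture summaries
#'   seed_paired, three_prime_paired, supp_paired, central_loop,
#'   terminal_3p_mismatches.
#' @export
#' @examples
#' m <- "UGAGGUAGUAGGUUGUAUAGUU"
#' aln <- pair_duplex(m, revcomp(m))
#' aln$score  # all 22 positions Watson-Crick: 44
pair_duplex <- function(mirna, site) {
  check_alphabet(mirna, "miRNA")
  check_alphabet(site, "site")
  a <- seq_chars(norm_t(mirna))
  L <- length(a)
  if (L < 18 || L > 26)
    stop_mirarm("miRNA length must be 18-26 nt")
  s <- seq_chars(norm_t(site))
  m <- length(s)
  if (m < L - 4 || m > L + 8)
    stop_mirarm("site length must lie within [L-4, L+8]")
  t <- rev(s)  # t[j] faces a[i] in the antiparallel duplex
  NEG <- -1e9
  M <- matrix(NEG, L + 1, m + 1); X <- matrix(NEG, L + 1, m + 1)
  Y <- matrix(NEG, L + 1, m + 1)
  M[1, ] <- 0                       # free leading target overhang
  for (i in 2:(L + 1))              # leading miRNA bulge
    X[i, 1] <- max(M[i - 1, 1] + GAP_OPEN, X[i - 1, 1] + GAP_EXT)
  for (i in 2:(L + 1)) {
    for (j in 2:(m + 1)) {
      M[i, j] <- pair_score_base(a[i - 1], t[j - 1]) +
        max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] + GAP_OPEN, X[i - 1, j] + GAP_EXT,
                     Y[i - 1, j] + GAP_OPEN)
      Y[i, j] <- max(M[i, j - 1] + GAP_OPEN, Y[i, j - 1] + GAP_EXT,
                     X[i, j - 1] + GAP_OPEN)
    }
  }
  ends <- pmax(M[L + 1, ], X[L + 1, ])
  score <- max(ends)
  j_end <- which(ends == score)[1] - 1L   # smallest j: leftmost in target tail
  # traceback
  states <- character(L)
  ins <- list()
  i <- L; j <- j_end
  st <- if (M[L + 1, j + 1] >= X[L + 1, j + 1]) "M" else "X"
  while (i > 0) {
    if (st == "M") {
      states[i] <- pair_state(a[i], t[j])
      prev <- c(M = M[i, j], X = X[i, j], Y = Y[i, j])
      st <- names(prev)[which.max(prev)]
      i <- i - 1; j <- j - 1
    } else if (st == "X") {
      states[i] <- "mir_bulge"
      cand <- c(M = M[i, j + 1] + GAP_OPEN, X = X[i, j + 1] + GAP_EXT,
                Y = Y[i, j + 1] + GAP_OPEN)
      st <- names(cand)[which.max(cand)]
      i <- i - 1
    } else {  # Y: target base t[j] looped out after miRNA position i
      ins[[length(ins) + 1]] <- i
      cand <- c(M = M[i + 1, j] + GAP_OPEN, Y = Y[i + 1, j] + GAP_EXT,
                X = X[i + 1, j] + GAP_OPEN)
      st <- names(cand)[which.max(cand)]
      j <- j - 1
    }
  }
  j_first <- j + 1L  # first aligned target index in t (after free overhang)
  target_ins <- if (length(ins)) {
    tab <- table(unlist(ins))
    data.frame(after_mir_pos = as.integer(names(tab)),
               length = as.integer(tab))
  } else data.frame(after_mir_pos = integer(0), length = integer(0))
  # map aligned extent in t back onto the original site string (0-based)
  site_start0 <- m - j_end
  site_end0 <- m - j_first + 1L
  paired <- states %in% c("wc", "gu")
  supp <- 13:(L - 3)
  loop_pos <- intersect(9:12, which(!paired))
  has_loop <- length(loop_pos) > 0 ||
    any(target_ins$after_mir_pos >= 8 & target_ins$after_mir_pos <= 12)
  term_mm <- 0L
  for (k in L:1) { if (paired[k]) break; term_mm <- term_mm + 1L }
  structure(list(mirna = chars_to_seq(a), site = chars_to_seq(s),
                 score = score, states = states,
                 target_insertions = target_ins,
                 site_start0 = site_start0, site_end0 = site_end0,
                 seed_paired = sum(states[2:7] == "wc"),
                 three_prime_paired = sum(paired[13:L]),
                 supp_paired = sum(paired[supp]),
                 supp_size = length(supp),
                 central_loop = loop_pos, has_central_loop = has_loop,
                 terminal_3p_mismatches = term_mm,
                 paired_fraction = mean(paired)),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf(paste0("<duplex_alignment> score %d | seed %d/6 WC, 3' %d paired,",
                     " loop [%s], terminal mm %d\n"),
              x$score, x$seed_paired, x$three_prime_paired,
              if (length(x$central_loop)) paste(range(x$central_loop),
                                                collapse = "-") else "",
              x$terminal_3p_mismatches))
  invisible(x)
}

#' Classify a duplex alignment into a site class
#'
#' Labels (mutually exclusive, checked in this precedence):
#' \describe{
#'   \item{tdmd_competent}{full Watson-Crick seed (positions 2-7), a
#'     central loop opposite positions 9-12, at least
#'     \code{three_prime_min} paired positions in the 3'-adjacent region
#'     13..L-3 (capped at the region size for short miRNAs), and at most
#'     \code{max_terminal_mm} unpaired nucleotides at the miRNA 3'
#'     extremity.}
#'   \item{extensive}{at least \code{extensive_frac} of all positions
#'     paired with no central loop (e.g. a perfect complement).}
#'   \item{seed_only}{full seed but fewer than \code{three_prime_min}
#'     paired positions in 13..L.}
#'   \item{none}{anything else.}
#' }
#' G:U wobbles count as paired for 3' coverage but not for the seed.
#'
#' @param aln a \code{\link{pair_duplex}} alignment.
#' @param three_prime_min required 3'-adjacent pairing (default 7).
#' @param extensive_frac paired fraction for the extensive class.
#' @param max_terminal_mm tolerated unpaired 3'-terminal positions.
#' @return list of class \code{site_class}: label plus the score
#'   components used.
#' @export
classify_site <- function(aln, three_prime_min = 7, extensive_frac = 0.9,
                          max_terminal_mm = 2) {
  stopifnot(inherits(aln, "duplex_alignment"))
  supp_min <- min(three_prime_min, aln$supp_size)
  label <- if (aln$seed_paired == 6 && aln$has_central_loop &&
               aln$supp_paired >= supp_min &&
               aln$terminal_3p_mismatches <= max_terminal_mm) {
    "tdmd_competent"
  } else if (aln$paired_fraction >= extensive_frac && !aln$has_central_loop) {
    "extensive"
  } else if (aln$seed_paired == 6 && aln$three_prime_paired < three_prime_min) {
    "seed_only"
  } else "none"
  structure(list(label = label, seed_paired = aln$seed_paired,
                 three_prime_paired = aln$three_prime_paired,
                 supp_paired = aln$supp_paired,
                 central_loop = aln$central_loop,
                 has_central_loop = aln$has_central_loop,
                 terminal_3p_mismatches = aln$terminal_3p_mismatches,
                 paired_fraction = aln$paired_fraction),
            class = "site_class")
}

#' Scan a transcript for miRNA binding sites
#'
#' Finds every perfect match to the reverse complement of the miRNA seed
#' (positions 2-7 by default, 2-8 optionally) on the transcript's sense
#' strand, extends each match to a window wide enough for 3' pairing and
#' bulges (L + 8 nt), aligns with \code{\link{pair_duplex}} and classifies
#' with \code{\link{classify_site}}. Coordinates are 0-based half-open on
#' the given strand.
#'
#' @param mirna miRNA sequence 5' to 3'.
#' @param transcript transcript sequence (sense strand; T and U
#'   equivalent).
#' @param seed_def \code{"2-7"} or \code{"2-8"}.
#' @param window_slack extra target nucleotides beyond the miRNA length
#'   allowed in the scan window (room for target-side bulges; default 4,
#'   the default sponge bulge size). Because mismatches are cost-free,
#'   wide windows would let the 3' region pick up spurious pairing in
#'   flanking sequence, so the window is kept tight.
#' @param ... thresholds passed to \code{\link{classify_site}}.
#' @return data frame with one row per seed match: seed_start, seed_end
#'   (the exact coordinates of the seed complement on the transcript),
#'   start, end (the aligned site extent, which for weakly pairing sites
#'   can shift by a few bases because mismatches are cost-free), label,
#'   score, seed_paired, three_prime_paired, loop_span, terminal_3p_mm.
#' @export
scan_transcript <- function(mirna, transcript, seed_def = c("2-7", "2-8"),
                            window_slack = 4, ...) {
  seed_def <- match.arg(seed_def)
  check_alphabet(mirna, "miRNA")
  if (!nzchar(transcript)) stop_mirarm("empty transcript")
  m <- norm_t(mirna)
  tx <- norm_t(transcript)
  L <- nchar(m)
  if (nchar(tx) < L - 4) stop_mirarm("transcript shorter than a site")
  seed_to <- if (seed_def == "2-7") 7L else 8L
  seed_rc <- revcomp(substr(m, 2, seed_to))
  hits <- gregexpr(seed_rc, tx, fixed = TRUE)[[1]]
  hits <- hits[hits > 0]
  empty <- data.frame(seed_start = integer(0), seed_end = integer(0),
                      start = integer(0), end = integer(0),
                      label = character(0), score = integer(0),
                      seed_paired = integer(0), three_prime_paired = integer(0),
                      loop_span = character(0), terminal_3p_mm = integer(0),
                      stringsAsFactors = FALSE)
  if (length(hits) == 0) return(empty)
  rows <- lapply(hits, function(s) {
    # the seed complement pairs miRNA 2..seed_to near the site 3' end;
    # one more downstream base faces position 1, upstream bases face the
    # 3' half of the miRNA (plus bulge allowance)
    w_end <- min(nchar(tx), s + nchar(seed_rc))
    w_start <- max(1, w_end - (L + window_slack) + 1)
    window <- substr(tx, w_start, w_end)
    if (nchar(window) < L - 4) return(NULL)
    aln <- pair_duplex(m, window)
    cls <- classify_site(aln, ...)
    data.frame(seed_start = s - 1L, seed_end = s - 1L + nchar(seed_rc),
               start = w_start - 1L + aln$site_start0,
               end = w_start - 1L + aln$site_end0,
               label = cls$label, score = aln$score,
               seed_paired = aln$seed_paired,
               three_prime_paired = aln$three_prime_paired,
               loop_span = if (length(aln$central_loop))
                 paste(range(aln$central_loop), collapse = "-") else "",
               terminal_3p_mm = aln$terminal_3p_mismatches,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Scan a set of transcripts against a set of miRNAs
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param transcripts named character vector of transcript sequences.
#' @inheritParams scan_transcript
#' @return combined site table with mirna_id and transcript_id columns.
#' @export
scan_transcripts <- function(mirnas, transcripts, seed_def = c("2-7", "2-8"),
                             window_slack = 4, ...) {
  seed_def <- match.arg(seed_def)
  out <- list()
  for (mi in names(mirnas)) {
    for (ti in names(transcripts)) {
      tab <- scan_transcript(mirnas[[mi]], transcripts[[ti]],
                             seed_def = seed_def,
                             window_slack = window_slack, ...)
      if (nrow(tab))
        out[[length(out) + 1]] <- cbind(mirna_id = mi, transcript_id = ti,
                                        tab, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(mirna_id = character(0), transcript_id = character(0)))
  do.call(rbind, out)
}

#' Design a bulged miRNA sponge construct
#'
#' Builds the classic decoy architecture: \code{n_sites} identical binding
#' sites joined by \code{spacer_len}-nt spacers. Each site is the reverse
#' complement of the miRNA with a central internal loop opposite positions
#' 9-12 (the four complementary bases are replaced by eight
#' non-complementary ones, a net 4-nt insertion), so the miRNA binds
#' through its seed and 3' region but cannot be sliced. The construct is
#' verified with the package's own scanner: all \code{n_sites} sites must
#' classify as \code{tdmd_competent}.
#'
#' @param mirna miRNA sequence 5' to 3'.
#' @param mirna_id label carried into the design.
#' @param n_sites number of binding sites (default 6).
#' @param spacer_len spacer length between sites (default 4).
#' @param spacer_seq optional fixed spacer sequence (length
#'   \code{spacer_len}); random if omitted.
#' @param bulge list with \code{start}, \code{end} (miRNA positions looped
#'   out, default 9-12) and \code{insert} (net inserted target
#'   nucleotides, default 4). The loop must not touch the seed
#'   (positions 2-8).
#' @param seed integer seed for the (deterministic) random choices.
#' @return object of class \code{sponge_design}: site and construct
#'   sequences, 0-based half-open site coordinates, and the verifying
#'   site table.
#' @export
design_sponge <- function(mirna, mirna_id = "miRNA", n_sites = 6,
                          spacer_len = 4, spacer_seq = NULL,
                          bulge = list(start = 9, end = 12, insert = 4),
                          seed = 1L) {
  check_alphabet(mirna, "miRNA")
  if (bulge$start <= 8)
    stop_mirarm("bulge would collide with the seed (positions 2-8)")
  m <- norm_t(mirna)
  L <- nchar(m)
  if (bulge$end >= L - 6)
    stop_mirarm("bulge would erode the 3'-adjacent pairing region")
  if (!is.null(spacer_seq) && nchar(spacer_seq) != spacer_len)
    stop_mirarm("spacer_seq must have length spacer_len")
  with_seed(child_seed(seed, 131), {
    seed_rc <- revcomp(substr(m, 2, 7))
    for (attempt in 1:50) {
      site <- build_site(m, "tdmd_competent", loop_start = bulge$start,
                        loop_end = bulge$end, loop_insert = bulge$insert)
      if (lengths(gregexpr(seed_rc, site, fixed = TRUE)) != 1) next
      spacer <- if (is.null(spacer_seq)) random_seq(spacer_len)
                else norm_t(spacer_seq)
      construct <- paste(rep(site, n_sites), collapse = spacer)
      site_len <- nchar(site)
      starts <- (seq_len(n_sites) - 1L) * (site_len + spacer_len)
      tab <- scan_transcript(m, construct)
      ok <- nrow(tab) == n_sites && all(tab$label == "tdmd_competent") &&
        all(sort(tab$start) == starts)
      if (ok) {
        return(structure(list(mirna_id = mirna_id, mirna = m,
                              site = site, spacer = spacer,
                              construct = construct, n_sites = n_sites,
                              site_coords = data.frame(start = starts,
                                                       end = starts + site_len),
                              site_table = tab),
                         class = "sponge_design"))
      }
      if (!is.null(spacer_seq) && attempt > 25)
        stop_mirarm("could not build a clean sponge with the fixed spacer")
    }
    stop_mirarm("sponge design failed verification after 50 attempts")
  })
}

#' @export
print.sponge_design <- function(x, ...) {
  cat(sprintf("<sponge_design> %s: %dx %d-nt bulged sites, %d-nt spacers (%d nt)\n",
              x$mirna_id, x$n_sites, nchar(x$site), nchar(x$spacer),
              nchar(x$construct)))
  invisible(x)
}
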