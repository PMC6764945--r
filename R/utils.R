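# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random state. All generators funnel their randomness through this so that
# one integer seed pins an entire simulated study.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from the master seed. Offsets are
# fixed per generator so adding patients to one table never reshuffles
# another. Kept below 2^31 - 1.
child_seed <- function(seed, offset) {
  (as.numeric(seed) * 1000 + offset) %% 2147483647
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_mirarm <- function(..., class = "mirarmkit_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_proportions <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop_mirarm(what, " must be non-negative and sum to 1",
                class = "mirarmkit_config_error")
  invisible(p)
}

# Largest-remainder apportionment of n items to proportions p; exact,
# deterministic, sums to n.
apportion <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

## -- sequence helpers (RNA/DNA strings, vectorised over characters) --------

BASES_DNA <- c("A", "C", "G", "T")

norm_t <- function(x) chartr("Uu", "Tt", toupper(x))

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_to_seq <- function(ch) paste0(ch, collapse = "")

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a nucleotide sequence
#'
#' U is treated as T; the result is returned in the DNA (T) alphabet.
#'
#' @param x a sequence string (RNA or DNA).
#' @return the reverse complement as a DNA string.
#' @export
revcomp <- function(x) {
  ch <- rev(seq_chars(norm_t(x)))
  chars_to_seq(unname(comp_base[ch]))
}

to_rna <- function(x) chartr("Tt", "Uu", x)

check_alphabet <- function(x, what = "sequence") {
  ch <- seq_chars(norm_t(x))
  if (length(ch) == 0 || !all(ch %in% BASES_DNA))
    stop_mirarm("invalid ", what, " alphabet (need A/C/G/U or A/C/G/T)")
  invisible(x)
}

random_seq <- function(n) chars_to_seq(sample(BASES_DNA, n, replace = TRUE))

# A base that is neither the Watson-Crick complement of `b` nor its G:U
# wobble partner -- used to plant guaranteed mismatches.
noncomp_base <- function(b) {
  bad <- comp_base[b]
  if (b == "G") bad <- c(bad, "T")
  if (b == "T") bad <- c(bad, "G")
  ok <- setdiff(BASES_DNA, c(bad))
  sample(ok, 1)
}

## -- tabular I/O ------------------------------------------------------------

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
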