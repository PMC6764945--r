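# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: the aligner oracle is a direct top-down
# recursion over the scoring definition, and the tiny enumerator explores
# every alignment explicitly.

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

oracle_pair_score <- function(a, b) {
  if (COMP[[a]] == b) return(2)
  if ((a == "G" && b == "T") || (a == "T" && b == "G")) return(1)
  0
}

# Best alignment score of mirna against site under WC +2 / GU +1 /
# mismatch 0 / bulge open -2, extend -1, miRNA aligned end to end,
# free target overhangs on both sides. Memoized recursion.
oracle_align_score <- function(mirna, site) {
  a <- strsplit(chartr("U", "T", toupper(mirna)), "")[[1]]
  t <- rev(strsplit(chartr("U", "T", toupper(site)), "")[[1]])
  L <- length(a); m <- length(t)
  memo <- new.env(hash = TRUE)
  g <- function(i, j, prev) {
    if (i > L) return(0)
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (j <= m)
      best <- max(best, oracle_pair_score(a[i], t[j]) + g(i + 1, j + 1, "M"))
    best <- max(best, (if (prev == "X") -1 else -2) + g(i + 1, j, "X"))
    if (j <= m && i > 1)
      best <- max(best, (if (prev == "Y") -1 else -2) + g(i, j + 1, "Y"))
    memo[[key]] <- best
    best
  }
  max(vapply(1:(m + 1), function(j0) g(1, j0, "M"), 1.0))
}

# Exhaustive enumeration of every alignment (tiny sequences only);
# validates the memoized oracle itself.
enum_align_score <- function(mirna, site) {
  a <- strsplit(chartr("U", "T", toupper(mirna)), "")[[1]]
  t <- rev(strsplit(chartr("U", "T", toupper(site)), "")[[1]])
  L <- length(a); m <- length(t)
  rec <- function(i, j, prev) {
    if (i > L) return(0)
    scores <- c()
    if (j <= m)
      scores <- c(scores, oracle_pair_score(a[i], t[j]) + rec(i + 1, j + 1, "M"))
    scores <- c(scores, (if (prev == "X") -1 else -2) + rec(i + 1, j, "X"))
    if (j <= m && i > 1)
      scores <- c(scores, (if (prev == "Y") -1 else -2) + rec(i, j + 1, "Y"))
    max(scores)
  }
  max(vapply(1:(m + 1), function(j0) rec(1, j0, "M"), 1.0))
}

random_rna <- function(n) {
  paste0(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# mutate k random positions of a DNA/RNA string
mutate_seq <- function(x, k) {
  ch <- strsplit(chartr("U", "T", toupper(x)), "")[[1]]
  pos <- sample(seq_along(ch), min(k, length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
  paste0(ch, collapse = "")
}

small_ref_config <- function(seed = 1, ...) {
  args <- utils::modifyList(list(seed = seed, n_arm_pairs = 10,
                                 n_patients = 10, n_genes = 300,
                                 n_enriched = 20, n_mirnas = 3,
                                 n_reads = 500),
                            list(...))
  do.call(sim_config, args)
}
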