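toy_refs <- function() {
  # two distinct references plus one sharing its mature with the first
  m1 <- "TGAGGTAGTAGGTTGTATAGTT"
  m2 <- "ACCCGTAGATCCGAACTTGTGA"
  up <- strrep("C", 25); dn1 <- paste0("GG", strrep("C", 23))
  dn2 <- paste0("AT", strrep("C", 23))
  data.frame(mirna_id = c("mirA", "mirB"),
             mature = c(m1, m2),
             precursor = c(paste0(up, m1, dn1), paste0(up, m2, dn2)),
             mature_start = 26L, stringsAsFactors = FALSE)
}

test_that("read filter applies the length boundary and entropy cutoff", {
  reads <- c(r13 = strrep("ACGT", 4), r14 = paste0(strrep("ACGT", 3), "AC"),
             homo = strrep("A", 16))
  reads["r13"] <- substr(reads["r13"], 1, 13)
  expect_equal(dinucleotide_entropy(strrep("A", 16)), 0)
  out <- filter_reads(reads, min_len = 14, entropy_cutoff = 0.5)
  expect_identical(names(out$reads), "r14")   # 13-nt and homopolymer removed
  expect_equal(out$n_removed, 2)
  # homopolymer survives only a zero cutoff
  expect_equal(length(filter_reads(reads, 14, 0)$reads), 2)
})

test_that("default filter removes under 1% of a generated library", {
  cfg <- small_ref_config(seed = 51, n_reads = 2000)
  rd <- gen_small_rna_reads(cfg, gen_references(cfg))
  out <- filter_reads(rd$reads)
  expect_lt(out$fraction_removed, 0.01)
})

test_that("anchored assignment handles exact, mutated and ambiguous reads", {
  refs <- toy_refs()
  # exact mature: single hit, weight 1, zero mismatches
  calls <- assign_reads(c(r1 = refs$mature[1]), refs)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$mirna_id, "mirA")
  expect_equal(calls$mismatches, 0)
  expect_equal(calls$weight, 1)
  # three substitutions exceed max_mm = 2
  withr::with_seed(50, bad <- mutate_seq(refs$mature[2], 3))
  expect_equal(nrow(assign_reads(setNames(bad, "r2"), refs)), 0)
  # two identical-sequence references split the weight equally
  refs2 <- rbind(refs, data.frame(mirna_id = "mirA2", mature = refs$mature[1],
                                  precursor = refs$precursor[1],
                                  mature_start = 26L))
  calls2 <- assign_reads(c(r3 = refs$mature[1]), refs2)
  expect_equal(nrow(calls2), 2)
  expect_equal(calls2$weight, c(0.5, 0.5))
  expect_error(assign_reads(c(r = "ACGT"), refs[0, ]), "empty reference")
})

test_that("assignment weights are conserved per read", {
  cfg <- small_ref_config(seed = 52, n_reads = 400, read_error_rate = 0.01)
  refs <- gen_references(cfg)
  rd <- gen_small_rna_reads(cfg, refs)
  calls <- assign_reads(rd$reads, refs$mirnas)
  w <- tapply(calls$weight, calls$read_id, sum)
  expect_true(all(abs(w - 1) < 1e-9))
  expect_equal(sum(calls$weight), length(unique(calls$read_id)))
})

test_that("anchored matcher agrees with a brute-force window scan", {
  refs <- toy_refs()
  withr::with_seed(53, {
    # random perturbations of the references and random junk
    reads <- c(vapply(1:30, function(i)
      mutate_seq(refs$mature[sample(2, 1)], sample(0:3, 1)), ""),
      vapply(1:10, function(i)
        paste0(sample(c("A","C","G","T"), 22, TRUE), collapse = ""), ""))
    names(reads) <- sprintf("r%02d", seq_along(reads))
  })
  calls <- assign_reads(reads, refs, max_offset = 3)
  # brute force: all 5' offsets in [-3, 3], count mismatches in the mature
  # overlap, require <= 2
  brute_best <- function(s) {
    best <- Inf
    for (k in 1:2) {
      mat <- strsplit(refs$mature[k], "")[[1]]
      rch <- strsplit(s, "")[[1]]
      for (off in -3:3) {
        mpos <- off + seq_along(rch)
        ok <- mpos >= 1 & mpos <= length(mat)
        if (!any(ok)) next
        best <- min(best, sum(rch[ok] != mat[mpos[ok]]))
      }
    }
    best
  }
  for (nm in names(reads)) {
    b <- brute_best(reads[[nm]])
    got <- calls[calls$read_id == nm, ]
    if (b > 2) expect_equal(nrow(got), 0, info = nm)
    else expect_equal(min(got$mismatches), b, info = nm)
  }
})

test_that("isoform classes and tail types follow their definitions", {
  refs <- toy_refs()
  m1 <- refs$mature[1]  # precursor continues "GG"
  reads <- c(canon = m1,
             trim2 = substr(m1, 1, nchar(m1) - 2),
             tail_nt = paste0(m1, "AA"),       # downstream is GG -> non-templated
             tail_t = paste0(m1, "GG"),        # matches downstream -> templated
             tail_mix = paste0(m1, "GA"),
             five_p = substr(m1, 2, nchar(m1)))
  calls <- classify_isoform(assign_reads(reads, refs), refs)
  got <- setNames(calls$class, calls$read_id)
  expect_equal(got[["canon"]], "canonical")
  expect_equal(got[["trim2"]], "trimmed")
  expect_equal(calls$trim3[calls$read_id == "trim2"], 2)
  expect_equal(got[["tail_nt"]], "tailed")
  expect_equal(calls$tail_type[calls$read_id == "tail_nt"], "non_templated")
  expect_equal(calls$tail_type[calls$read_id == "tail_t"], "templated")
  expect_equal(calls$tail_type[calls$read_id == "tail_mix"], "mixed")
  expect_equal(got[["five_p"]], "five_prime_variant")
})

test_that("profile normalization matches the printed formula", {
  refs <- toy_refs()
  calls <- data.frame(read_id = sprintf("r%d", 1:10), mirna_id = "mirA",
                      mismatches = 0, offset5 = 0, trim3 = 0, tail_seq = "",
                      weight = 1)
  calls <- classify_isoform(calls, refs)
  # count 10 in a library of 100, totals (100, 200): 10/100 * 150 = 15
  prof <- build_profile(calls, library_total = 100,
                        all_library_totals = c(100, 200))
  canon <- prof[prof$class == "canonical", ]
  expect_equal(canon$count, 10)
  expect_equal(canon$normalized, 15)
  expect_equal(canon$log2_normalized, 4)      # log2(16)
  # single library: normalized equals the raw count
  p1 <- build_profile(calls)
  expect_equal(p1$normalized[p1$class == "canonical"], 10)
  expect_error(build_profile(calls, library_total = 0), "positive")
})

test_that("per-miRNA proportions sum to one and classes are exclusive", {
  cfg <- small_ref_config(seed = 54, n_reads = 1000)
  refs <- gen_references(cfg)
  rd <- gen_small_rna_reads(cfg, refs)
  calls <- classify_isoform(assign_reads(rd$reads, refs$mirnas), refs$mirnas)
  prof <- build_profile(calls)
  sums <- tapply(prof$proportion, prof$mirna_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(sum(prof$count), sum(calls$weight[calls$class != "five_prime_variant"]))
})

test_that("profile comparison is antisymmetric and detects planted shifts", {
  cfg_a <- small_ref_config(seed = 55, n_reads = 4000)
  cfg_b <- small_ref_config(seed = 56, n_reads = 4000,
                            isoform_mixture = c(canonical = 0.5, trimmed = 0.4,
                                                tailed_nt = 0.05,
                                                tailed_t = 0.05))
  refs <- gen_references(cfg_a)
  pa <- build_profile(classify_isoform(
    assign_reads(gen_small_rna_reads(cfg_a, refs)$reads, refs$mirnas),
    refs$mirnas))
  pb <- build_profile(classify_isoform(
    assign_reads(gen_small_rna_reads(cfg_b, refs)$reads, refs$mirnas),
    refs$mirnas))
  cmp <- compare_profiles(pa, pb)
  expect_equal(compare_profiles(pb, pa)$delta, -cmp$delta)
  expect_equal(compare_profiles(pa, pa)$delta, rep(0, nrow(cmp)))
  trm <- cmp[cmp$class == "trimmed", ]
  expect_true(all(trm$delta > 0.1))
  expect_true(all(trm$p_value < 1e-6))
  expect_true(all(trm$increased))
})
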