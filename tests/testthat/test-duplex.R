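test_that("perfect reverse complement pairs every position Watson-Crick", {
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  aln <- pair_duplex(m, revcomp(m))
  expect_true(all(aln$states == "wc"))
  expect_equal(aln$score, 2 * nchar(m))
  expect_equal(nrow(aln$target_insertions), 0)
  expect_equal(aln$site_start0, 0)
  expect_equal(aln$site_end0, nchar(m))
  expect_equal(classify_site(aln)$label, "extensive")
})

test_that("a 4-nt insertion opposite positions 9-12 is resolved as a central bulge", {
  withr::with_seed(20, {
    m <- random_rna(22)
    rc <- strsplit(revcomp(m), "")[[1]]
    # insert 4 nt between the complements of positions 9 and 8
    # (complement of position i sits at site index L - i + 1)
    ins_at <- 22 - 9 + 1
    site <- paste0(paste(rc[1:ins_at], collapse = ""), "AAAA",
                   paste(rc[(ins_at + 1):22], collapse = ""))
    aln <- pair_duplex(m, site)
    expect_equal(sum(aln$target_insertions$length), 4)
    expect_true(all(aln$target_insertions$after_mir_pos %in% 8:12))
    expect_true(aln$has_central_loop)
  })
})

test_that("alignment score equals the independent recursive oracle", {
  # the enumerator validates the oracle on tiny instances first
  withr::with_seed(21, {
    for (i in 1:10) {
      a <- random_rna(6); t <- random_rna(sample(4:8, 1))
      expect_equal(oracle_align_score(a, t), enum_align_score(a, t))
    }
    # then the production aligner against the oracle at miRNA scale
    for (i in 1:50) {
      L <- sample(18:26, 1)
      m <- random_rna(L)
      site <- switch(sample(3, 1),
                     mutate_seq(revcomp(m), sample(0:6, 1)),
                     paste0(mutate_seq(revcomp(m), 2),
                            paste(sample(c("A","C","G","T"), 4, TRUE),
                                  collapse = "")),
                     paste0(sample(c("A","C","G","T"), L + sample(-4:8, 1),
                                   TRUE), collapse = ""))
      expect_equal(pair_duplex(m, site)$score, oracle_align_score(m, site),
                   info = paste(m, site))
    }
  })
})

test_that("site classes follow the TDMD architecture rules", {
  withr::with_seed(22, {
    m <- random_rna(22)
    md <- chartr("U", "T", m)
    # seed pairing only
    s_seed <- mirarmkit:::build_site(md, "seed_only")
    cls <- classify_site(pair_duplex(m, s_seed))
    expect_equal(cls$label, "seed_only")
    expect_equal(cls$seed_paired, 6)
    # seed + 3' adjacent pairing + central loop (+2 terminal mismatches)
    s_tdmd <- mirarmkit:::build_site(md, "tdmd_competent")
    ch <- strsplit(s_tdmd, "")[[1]]
    # the site 5' end faces the miRNA 3' end: mismatch the two terminal nt
    mch <- strsplit(md, "")[[1]]
    for (k in 1:2) ch[k] <- mirarmkit:::noncomp_base(mch[22 - k + 1])
    cls2 <- classify_site(pair_duplex(m, paste(ch, collapse = "")))
    expect_equal(cls2$label, "tdmd_competent")
    expect_lte(cls2$terminal_3p_mismatches, 2)
    expect_true(cls2$has_central_loop)
    # three or more terminal mismatches break competence
    for (k in 1:4) ch[k] <- mirarmkit:::noncomp_base(mch[22 - k + 1])
    cls3 <- classify_site(pair_duplex(m, paste(ch, collapse = "")))
    expect_false(cls3$label == "tdmd_competent")
  })
})

test_that("classification is monotone in 3' pairing", {
  withr::with_seed(23, {
    m <- random_rna(22)
    md <- chartr("U", "T", m)
    s <- mirarmkit:::build_site(md, "seed_only")
    lab0 <- classify_site(pair_duplex(m, s))$label
    expect_equal(lab0, "seed_only")
    # progressively restore 3' complementarity; seed_only may become
    # tdmd-competent or none (if partial), but never loses its seed call
    ch <- strsplit(s, "")[[1]]
    mch <- strsplit(md, "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    labs <- character(0)
    for (i in 13:22) {
      ch[22 - i + 1] <- comp[[mch[i]]]
      labs <- c(labs, classify_site(pair_duplex(m, paste(ch, collapse = "")))$label)
    }
    expect_false(any(labs == "extensive"))   # central region still unpaired
    expect_equal(labs[length(labs)], "tdmd_competent")
  })
})

test_that("scanner finds planted sites at their recorded coordinates", {
  cfg <- small_ref_config(seed = 24)
  refs <- gen_references(cfg)
  truth <- refs$truth
  for (r in seq_len(nrow(truth))) {
    mi <- match(truth$mirna_id[r], refs$mirnas$mirna_id)
    tab <- scan_transcript(refs$mirnas$mature[mi],
                           refs$transcripts$sequence[
                             match(truth$transcript_id[r],
                                   refs$transcripts$transcript_id)])
    if (truth$site_class[r] == "none") {
      expect_equal(nrow(tab), 0)
    } else {
      expect_equal(nrow(tab), 1)
      expect_equal(tab$label, truth$site_class[r])
      # the seed anchor is geometric and always exact
      expect_equal(tab$seed_start, truth$seed_start[r])
      expect_equal(tab$seed_end, truth$seed_end[r])
      # the full extent is exact for sites with designed 3' pairing;
      # for seed-only sites it may drift where flanks pair by chance
      if (truth$site_class[r] != "seed_only") {
        expect_equal(tab$start, truth$start[r])
        expect_equal(tab$end, truth$end[r])
      }
    }
  }
})

test_that("no spurious calls on the antisense strand", {
  cfg <- small_ref_config(seed = 25)
  refs <- gen_references(cfg)
  tx <- refs$transcripts$sequence[refs$truth$site_class == "extensive"][1]
  mi <- refs$mirnas$mature[match(refs$truth$mirna_id[
    refs$truth$site_class == "extensive"][1], refs$mirnas$mirna_id)]
  expect_gt(nrow(scan_transcript(mi, tx)), 0)
  rc_hits <- scan_transcript(mi, revcomp(tx))
  expect_true(nrow(rc_hits) == 0 || all(rc_hits$label == "none"))
})

test_that("empty or degenerate scanner inputs are handled", {
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  expect_error(scan_transcript(m, ""), "empty transcript")
  # transcript with no seed match -> empty table
  expect_equal(nrow(scan_transcript(m, strrep("A", 100))), 0)
  expect_error(pair_duplex("UGAG", "CUCA"), "18-26")
  expect_error(pair_duplex(m, strrep("A", 40)), "site length")
  expect_error(pair_duplex("UGAXGUAGUAGGUUGUAUAGUU", revcomp(m)), "alphabet")
})

test_that("sponge construct has the stated geometry and verifies", {
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  sp <- design_sponge(m, "let-7", seed = 3)
  L <- nchar(m)
  expect_equal(nchar(sp$site), L + 4)
  expect_equal(nchar(sp$construct), 6 * (L + 4) + 5 * 4)
  tab <- scan_transcript(m, sp$construct)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$label == "tdmd_competent"))
  expect_equal(sort(tab$start), sp$site_coords$start)
})

test_that("spacer choice does not affect site classification", {
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  sp1 <- design_sponge(m, "x", spacer_seq = "ACCA", seed = 5)
  sp2 <- design_sponge(m, "x", spacer_seq = "CAAC", seed = 5)
  expect_identical(sp1$site_table$label, sp2$site_table$label)
  expect_identical(sp1$site, sp2$site)
})

test_that("bulge specifications colliding with the seed are rejected", {
  m <- "UGAGGUAGUAGGUUGUAUAGUU"
  expect_error(design_sponge(m, bulge = list(start = 5, end = 8, insert = 4)),
               "seed")
  expect_error(design_sponge(m, bulge = list(start = 16, end = 20, insert = 4)),
               "3'-adjacent")
})
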