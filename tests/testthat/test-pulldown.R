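abund <- function(bp, cp, bi, ci) {
  data.frame(gene_id = sprintf("g%d", seq_along(bp)), bait_pd = bp,
             ctrl_pd = cp, bait_input = bi, ctrl_input = ci)
}

test_that("expression filter keeps exactly genes above the floor somewhere", {
  tab <- data.frame(gene_id = c("a", "b", "c", "d"),
                    lib1 = c(0.05, 0.05, 0, 5),
                    lib2 = c(0.08, 0.2, 0, 0))
  out <- filter_expressed(tab, 0.1)
  expect_identical(out$gene_id, c("b", "d"))   # (0.05, 0.08) removed
  expect_identical(filter_expressed(out, 0.1), out)  # idempotent
  # min_level = 0: any positive value survives
  expect_identical(filter_expressed(tab, 0)$gene_id, c("a", "b", "d"))
  expect_error(filter_expressed(tab, -1), "non-negative")
})

test_that("enrichment ratio matches the printed formula by hand", {
  # (10/5) / (2/2) = 2
  r <- enrichment_ratio(abund(10, 5, 2, 2), pseudocount = 0)
  expect_equal(r$er, 2)
  # all four equal -> ER = 1
  expect_equal(enrichment_ratio(abund(7, 7, 7, 7), pseudocount = 0)$er, 1)
  # strict candidate boundary at 1.2
  r2 <- enrichment_ratio(abund(c(12.5, 12), c(10, 10), c(1, 1), c(1, 1)),
                         pseudocount = 0)
  expect_equal(r2$er, c(1.25, 1.2))
  expect_identical(r2$candidate, c(TRUE, FALSE))
})

test_that("ER agrees with brute-force recomputation on random tables", {
  withr::with_seed(10, {
    for (rep in 1:5) {
      n <- 100
      tab <- abund(runif(n, 0, 50), runif(n, 0.1, 50),
                   runif(n, 0.1, 50), runif(n, 0.1, 50))
      eps <- 0.01
      r <- enrichment_ratio(tab, pseudocount = eps)
      brute <- vapply(seq_len(n), function(i)
        ((tab$bait_pd[i] + eps) / (tab$ctrl_pd[i] + eps)) /
          ((tab$bait_input[i] + eps) / (tab$ctrl_input[i] + eps)), 1.0)
      expect_equal(r$er, brute, tolerance = 1e-12)
    }
  })
})

test_that("ER is invariant to consistent library rescaling at eps = 0", {
  withr::with_seed(11, {
    tab <- abund(runif(20, 1, 50), runif(20, 1, 50),
                 runif(20, 1, 50), runif(20, 1, 50))
    r0 <- enrichment_ratio(tab, pseudocount = 0)
    # depth rescaling applied to a bait pull-down/input pair cancels, as
    # does rescaling the control pair or all four libraries together
    tab2 <- tab
    tab2$bait_pd <- tab$bait_pd * 7.3
    tab2$bait_input <- tab$bait_input * 7.3
    tab2$ctrl_pd <- tab$ctrl_pd * 0.2
    tab2$ctrl_input <- tab$ctrl_input * 0.2
    expect_equal(enrichment_ratio(tab2, pseudocount = 0)$er, r0$er,
                 tolerance = 1e-12)
    tab3 <- tab
    tab3[, -1] <- tab3[, -1] * 3.7
    expect_equal(enrichment_ratio(tab3, pseudocount = 0)$er, r0$er,
                 tolerance = 1e-12)
  })
})

test_that("zero denominators require a pseudocount", {
  expect_error(enrichment_ratio(abund(1, 0, 1, 1), pseudocount = 0),
               "pseudocount")
  expect_silent(enrichment_ratio(abund(1, 0, 1, 1), pseudocount = 0.01))
})

test_that("log2 fold change and DE flags follow the stated rules", {
  lfc <- log2fc_table(c(15, 5, 7), c(3, 5, 1), pseudo = 1)
  expect_equal(lfc$log2fc, c(2, 0, 2))      # (15+1)/(3+1) = 4
  f <- flag_de(lfc, fdr = c(1e-5, 1e-5, 0.5))
  expect_identical(f$de_flag, c(TRUE, FALSE, FALSE))
  # |log2FC| = 1 exactly is not flagged (strict >)
  f2 <- flag_de(log2fc_table(7, 3, pseudo = 1), fdr = 1e-9)
  expect_equal(f2$log2fc, 1)
  expect_false(f2$de_flag)
  expect_error(log2fc_table(-1, 2), "non-negative")
})

test_that("potential targets need enrichment and depletion", {
  rec <- data.frame(gene_id = c("a", "b", "c"),
                    er = c(3, 3, 1), candidate = c(TRUE, TRUE, FALSE),
                    log2fc = c(-0.5, 0.5, -2))
  out <- define_potential_targets(rec)
  expect_identical(out$potential_target, c(TRUE, FALSE, FALSE))
  rec$de_flag <- c(FALSE, TRUE, TRUE)
  expect_identical(define_potential_targets(rec, require_de = TRUE)$potential_target,
                   c(FALSE, FALSE, FALSE))
})

test_that("KS shift test behaves at the degenerate extremes", {
  x <- c(1, 2, 3, 4, 5)
  same <- cdf_shift_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  disjoint <- cdf_shift_test(rep(0, 6), rep(1, 6))
  expect_equal(disjoint$statistic, 1)
  expect_equal(disjoint$direction, -1)
  # two-sided D is symmetric in the samples
  withr::with_seed(12, {
    a <- rnorm(30); b <- rnorm(30, 0.5)
    expect_equal(cdf_shift_test(a, b)$statistic,
                 cdf_shift_test(b, a)$statistic)
  })
  expect_error(cdf_shift_test(1:3, 1:10), "at least 5")
})

test_that("cutoff sweep yields nested sets and monotone medians on spiked data", {
  cfg <- sim_config(seed = 13, n_genes = 2000, n_enriched = 100)
  pd <- gen_pulldown(cfg)
  er <- enrichment_ratio(pd$abundance)
  lfc <- log2fc_table(pd$abundance$oe, pd$abundance$oe_ctrl,
                      gene_id = pd$abundance$gene_id)
  rec <- cbind(er, log2fc = lfc$log2fc)
  sw <- cutoff_sweep(rec, c(1.2, 2, 2.5))
  sizes <- sw$summary$n
  expect_true(all(diff(sizes) <= 0))
  for (i in 2:3)
    expect_true(all(sw$sets[[i]] %in% sw$sets[[i - 1]]))
  # medians saturate near the planted depletion at high cutoffs; require
  # a non-increasing trend up to counting noise
  expect_true(all(diff(sw$summary$median_log2fc) <= 0.05))
  expect_lt(sw$summary$median_log2fc[3], median(rec$log2fc))
  expect_error(cutoff_sweep(rec, c(2, 1.2)), "ascending")
})

test_that("spiked genes are recovered as potential targets", {
  cfg <- sim_config(seed = 14, n_genes = 2000, n_enriched = 100)
  pd <- gen_pulldown(cfg)
  expressed <- filter_expressed(pd$abundance)
  er <- enrichment_ratio(expressed)
  lfc <- log2fc_table(expressed$oe, expressed$oe_ctrl,
                      gene_id = expressed$gene_id)
  rec <- define_potential_targets(cbind(er, log2fc = lfc$log2fc))
  truth <- pd$truth$enriched[match(rec$gene_id, pd$truth$gene_id)]
  recall <- sum(rec$potential_target & truth) / sum(pd$truth$enriched)
  precision <- sum(rec$potential_target & truth) / sum(rec$potential_target)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})
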