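test_that("continuity-corrected Wilson interval reproduces published agreement CIs", {
  # 38/52 concordant pairs -> (0.587, 0.840); 35/52 -> lower 0.528. The
  # printed upper bound for 35/52 is 0.792 while the computed bound is
  # 0.792844 (truncated, not rounded, in print); asserted at 1e-3.
  ci1 <- wilson_cc_ci(38, 52)
  expect_equal(round(unname(ci1), 3), c(0.587, 0.840))
  ci2 <- wilson_cc_ci(35, 52)
  expect_equal(round(unname(ci2[1]), 3), 0.528)
  expect_lt(abs(ci2[2] - 0.792), 1.5e-3)

  expect_identical(unname(wilson_cc_ci(0, 10)[1]), 0)
  expect_identical(unname(wilson_cc_ci(10, 10)[2]), 1)
  expect_error(wilson_cc_ci(3, 0), "at least 1")
  expect_error(wilson_cc_ci(5, 4))
})

test_that("wilson_cc_ci matches numeric inversion of the corrected score test", {
  for (n in c(5, 12, 23, 30)) {
    for (k in 0:n) {
      got <- wilson_cc_ci(k, n)
      want <- wilson_cc_oracle(k, n)
      expect_equal(unname(got[1]), want[1], tolerance = 1e-9)
      expect_equal(unname(got[2]), want[2], tolerance = 1e-9)
    }
  }
})

test_that("wilson interval contains k/n and narrows with n at fixed ratio", {
  for (n in c(10, 25, 60)) for (k in c(0, 3, n %/% 2, n)) {
    ci <- wilson_cc_ci(k, n)
    expect_lte(ci[1], k / n); expect_gte(ci[2], k / n)
  }
  widths <- vapply(c(1, 2, 4, 8, 16), function(m)
    diff(wilson_cc_ci(3 * m, 10 * m)), numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("agreement_stats counts concordant patients", {
  a <- setNames(rep(c("LR", "HR"), c(30, 22)), sprintf("P%02d", 1:52))
  expect_identical(agreement_stats(a, a)$proportion, 1)
  b <- a; flips <- sprintf("P%02d", 1:14)
  b[flips] <- ifelse(a[flips] == "LR", "HR", "LR")
  ag <- agreement_stats(a, b)
  expect_identical(ag$k, 38L + 0L)
  expect_equal(round(ag$proportion, 3), 0.731)
  expect_equal(round(ag$ci_low, 3), 0.587)
  all_flip <- setNames(ifelse(a == "LR", "HR", "LR"), names(a))
  expect_identical(agreement_stats(a, all_flip)$proportion, 0)
  expect_error(agreement_stats(a, a[-1]), "unmatched")
})

test_that("proportion difference CI: published cross-cohort check and symmetry", {
  # high-risk fractions 38/115 = 0.33 vs 53/206 = 0.26: not significant
  r <- proportion_diff_ci(38, 115, 53, 206)
  expect_lt(r$low, 0); expect_gt(r$high, 0)
  expect_false(r$significant)

  s <- proportion_diff_ci(20, 50, 20, 50)
  expect_equal(s$low, -s$high, tolerance = 1e-12)

  e <- proportion_diff_ci(50, 50, 0, 50)
  expect_gt(e$low, 0); expect_true(e$significant)
  expect_error(proportion_diff_ci(1, 0, 1, 5), "at least 1")
})

test_that("hypergeometric overlap tail matches exhaustive enumeration", {
  # |A| = |B| = 3 in a universe of 10: enumerate all C(10,3) draws of B
  # against a fixed A and count overlaps
  universe <- letters[1:10]
  A <- letters[1:3]
  draws <- combn(universe, 3)
  ov <- apply(draws, 2, function(b) length(intersect(A, b)))
  # observed overlap 3 (B = A): tail probability by direct enumeration
  expect_equal(hypergeom_overlap(A, A, 10), mean(ov >= 3), tolerance = 1e-12)
  # observed overlap 2: use phyper-free enumeration as the expected value
  expect_equal(unname(phyper(1, 3, 7, 3, lower.tail = FALSE)),
               mean(ov >= 2), tolerance = 1e-12)
  # zero overlap -> upper tail at 0 is 1
  expect_identical(hypergeom_overlap(letters[1:3], letters[4:6], 10), 1)
  expect_identical(hypergeom_overlap(universe, universe, 10), 1)
  expect_error(hypergeom_overlap(letters[1:5], letters[6:10], 8), "universe")
})

make_cpg_inputs <- function() {
  sim <- small_sim(seed = 7, n = 80, genes = 30, signal = 8)
  clin <- sim$cohort$clin
  pt <- suppressWarnings(batch_scan(sim$cohort$pt, clin[clin$tissue == "PT", ],
                                    tissue = "PT"))
  at <- suppressWarnings(batch_scan(sim$cohort$at, clin[clin$tissue == "AT", ],
                                    tissue = "AT"))
  list(pt = pt, at = at, pairing = sim$cohort$pairing)
}

test_that("select_cpg applies the design-concordance and threshold rules", {
  inp <- make_cpg_inputs()
  cfg <- pipeline_config()
  cpg <- select_cpg(inp$pt, inp$at, inp$pairing, cfg)
  rpt <- inp$pt$results; rat <- inp$at$results
  for (g in cpg$gene_id) {
    expect_identical(rpt$design[rpt$gene_id == g], rat$design[rat$gene_id == g])
    expect_lte(rpt$wald_p[rpt$gene_id == g], cfg$alpha_pre)
    expect_lte(rat$wald_p[rat$gene_id == g], cfg$alpha_pre)
  }
  # every scored gene NOT selected violates at least one rule
  for (g in setdiff(intersect(rpt$gene_id, rat$gene_id), cpg$gene_id)) {
    viol <- rpt$design[rpt$gene_id == g] != rat$design[rat$gene_id == g] ||
      rpt$wald_p[rpt$gene_id == g] > cfg$alpha_pre ||
      rat$wald_p[rat$gene_id == g] > cfg$alpha_pre
    expect_true(viol)
  }
  # agreement n equals the number of PT/AT-paired patients
  if (nrow(cpg) > 0)
    expect_true(all(cpg$agreement_n == sum(!is.na(inp$pairing$at_sample))))
  # symmetric in tissue order for the gene set (pairing columns swapped too)
  pairing_rev <- data.frame(patient_id = inp$pairing$patient_id,
                            pt_sample = inp$pairing$at_sample,
                            at_sample = inp$pairing$pt_sample,
                            stringsAsFactors = FALSE)
  cpg_rev <- select_cpg(inp$at, inp$pt, pairing_rev, cfg)
  expect_identical(sort(cpg$gene_id), sort(cpg_rev$gene_id))
  # partition attributes
  expect_setequal(c(attr(cpg, "design1"), attr(cpg, "design2")), cpg$gene_id)
})

test_that("select_cpg on disjoint gene sets warns and returns empty", {
  inp <- make_cpg_inputs()
  at2 <- inp$at
  at2$results$gene_id <- paste0("X_", at2$results$gene_id)
  expect_warning(out <- select_cpg(inp$pt, at2, inp$pairing), "no genes")
  expect_identical(nrow(out), 0L)
})
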