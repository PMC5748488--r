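test_that("gene_vote and swvg_score follow the documented rules", {
  expect_identical(gene_vote(5, 4, 2L), 1L)
  expect_identical(gene_vote(5, 4, 1L), 0L)
  expect_identical(gene_vote(4, 4, 2L), 0L)  # boundary falls on the <= side
  expect_identical(gene_vote(4, 4, 1L), 1L)

  expect_identical(swvg_score(c(0, 0, 0), c(1, 2, 3)), 0)
  expect_identical(swvg_score(c(1, 1, 1), c(1, 2, 3)), 1)
  expect_identical(swvg_score(c(1, 1, 0, 0), rep(2, 4)), 0.5)
  expect_error(swvg_score(c(1, 0), c(0, 0)), "all-zero")
  expect_error(swvg_score(c(1, 0), c(1, 2, 3)), "misaligned")

  # score monotonicity: flipping any vote 0 -> 1 never decreases the score
  set.seed(8)
  w <- runif(10); v <- rbinom(10, 1, 0.5)
  s0 <- swvg_score(v, w)
  for (j in which(v == 0)) {
    v2 <- v; v2[j] <- 1
    expect_gte(swvg_score(v2, w), s0)
  }
})

fit_fixture <- function(seed = 21) {
  sim <- small_sim(seed = seed, n = 80, genes = 60, signal = 10)
  clin <- sim$cohort$clin
  spt <- clin[clin$tissue == "PT", ]
  sc <- suppressWarnings(batch_scan(sim$cohort$pt, spt, tissue = "PT"))
  list(sim = sim, surv = spt, scan = sc)
}

test_that("single-candidate model reduces to the gene's own split", {
  fx <- fit_fixture()
  cand <- fx$scan$results[order(fx$scan$results$wald_p), ][1, , drop = FALSE]
  m <- fit_swvg(cand, fx$sim$cohort$pt, fx$surv)
  expect_identical(nrow(m$genes), 1L)
  expect_identical(m$score_cutoff, 0.5)
  st <- apply_frozen(m, fx$sim$cohort$pt)
  g <- cand$gene_id
  expected <- ddg_labels(fx$sim$cohort$pt[g, st$data$sample_id],
                         cand$cutoff, cand$design)
  expect_identical(setNames(st$data$label, st$data$sample_id), expected)
})

test_that("identical candidate votes collapse to a panel of size 1", {
  fx <- fit_fixture()
  top <- fx$scan$results[order(fx$scan$results$wald_p), ][1, , drop = FALSE]
  clones <- do.call(rbind, replicate(4, top, simplify = FALSE))
  clones$gene_id <- paste0(top$gene_id, c("", "_c1", "_c2", "_c3"))
  X <- fx$sim$cohort$pt
  Xc <- rbind(X, X[rep(top$gene_id, 3), , drop = FALSE])
  rownames(Xc) <- c(rownames(X), paste0(top$gene_id, c("_c1", "_c2", "_c3")))
  m <- fit_swvg(clones, as_expr_matrix(Xc), fx$surv)
  expect_identical(nrow(m$genes), 1L)
})

test_that("no candidate passing alpha_sel is an error", {
  fx <- fit_fixture()
  cand <- fx$scan$results
  cand$wald_p <- 0.5
  expect_error(fit_swvg(cand, fx$sim$cohort$pt, fx$surv), "alpha_sel")
})

test_that("apply_frozen is idempotent on training data and order-invariant", {
  fx <- fit_fixture()
  m <- fit_swvg(fx$scan, fx$sim$cohort$pt, fx$surv)
  st1 <- apply_frozen(m, fx$sim$cohort$pt, fx$surv)
  # shuffled columns give identical per-sample results
  X <- fx$sim$cohort$pt
  set.seed(2); Xs <- as_expr_matrix(X[, sample(ncol(X)), drop = FALSE])
  st2 <- apply_frozen(m, Xs, fx$surv)
  i <- match(st1$data$sample_id, st2$data$sample_id)
  expect_identical(st1$data$label, st2$data$label[i])
  expect_equal(st1$data$score, st2$data$score[i], tolerance = 0)
  # withholding survival changes labels not at all
  st3 <- apply_frozen(m, fx$sim$cohort$pt)
  expect_identical(st3$data, st1$data)
  expect_null(st3$summary)
  # missing panel gene is a hard error naming the gene
  Xm <- as_expr_matrix(X[setdiff(rownames(X), m$genes$gene_id[1]), , drop = FALSE])
  expect_error(apply_frozen(m, Xm), m$genes$gene_id[1], fixed = TRUE)
  # label rule: HR iff score strictly above the cutoff
  expect_identical(st1$data$label, ifelse(st1$data$score > m$score_cutoff, "HR", "LR"))
})

test_that("samples with missing panel expression are flagged and excluded", {
  fx <- fit_fixture()
  m <- fit_swvg(fx$scan, fx$sim$cohort$pt, fx$surv)
  X <- unclass(fx$sim$cohort$pt)
  X[m$genes$gene_id[1], 3] <- NA
  class(X) <- c("expr_matrix", class(matrix()))
  st <- apply_frozen(m, X, fx$surv)
  expect_identical(st$excluded, colnames(X)[3])
  expect_false(colnames(X)[3] %in% st$data$sample_id)
})

test_that("combined stratification is exactly the LR intersection", {
  pts <- sprintf("P%02d", 1:30)
  set.seed(5)
  a <- setNames(sample(c("LR", "HR"), 30, TRUE), pts)
  b <- setNames(sample(c("LR", "HR"), 30, TRUE), pts)
  comb <- combine_pt_at(a, b)
  expect_identical(unname(comb), unname(ifelse(a == "LR" & b == "LR", "LR", "HR")))
  expect_identical(names(comb)[comb == "LR"],
                   intersect(names(a)[a == "LR"], names(b)[b == "LR"]))
  # rule table
  expect_identical(unname(combine_pt_at(c(P1 = "LR"), c(P1 = "LR"))), "LR")
  expect_identical(unname(combine_pt_at(c(P1 = "LR"), c(P1 = "HR"))), "HR")
  expect_identical(unname(combine_pt_at(c(P1 = "HR"), c(P1 = "HR"))), "HR")
  expect_error(combine_pt_at(c(P1 = "LR"), c(P2 = "LR")), "no patients")
})

test_that("model JSON round-trips bit-exactly", {
  fx <- fit_fixture()
  m <- fit_swvg(fx$scan, fx$sim$cohort$pt, fx$surv)
  f <- withr::local_tempfile(fileext = ".json")
  write_swvg_model(m, f)
  m2 <- read_swvg_model(f)
  expect_identical(m2$genes$gene_id, m$genes$gene_id)
  expect_identical(m2$genes$cutoff, m$genes$cutoff)
  expect_identical(m2$genes$design, m$genes$design)
  expect_identical(m2$genes$weight, m$genes$weight)
  expect_identical(m2$score_cutoff, m$score_cutoff)
  # identical labels from the reloaded model
  st1 <- apply_frozen(m, fx$sim$cohort$pt)
  st2 <- apply_frozen(m2, fx$sim$cohort$pt)
  expect_identical(st1$data, st2$data)
})

test_that("packaged ribosomal panel fixture lists 24 genes with probes", {
  panel <- ribosomal_panel()
  expect_identical(nrow(panel), 24L)
  expect_identical(names(panel), c("gene_id", "probe_id"))
  expect_true(all(grepl("^ILMN_", panel$probe_id)))
  expect_true(all(grepl("^RP[LS]", panel$gene_id)))
})
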