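test_that("degenerate inputs raise no_valid_cutoff", {
  surv <- make_surv(40, seed = 1)
  expect_error(scan_cutoff(named_expr(rep(2, 40), surv), surv),
               class = "no_valid_cutoff")
  expect_error(scan_cutoff(named_expr(rnorm(6), surv[1:6, ]), surv[1:6, ]),
               class = "no_valid_cutoff")
})

test_that("perfectly separated toy: cutoff between the groups, design 2, HR > 1", {
  n <- 40
  x <- c(rep(2, 20), rep(1, 20))
  surv <- data.frame(sample_id = sprintf("S%03d", 1:n),
                     os_years = c(seq(0.1, 0.5, length.out = 20), rep(5, 20)),
                     event = c(rep(1L, 20), rep(0L, 20)))
  gp <- suppressWarnings(scan_cutoff(named_expr(x, surv), surv))
  expect_gt(gp$cutoff, 1); expect_lt(gp$cutoff, 2)
  expect_identical(gp$design, 2L)
  expect_gt(gp$hazard_ratio, 1)

  # swapping the survival roles of the two expression groups flips the design
  surv2 <- surv
  surv2$os_years <- rev(surv$os_years); surv2$event <- rev(surv$event)
  gp2 <- suppressWarnings(scan_cutoff(named_expr(x, surv2), surv2))
  expect_identical(gp2$cutoff, gp$cutoff)
  expect_identical(gp2$design, 1L)
})

test_that("scan equals brute-force enumeration with independent fits", {
  # independent route: plain-R Efron likelihood + root-finding (plus a coxph
  # spot-check below); same tie-break rule applied outside the package.
  set.seed(20)
  for (rep in 1:12) {
    n <- sample(20:60, 1)
    surv <- make_surv(n, rate = runif(1, 0.2, 0.8))
    x <- named_expr(rnorm(n, sd = runif(1, 0.5, 2)), surv)
    gp <- suppressWarnings(scan_cutoff(x, surv))
    or <- ddg_oracle_scan(x, surv)
    expect_equal(unname(gp$cutoff), unname(or$cutoff), tolerance = 1e-12)
    expect_equal(unname(gp$wald_p), unname(or$p), tolerance = 1e-9)
  }
  # formula cross-check against the survival package on one instance
  surv <- make_surv(50, seed = 77)
  x <- named_expr(rnorm(50), surv)
  gp <- suppressWarnings(scan_cutoff(x, surv))
  fit <- survival::coxph(
    survival::Surv(surv$os_years, surv$event) ~ I(x[surv$sample_id] > gp$cutoff),
    ties = "efron")
  p_coxph <- pchisq((coef(fit)[1] / sqrt(fit$var[1, 1]))^2, 1, lower.tail = FALSE)
  expect_equal(gp$wald_p, unname(p_coxph), tolerance = 1e-6)
})

test_that("labels are reproduced by the stored cutoff and design", {
  set.seed(3)
  for (rep in 1:5) {
    surv <- make_surv(45)
    x <- named_expr(rnorm(45), surv)
    gp <- suppressWarnings(scan_cutoff(x, surv))
    relab <- ddg_labels(x[names(gp$labels)], gp$cutoff, gp$design)
    expect_identical(relab, gp$labels)
    expect_identical(gp$n_lr + gp$n_hr, gp$n)
  }
})

test_that("enlarging the admissibility floor never decreases the minimum p", {
  set.seed(9)
  surv <- make_surv(60)
  x <- named_expr(rnorm(60), surv)
  p_seq <- vapply(c(0.1, 0.2, 0.3, 0.4), function(f)
    suppressWarnings(scan_cutoff(x, surv,
                                 pipeline_config(min_group_fraction = f)))$wald_p,
    numeric(1))
  expect_true(all(diff(p_seq) >= -1e-12))
})

test_that("scan is equivariant under affine expression transforms", {
  set.seed(11)
  surv <- make_surv(50)
  x <- named_expr(rnorm(50), surv)
  gp <- suppressWarnings(scan_cutoff(x, surv))
  a <- 2.5; b <- -3
  gp2 <- suppressWarnings(scan_cutoff(a * x + b, surv))
  expect_equal(gp2$cutoff, a * gp$cutoff + b, tolerance = 1e-9)
  expect_equal(gp2$wald_p, gp$wald_p, tolerance = 1e-12)
  expect_identical(gp2$design, gp$design)
  expect_equal(gp2$hazard_ratio, gp$hazard_ratio, tolerance = 1e-9)
})

test_that("batch_scan separates degenerate genes and is deterministic", {
  set.seed(4)
  surv <- make_surv(50)
  X <- matrix(rnorm(10 * 50), 10, 50,
              dimnames = list(sprintf("G%02d", 1:10), surv$sample_id))
  X[3, ] <- 1; X[7, ] <- 0  # constant genes
  X <- as_expr_matrix(X)
  t1 <- batch_scan(X, surv)
  expect_identical(nrow(t1$results), 8L)
  expect_identical(sort(t1$degenerate), c("G03", "G07"))
  t2 <- batch_scan(X, surv)
  expect_identical(t1$results, t2$results)
  expect_identical(t1$labels, t2$labels)
  expect_error(batch_scan(X, make_surv(5, seed = 1)[0, ], tissue = "PT"),
               "no overlapping")
})

test_that("min-p selection is anti-conservative under the null and the
           permutation adjustment calibrates it", {
  # null: expression independent of survival
  set.seed(100)
  surv <- make_surv(100, rate = 0.4)
  X <- as_expr_matrix(matrix(rnorm(200 * 100), 200, 100,
                             dimnames = list(sprintf("G%03d", 1:200),
                                             surv$sample_id)))
  tab <- batch_scan(X, surv)
  raw_rate <- mean(tab$results$wald_p < 0.05)
  expect_gt(raw_rate, 0.05)  # documented selection bias

  # permutation-adjusted p is roughly uniform: mean over noise genes in
  # [0.35, 0.65]
  genes <- rownames(X)[1:50]
  adj <- vapply(seq_along(genes), function(i) {
    g <- genes[i]
    gp <- suppressWarnings(scan_cutoff(X[g, ], surv))
    permutation_adjust(gp, X[g, ], surv, n_perm = 100, seed = 200 + i)
  }, numeric(1))
  expect_gt(mean(adj), 0.35)
  expect_lt(mean(adj), 0.65)
})

test_that("permutation_adjust: strong signal small p, precondition enforced", {
  n <- 40
  x <- c(rep(2, 20), rep(1, 20))
  surv <- data.frame(sample_id = sprintf("S%03d", 1:n),
                     os_years = c(seq(0.1, 0.5, length.out = 20), rep(5, 20)),
                     event = c(rep(1L, 20), rep(0L, 20)))
  xx <- named_expr(x, surv)
  gp <- suppressWarnings(scan_cutoff(xx, surv))
  expect_lte(permutation_adjust(gp, xx, surv, n_perm = 100, seed = 1), 0.02)
  expect_error(permutation_adjust(gp, xx, surv, n_perm = 50), "at least 100")
})
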