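# Shared fixtures and independent oracles. Everything here is deliberately
# written without calling the package's own fitting path, so that the tests
# compare two genuinely different routes to the same quantity.

# Random censored survival data with sample names.
make_surv <- function(n, rate = 0.3, horizon = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tev <- rexp(n, rate)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             os_years = pmin(tev, horizon),
             event = as.integer(tev <= horizon),
             stringsAsFactors = FALSE)
}

named_expr <- function(x, surv) setNames(x, surv$sample_id)

# --- Independent Efron partial-likelihood oracle (plain R) -----------------
# Log partial likelihood, score and information for a binary covariate,
# written directly from the definition (per-risk-set sums, no count
# shortcuts). Used to locate the MLE by root-finding, independently of the
# package's Newton solver.
efron_fns <- function(time, event, z) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; z <- z[ord]
  utimes <- unique(time[event == 1])
  function(beta) {
    r <- exp(beta * z)
    ll <- 0; U <- 0; I <- 0
    for (t in utimes) {
      R <- which(time >= t)
      D <- which(time == t & event == 1)
      d <- length(D)
      sR <- sum(r[R]); sD <- sum(r[D])
      zR <- sum(z[R] * r[R]); zD <- sum(z[D] * r[D])
      ll <- ll + beta * sum(z[D])
      U <- U + sum(z[D])
      for (k in seq_len(d) - 1) {
        den <- sR - (k / d) * sD
        num1 <- zR - (k / d) * zD   # sum z r over effective risk set
        mu <- num1 / den
        ll <- ll - log(den)
        U <- U - mu
        I <- I + mu - mu^2          # z binary: E[z^2] = E[z]
      }
    }
    list(ll = ll, U = U, I = I)
  }
}

# MLE by root-finding on the score; returns c(beta, se, p).
cox_binary_oracle <- function(time, event, z) {
  f <- efron_fns(time, event, z)
  sc <- function(b) f(b)$U
  lo <- -20; hi <- 20
  if (sc(lo) * sc(hi) > 0) return(c(NA_real_, NA_real_, NA_real_))  # monotone
  b <- uniroot(sc, c(lo, hi), tol = 1e-13)$root
  info <- f(b)$I
  se <- 1 / sqrt(info)
  c(beta = b, se = se, p = pchisq((b / se)^2, 1, lower.tail = FALSE))
}

# Brute-force cutoff scan: independent grid + per-cutoff oracle fits.
ddg_oracle_scan <- function(x, surv, cfg = pipeline_config()) {
  ids <- intersect(names(x), surv$sample_id)
  i <- match(ids, surv$sample_id)
  xx <- x[ids]; tt <- surv$os_years[i]; ee <- surv$event[i]
  n <- length(xx)
  floor_n <- max(cfg$min_group_size, ceiling(cfg$min_group_fraction * n))
  u <- sort(unique(xx))
  mids <- (u[-1] + u[-length(u)]) / 2
  mids <- mids[vapply(mids, function(c) {
    nb <- sum(xx <= c); nb >= floor_n && (n - nb) >= floor_n
  }, logical(1))]
  fits <- t(vapply(mids, function(c)
    cox_binary_oracle(tt, ee, as.integer(xx > c)), numeric(3)))
  ok <- is.finite(fits[, 3])
  pmin_ <- min(fits[ok, 3])
  tied <- which(ok & fits[, 3] <= pmin_ + 1e-12)
  med <- median(xx)
  tied <- tied[order(abs(mids[tied] - med), mids[tied])]
  j <- tied[1]
  list(cutoff = mids[j], p = fits[j, 3], beta = fits[j, 1])
}

# Exhaustive 2x2 Fisher two-sided p: sum of hypergeometric probabilities of
# all tables with the observed margins whose probability does not exceed the
# observed one (with the standard relative tolerance).
fisher_oracle_2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  pr <- dhyper(ks, r1, n - r1, c1)
  obs <- dhyper(a, r1, n - r1, c1)
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Numeric inversion of the continuity-corrected score test: the CI bounds
# are the p0 values at which the corrected z-statistic equals the critical
# value.
wilson_cc_oracle <- function(k, n, conf = 0.95) {
  zc <- qnorm(1 - (1 - conf) / 2)
  stat <- function(p0) {
    num <- max(abs(k - n * p0) - 0.5, 0)
    num / sqrt(n * p0 * (1 - p0)) - zc
  }
  lo <- if (k == 0) 0 else
    uniroot(stat, c(1e-12, min(k / n, 1 - 1e-12)), tol = 1e-12)$root
  hi <- if (k == n) 1 else
    uniroot(stat, c(max(k / n, 1e-12), 1 - 1e-12), tol = 1e-12)$root
  c(lo, hi)
}

# Tiny synthetic cohort for the structural tests.
small_sim <- function(seed = 42, n = 60, genes = 40, signal = 6) {
  generate_paired_cohort(simulation_config(
    n_patients = n, n_genes = genes, n_signal = signal, seed = seed))
}
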