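# Survival and categorical statistics used throughout the pipeline. These
# are contract-level wrappers around the survival package (Efron handling of
# tied event times everywhere) plus the exact/categorical tests.

#' Kaplan-Meier product-limit estimate for one group
#'
#' @param time non-negative follow-up times (years).
#' @param event 1 = death, 0 = censored.
#' @return a `km_curve`: data.frame `time, survival, at_risk` (step values
#'   immediately after each distinct observed time, with a leading `t = 0`
#'   row at survival 1).
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) stop("empty survival data")
  if (any(time < 0)) stop("negative survival times")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = c(0, fit$time),
                    survival = c(1, fit$surv),
                    at_risk = c(length(time), fit$n.risk))
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a `km_curve` at arbitrary times
#' @param curve a `km_curve`.
#' @param t times at which to evaluate the step function.
#' @return survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  curve$survival[pmax(idx, 1L)]
}

#' Two-group survival comparison
#'
#' Univariate proportional-hazards fit (Efron ties) on the binary group
#' indicator; the hazard ratio is reported for the `"HR"`-labelled (or
#' second-level) group versus the other. The log-rank p-value is reported
#' alongside; if the Wald fit does not converge (monotone likelihood), the
#' log-rank p is substituted and flagged.
#'
#' @param time,event survival data.
#' @param labels two-level group labels (character or factor); `"HR"`
#'   is treated as the risk group when present.
#' @param conf_level CI level.
#' @return list: `wald_p, hazard_ratio, ci_low, ci_high, logrank_p,
#'   converged`.
#' @export
two_group_test <- function(time, event, labels, conf_level = 0.95) {
  labels <- as.character(labels)
  lv <- unique(labels)
  if (length(lv) != 2L) stop("labels must have exactly two levels, got: ",
                             paste(lv, collapse = ", "))
  risk <- if ("HR" %in% lv) "HR" else sort(lv)[2L]
  g <- as.integer(labels == risk)
  fit <- survival::coxph(survival::Surv(time, event) ~ g, ties = "efron",
                         control = survival::coxph.control(eps = 1e-12,
                                                           toler.chol = 1e-13))
  beta <- unname(fit$coefficients[1L])
  se <- sqrt(fit$var[1L, 1L])
  wald_p <- pchisq((beta / se)^2, 1L, lower.tail = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  logrank_p <- pchisq(sd$chisq, 1L, lower.tail = FALSE)
  converged <- is.finite(beta) && abs(beta) < 15 && is.finite(se)
  if (!converged) wald_p <- logrank_p
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(wald_p = wald_p, hazard_ratio = exp(beta),
       ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
       logrank_p = logrank_p, converged = converged)
}

#' Multivariate proportional-hazards fit
#'
#' Joint Cox model over the given covariates with listwise deletion of rows
#' with missing values (`n_used` reports the complete-case count).
#'
#' @param surv data.frame with `os_years` and `event` columns plus the
#'   covariates.
#' @param terms character vector of covariate column names.
#' @param conf_level CI level.
#' @return a `cox_fit`: data.frame `term, coef, hazard_ratio, ci_low,
#'   ci_high, wald_p` with attributes `n_used` and `converged`.
#' @export
cox_multivariate <- function(surv, terms, conf_level = 0.95) {
  stopifnot(length(terms) >= 1L)
  miss <- setdiff(terms, names(surv))
  if (length(miss)) stop("covariates not in table: ", paste(miss, collapse = ", "))
  d <- surv[, c("os_years", "event", terms), drop = FALSE]
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10L) stop("fewer than 10 complete cases")
  const <- terms[vapply(terms, function(t) length(unique(d[[t]])) < 2L, logical(1))]
  if (length(const)) stop("constant covariate(s): ", paste(const, collapse = ", "))
  mm <- model.matrix(~ ., d[, terms, drop = FALSE])[, -1L, drop = FALSE]
  qr_ <- qr(cbind(1, mm))
  if (qr_$rank < ncol(mm) + 1L) {
    aliased <- colnames(mm)[qr_$pivot[seq(qr_$rank + 1L, ncol(mm) + 1L)] - 1L]
    stop("collinear covariates: ", paste(aliased, collapse = ", "))
  }
  fit <- survival::coxph(survival::Surv(d$os_years, d$event) ~ mm, ties = "efron")
  beta <- fit$coefficients
  se <- sqrt(diag(fit$var))
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(term = colnames(mm), coef = unname(beta),
                    hazard_ratio = exp(unname(beta)),
                    ci_low = exp(unname(beta) - z * se),
                    ci_high = exp(unname(beta) + z * se),
                    wald_p = pchisq((unname(beta) / se)^2, 1L, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  attr(out, "n_used") <- nrow(d)
  attr(out, "converged") <- fit$info["convergence"]
  class(out) <- c("cox_fit", "data.frame")
  out
}

#' Exact tests for categorical tables and the rank-sum test
#'
#' `fisher_exact_2x2` computes the exact two-sided Fisher p for a 2x2 table
#' (sum of table probabilities not exceeding that of the observed table);
#' `freeman_halton` extends this to r x c tables, with a seeded Monte-Carlo
#' fallback when the exact network computation is infeasible;
#' `mann_whitney` is the rank-sum test with normal approximation and tie
#' correction.
#'
#' @param table integer matrix of non-negative counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) stop("empty margin")
  fisher.test(table, alternative = "two.sided")$p.value
}

#' @rdname fisher_exact_2x2
#' @param mc_cutoff largest table total for which the exact computation is
#'   attempted; beyond it a seeded Monte-Carlo estimate with `B` draws is
#'   used.
#' @param B Monte-Carlo draws.
#' @param seed integer seed for the Monte-Carlo fallback.
#' @export
freeman_halton <- function(table, mc_cutoff = 400L, B = 1e5, seed = 1L) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) stop("empty margin")
  if (sum(table) <= mc_cutoff) {
    fisher.test(table, workspace = 2e7)$p.value
  } else {
    set.seed(seed)
    fisher.test(table, simulate.p.value = TRUE, B = B)$p.value
  }
}

#' @rdname fisher_exact_2x2
#' @param x,y numeric samples.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
}
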