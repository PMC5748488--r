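# Cross-tissue common-prognostic-gene (CPG) selection and the agreement /
# overlap statistics: a gene is a CPG when it is survival-significant in both
# the primary tumor (PT) and the adjacent non-malignant tissue (AT) of the
# same patients, with the same risk design in both tissues.

#' Newcombe continuity-corrected Wilson score interval
#'
#' Score-based (``efficient score'') confidence interval for a binomial
#' proportion with continuity correction, bounds truncated to `[0, 1]`.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param conf_level confidence level, default 0.95.
#' @return numeric vector `c(low, high)`.
#' @export
wilson_cc_ci <- function(k, n, conf_level = 0.95) {
  if (n < 1) stop("n must be at least 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  lo <- if (k == 0) 0 else
    (2 * n * p + z^2 - 1 - z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
    (2 * (n + z^2))
  hi <- if (k == n) 1 else
    (2 * n * p + z^2 + 1 + z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
    (2 * (n + z^2))
  c(low = max(0, lo), high = min(1, hi))
}

#' Agreement between two label assignments over the same patients
#'
#' @param labels_a,labels_b named `"LR"`/`"HR"` vectors over an identical
#'   patient domain.
#' @param conf_level confidence level for the Wilson interval.
#' @return list of class `agreement_stats`: `k, n, proportion, ci_low,
#'   ci_high`.
#' @export
agreement_stats <- function(labels_a, labels_b, conf_level = 0.95) {
  if (is.null(names(labels_a)) || is.null(names(labels_b)))
    stop("label vectors must be named by patient")
  miss <- c(setdiff(names(labels_a), names(labels_b)),
            setdiff(names(labels_b), names(labels_a)))
  if (length(miss))
    stop("patient domains differ; unmatched: ", paste(unique(miss), collapse = ", "))
  if (length(labels_a) == 0L) stop("empty label vectors")
  b <- labels_b[names(labels_a)]
  k <- sum(labels_a == b)
  n <- length(labels_a)
  ci <- wilson_cc_ci(k, n, conf_level)
  structure(list(k = k, n = n, proportion = k / n,
                 ci_low = unname(ci[1L]), ci_high = unname(ci[2L])),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("agreement %d/%d = %.3f (CI %.3f-%.3f)\n",
              x$k, x$n, x$proportion, x$ci_low, x$ci_high))
  invisible(x)
}

#' Newcombe score-based CI for a difference of two proportions
#'
#' Hybrid "square-and-add" interval built from the two uncorrected Wilson
#' intervals (Newcombe method 10).
#'
#' @param k1,n1,k2,n2 binomial counts of the two groups.
#' @param conf_level confidence level.
#' @return list: `diff`, `low`, `high`, `significant` (TRUE iff 0 outside CI).
#' @export
proportion_diff_ci <- function(k1, n1, k2, n2, conf_level = 0.95) {
  if (n1 < 1 || n2 < 1) stop("both sample sizes must be at least 1")
  z <- qnorm(1 - (1 - conf_level) / 2)
  wilson <- function(k, n) {
    p <- k / n
    ctr <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    c(ctr - hw, ctr + hw)
  }
  p1 <- k1 / n1; p2 <- k2 / n2
  w1 <- wilson(k1, n1); w2 <- wilson(k2, n2)
  d <- p1 - p2
  lo <- d - sqrt((p1 - w1[1])^2 + (w2[2] - p2)^2)
  hi <- d + sqrt((w1[2] - p1)^2 + (p2 - w2[1])^2)
  list(diff = d, low = lo, high = hi, significant = (lo > 0 || hi < 0))
}

#' Hypergeometric over-representation of a set overlap
#'
#' Upper-tail probability `P(X >= overlap)` that two sets of the given sizes
#' drawn from a universe share at least the observed number of members.
#'
#' @param set_a,set_b character vectors.
#' @param universe_size size of the common gene universe.
#' @return p-value.
#' @export
hypergeom_overlap <- function(set_a, set_b, universe_size) {
  a <- length(unique(set_a)); b <- length(unique(set_b))
  ov <- length(intersect(unique(set_a), unique(set_b)))
  if (length(union(set_a, set_b)) > universe_size)
    stop("universe smaller than the union of the two sets")
  phyper(ov - 1, a, universe_size - a, b, lower.tail = FALSE)
}

#' Select common prognostic genes across PT and AT
#'
#' Genes scored in both tissues with the identical risk design and
#' `wald_p <= alpha_pre` in both; each record carries the PT-vs-AT label
#' agreement over patients possessing both samples.
#'
#' @param pt_scan,at_scan `ddg_table` objects from [batch_scan()] on the PT
#'   and AT samples of the same paired cohort.
#' @param pairing pairing table from [pair_samples()] (columns
#'   `patient_id, pt_sample, at_sample`).
#' @param cfg a [pipeline_config()]; `alpha_pre` and `conf_level` are used.
#' @return `data.frame` with one row per CPG: `gene_id, shared_design, pt_p,
#'   at_p, pt_cutoff, at_cutoff, agreement_k, agreement_n, agreement,
#'   ci_low, ci_high`. The design-1 (tumor-suppressor-like) and design-2
#'   (pro-oncogenic) partitions are available via the `"design1"` /
#'   `"design2"` attributes.
#' @export
select_cpg <- function(pt_scan, at_scan, pairing, cfg = pipeline_config()) {
  pt <- pt_scan$results; at <- at_scan$results
  common <- intersect(pt$gene_id, at$gene_id)
  if (length(common) == 0L) {
    warning("no genes scored in both tissues")
    return(empty_cpg_table())
  }
  ip <- match(common, pt$gene_id); ia <- match(common, at$gene_id)
  keep <- pt$design[ip] == at$design[ia] &
    pt$wald_p[ip] <= cfg$alpha_pre & at$wald_p[ia] <= cfg$alpha_pre
  common <- common[keep]; ip <- ip[keep]; ia <- ia[keep]
  if (length(common) == 0L) return(empty_cpg_table())
  paired <- pairing[!is.na(pairing$at_sample), , drop = FALSE]
  paired <- paired[paired$pt_sample %in% colnames(pt_scan$labels) &
                   paired$at_sample %in% colnames(at_scan$labels), , drop = FALSE]
  rows <- lapply(seq_along(common), function(j) {
    g <- common[j]
    la <- setNames(pt_scan$labels[g, paired$pt_sample], paired$patient_id)
    lb <- setNames(at_scan$labels[g, paired$at_sample], paired$patient_id)
    ok <- !is.na(la) & !is.na(lb)
    ag <- agreement_stats(la[ok], lb[ok], cfg$conf_level)
    data.frame(gene_id = g, shared_design = pt$design[ip[j]],
               pt_p = pt$wald_p[ip[j]], at_p = at$wald_p[ia[j]],
               pt_cutoff = pt$cutoff[ip[j]], at_cutoff = at$cutoff[ia[j]],
               agreement_k = ag$k, agreement_n = ag$n,
               agreement = ag$proportion, ci_low = ag$ci_low,
               ci_high = ag$ci_high, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(pmax(out$pt_p, out$at_p), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "design1") <- out$gene_id[out$shared_design == 1L]
  attr(out, "design2") <- out$gene_id[out$shared_design == 2L]
  out
}

empty_cpg_table <- function() {
  out <- data.frame(gene_id = character(0), shared_design = integer(0),
                    pt_p = numeric(0), at_p = numeric(0),
                    pt_cutoff = numeric(0), at_cutoff = numeric(0),
                    agreement_k = integer(0), agreement_n = integer(0),
                    agreement = numeric(0), ci_low = numeric(0),
                    ci_high = numeric(0))
  attr(out, "design1") <- character(0)
  attr(out, "design2") <- character(0)
  out
}
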