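# Differential expression (Welch t-test + Benjamini-Hochberg FDR) between
# sample groups, and gene-set correlation profiling against a target gene
# (Kendall's tau of every focal / random-control gene with the target).

#' Per-gene Welch t-test between two sample groups
#'
#' @param matrix an `expr_matrix`.
#' @param group_a,group_b disjoint sample-id vectors (each >= 2 samples).
#' @param cfg a [pipeline_config()]; `deg_q` is recorded for downstream use.
#' @return a `deg_table` data.frame: `gene_id, mean_diff` (A minus B, log2
#'   units), `t, p, q` (Benjamini-Hochberg across all tested genes),
#'   `direction` (`"up"`/`"down"` in group A).
#' @details Genes with zero variance in both groups get `p = 1` when the
#'   means are equal and `p = 0` when they differ (infinite evidence under
#'   the model; flagged by `t = Inf`).
#' @export
deg_table <- function(matrix, group_a, group_b, cfg = pipeline_config()) {
  if (length(intersect(group_a, group_b)))
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "))
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 samples")
  A <- matrix[, group_a, drop = FALSE]
  B <- matrix[, group_b, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1L)
  vb <- rowSums((B - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  diff <- ma - mb
  t <- ifelse(se2 > 0, diff / sqrt(se2), ifelse(diff == 0, 0, Inf * sign(diff)))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L)),
               1)
  p <- ifelse(is.finite(t), 2 * pt(abs(t), df, lower.tail = FALSE),
              0)
  p[se2 == 0 & diff == 0] <- 1
  q <- p.adjust(p, method = "BH")
  out <- data.frame(gene_id = rownames(matrix), mean_diff = unname(diff),
                    t = unname(t), p = unname(p), q = unname(q),
                    direction = ifelse(diff >= 0, "up", "down"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "deg_q") <- cfg$deg_q
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Top differentially expressed genes in one direction
#'
#' @param tab a `deg_table`.
#' @param n number of genes to keep (default 1000).
#' @param direction `"up"` or `"down"` (in group A).
#' @param q_max optional FDR filter applied before ranking.
#' @return gene ids ordered by ascending p.
#' @export
top_deg <- function(tab, n = 1000L, direction = c("up", "down"), q_max = NULL) {
  direction <- match.arg(direction)
  d <- tab[tab$direction == direction, , drop = FALSE]
  if (!is.null(q_max)) d <- d[d$q <= q_max, , drop = FALSE]
  d <- d[order(d$p, d$gene_id), , drop = FALSE]
  head(d$gene_id, n)
}

#' Gene-set correlation profile against a target gene
#'
#' Kendall's tau of each focal-set gene with the target across samples,
#' compared with `n_control_sets` size-matched random control sets drawn
#' (without replacement, seeded) from the genes outside the focal set.
#'
#' @param matrix an `expr_matrix`.
#' @param target_gene target gene id.
#' @param focal_set character vector of focal gene ids (non-empty).
#' @param n_control_sets number of random control sets (default 10).
#' @param seed integer seed for control-set draws.
#' @return a `correlation_profile`: `focal_tau` (named), `control_tau`
#'   (pooled across sets), `median_focal`, `median_control`, `p`
#'   (Mann-Whitney comparison of the two tau distributions).
#' @export
correlation_profile <- function(matrix, target_gene, focal_set,
                                n_control_sets = 10L, seed = 1L) {
  if (length(focal_set) == 0L) stop("empty focal set")
  if (n_control_sets < 1L) stop("need at least one control set")
  miss <- setdiff(c(target_gene, focal_set), rownames(matrix))
  if (length(miss)) stop("genes missing from matrix: ", paste(miss, collapse = ", "))
  y <- matrix[target_gene, ]
  tau_with_target <- function(genes)
    vapply(genes, function(g) cor(matrix[g, ], y, method = "kendall"), numeric(1))
  focal_tau <- tau_with_target(focal_set)
  pool <- setdiff(rownames(matrix), c(focal_set, target_gene))
  if (length(pool) < length(focal_set))
    stop("not enough genes outside the focal set for size-matched controls")
  set.seed(seed)
  control_tau <- unlist(lapply(seq_len(n_control_sets), function(i)
    tau_with_target(sample(pool, length(focal_set)))))
  structure(list(target = target_gene,
                 focal_tau = focal_tau, control_tau = control_tau,
                 median_focal = median(focal_tau),
                 median_control = median(control_tau),
                 p = mann_whitney(focal_tau, control_tau)),
            class = "correlation_profile")
}

#' @export
print.correlation_profile <- function(x, ...) {
  cat(sprintf("correlation_profile vs %s: median tau focal %.3f, control %.3f, p = %.3g\n",
              x$target, x$median_focal, x$median_control, x$p))
  invisible(x)
}
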