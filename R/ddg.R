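# 1-D data-driven grouping (DDg): per-gene survival-optimal expression
# dichotomization. For every admissible cutoff the samples are split at the
# cutoff, a univariate proportional-hazards model is fitted on the binary
# indicator (Efron ties), and the cutoff minimizing the Wald p-value is
# retained. Design 2 (pro-oncogenic): above-cutoff group has the higher
# hazard; design 1 (tumor-suppressor-like): below-cutoff group does.

#' Candidate cutoff grid for dichotomizing one gene
#'
#' Midpoints between consecutive distinct observed expression values,
#' restricted to splits leaving at least
#' `max(min_group_size, ceiling(min_group_fraction * n))` samples on each
#' side. The grid may be empty for degenerate genes.
#'
#' @param x numeric expression values.
#' @param cfg a [pipeline_config()].
#' @return strictly increasing numeric vector (possibly length 0).
#' @export
cutoff_grid <- function(x, cfg = pipeline_config()) {
  n <- length(x)
  floor_n <- max(cfg$min_group_size, ceiling(cfg$min_group_fraction * n))
  u <- sort(unique(x))
  if (length(u) < 2L) return(numeric(0))
  mids <- (u[-1L] + u[-length(u)]) / 2
  n_below <- vapply(mids, function(c) sum(x <= c), integer(1))
  keep <- n_below >= floor_n & (n - n_below) >= floor_n
  mids[keep]
}

#' Condition for `NoValidCutoff` failures
#' @noRd
no_valid_cutoff <- function(msg) {
  stop(structure(class = c("no_valid_cutoff", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Apply a stored cutoff/design pair to expression values
#'
#' Design 2: `HR` iff expression strictly above the cutoff. Design 1: `HR`
#' iff expression at or below the cutoff (values exactly equal to the cutoff
#' always fall on the "at or below" side).
#'
#' @param x named numeric expression values.
#' @param cutoff numeric cutoff.
#' @param design 1 or 2.
#' @return named character vector of `"LR"`/`"HR"` labels.
#' @export
ddg_labels <- function(x, cutoff, design) {
  stopifnot(design %in% c(1L, 2L))
  above <- x > cutoff
  lab <- if (design == 2L) ifelse(above, "HR", "LR") else ifelse(above, "LR", "HR")
  setNames(lab, names(x))
}

# Align a named expression vector with a survival table; returns a list with
# time/event/x sorted by time ascending plus the sample ids in that order.
align_surv <- function(expr, surv) {
  if (is.null(names(expr))) stop("expression vector must carry sample names")
  surv <- as.data.frame(surv)
  if (!all(c("sample_id", "os_years", "event") %in% names(surv)))
    stop("survival table needs columns sample_id, os_years, event")
  common <- intersect(names(expr), surv$sample_id)
  if (length(common) == 0L) stop("no overlapping samples between expression and survival")
  i <- match(common, surv$sample_id)
  d <- data.frame(sample_id = common, x = unname(expr[common]),
                  time = surv$os_years[i], event = surv$event[i],
                  stringsAsFactors = FALSE)
  d <- d[is.finite(d$x) & is.finite(d$time), , drop = FALSE]
  d[order(d$time), , drop = FALSE]
}

#' Survival-optimal cutoff scan for a single gene
#'
#' @param expr named numeric vector of one gene's log2 expression.
#' @param surv survival table with columns `sample_id, os_years, event`.
#' @param cfg a [pipeline_config()].
#' @param gene_id,tissue identifiers stored in the result.
#' @param statistic `"wald"` (default; Wald test from the proportional-hazards
#'   fit) or `"logrank"` (score test at beta = 0, the log-rank-type variant).
#' @param keep_scan if `TRUE`, attach the full per-cutoff table.
#' @return object of class `gene_prognosis`: fields `gene_id, tissue, cutoff,
#'   design, wald_p, hazard_ratio, labels, n_lr, n_hr`.
#' @details Ties in the minimum p-value are broken towards the cutoff closest
#'   to the sample median, then towards the smaller cutoff. Cutoffs at which
#'   the fit does not converge (monotone likelihood) are skipped with a
#'   warning under `statistic = "wald"`.
#' @export
scan_cutoff <- function(expr, surv, cfg = pipeline_config(),
                        gene_id = "gene", tissue = "PT",
                        statistic = c("wald", "logrank"), keep_scan = FALSE) {
  statistic <- match.arg(statistic)
  d <- align_surv(expr, surv)
  n <- nrow(d)
  if (n < 2L * cfg$min_group_size)
    no_valid_cutoff(sprintf("gene %s: only %d usable samples", gene_id, n))
  grid <- cutoff_grid(d$x, cfg)
  if (length(grid) == 0L)
    no_valid_cutoff(sprintf("gene %s: no admissible cutoff (constant or near-constant expression)", gene_id))
  sc <- .ddg_scan_gene_cpp(d$time, as.integer(d$event), d$x, grid)
  res <- ddg_select_cutoff(grid, sc, d$x, statistic)
  if (is.null(res$ok)) {
    if (!is.null(res$skipped) && res$skipped > 0L)
      warning(sprintf("gene %s: all %d cutoffs skipped (non-convergent fits)",
                      gene_id, res$skipped))
    no_valid_cutoff(sprintf("gene %s: no usable cutoff", gene_id))
  }
  if (!is.null(res$skipped) && res$skipped > 0L)
    warning(sprintf("gene %s: %d non-convergent cutoff(s) skipped", gene_id, res$skipped))
  labels <- ddg_labels(setNames(d$x, d$sample_id), res$cutoff, res$design)
  out <- structure(list(
    gene_id = gene_id, tissue = tissue,
    cutoff = res$cutoff, design = res$design,
    wald_p = res$p, hazard_ratio = res$hr,
    labels = labels,
    n_lr = sum(labels == "LR"), n_hr = sum(labels == "HR"),
    statistic = statistic, n = n), class = "gene_prognosis")
  if (keep_scan)
    out$scan <- data.frame(cutoff = grid, sc)
  out
}

# Shared cutoff-selection logic (also used by the score-cutoff scan in the
# weighted-voting fit). `sc` is the matrix returned by .ddg_scan_gene_cpp.
# Under the Wald statistic, cutoffs with a monotone partial likelihood
# (complete separation; |beta| at the cap) fall back to the score-test p for
# that cutoff — the Wald statistic degenerates there — mirroring the
# log-rank fallback of two_group_test. Other non-convergent fits are skipped.
ddg_select_cutoff <- function(grid, sc, x, statistic) {
  score_ok <- is.finite(sc[, "i0"]) & sc[, "i0"] > 0
  score_chi <- ifelse(score_ok, sc[, "u0"]^2 / sc[, "i0"], NA_real_)
  if (statistic == "wald") {
    ok <- sc[, "converged"] == 1 & is.finite(sc[, "se"]) & sc[, "se"] > 0
    capped <- sc[, "converged"] != 1 & is.finite(sc[, "beta"]) &
      abs(sc[, "beta"]) >= 21.9 & score_ok
    usable <- ok | capped
    chi <- ifelse(capped, score_chi, (sc[, "beta"] / sc[, "se"])^2)
  } else {
    usable <- score_ok
    chi <- score_chi
  }
  skipped <- sum(!usable)
  if (!any(usable)) return(list(ok = NULL, skipped = skipped))
  p <- ifelse(usable, pchisq(chi, 1L, lower.tail = FALSE), NA_real_)
  pmin_ <- min(p, na.rm = TRUE)
  tied <- which(usable & p <= pmin_ + 1e-12)
  med <- median(x)
  tied <- tied[order(abs(grid[tied] - med), grid[tied])]
  j <- tied[1L]
  beta <- sc[j, "beta"]
  design <- if (beta > 0) 2L else 1L
  list(ok = TRUE, cutoff = grid[j], p = p[j],
       design = design, beta = beta,
       hr = exp(abs(beta)), skipped = skipped)
}

#' @export
print.gene_prognosis <- function(x, ...) {
  cat(sprintf("gene_prognosis %s [%s]: cutoff %.4g, design %d, p = %.3g, HR = %.3g (n_lr %d, n_hr %d)\n",
              x$gene_id, x$tissue, x$cutoff, x$design, x$wald_p,
              x$hazard_ratio, x$n_lr, x$n_hr))
  invisible(x)
}

#' Genome-wide DDg scan
#'
#' Runs [scan_cutoff()] for every gene of an expression matrix. Degenerate
#' genes (no admissible cutoff) are listed separately rather than failing
#' the scan.
#'
#' @param matrix an `expr_matrix`.
#' @param surv survival table (`sample_id, os_years, event`), one row per
#'   sample of the scanned tissue.
#' @param cfg a [pipeline_config()].
#' @param tissue label stored with each result.
#' @param statistic see [scan_cutoff()].
#' @return a `ddg_table`: list with `results` (one row per scored gene:
#'   `gene_id, tissue, cutoff, design, wald_p, hazard_ratio, n_lr, n_hr`),
#'   `labels` (gene x sample character matrix) and `degenerate` (gene ids).
#' @export
batch_scan <- function(matrix, surv, cfg = pipeline_config(), tissue = "PT",
                       statistic = c("wald", "logrank")) {
  statistic <- match.arg(statistic)
  surv <- as.data.frame(surv)
  samples <- intersect(colnames(matrix), surv$sample_id)
  if (length(samples) == 0L) stop("no overlapping samples between matrix and survival table")
  genes <- rownames(matrix)
  rows <- vector("list", length(genes))
  labmat <- base::matrix(NA_character_, nrow = length(genes), ncol = length(samples),
                         dimnames = list(genes, samples))
  degenerate <- character(0)
  for (g in seq_along(genes)) {
    gp <- withCallingHandlers(
      tryCatch(scan_cutoff(matrix[g, samples], surv, cfg, gene_id = genes[g],
                           tissue = tissue, statistic = statistic),
               no_valid_cutoff = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(gp)) { degenerate <- c(degenerate, genes[g]); next }
    rows[[g]] <- data.frame(gene_id = gp$gene_id, tissue = gp$tissue,
                            cutoff = gp$cutoff, design = gp$design,
                            wald_p = gp$wald_p, hazard_ratio = gp$hazard_ratio,
                            n_lr = gp$n_lr, n_hr = gp$n_hr,
                            stringsAsFactors = FALSE)
    labmat[genes[g], names(gp$labels)] <- gp$labels
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(results))
    results <- data.frame(gene_id = character(0), tissue = character(0),
                          cutoff = numeric(0), design = integer(0),
                          wald_p = numeric(0), hazard_ratio = numeric(0),
                          n_lr = integer(0), n_hr = integer(0))
  rownames(results) <- NULL
  structure(list(results = results,
                 labels = labmat[results$gene_id, , drop = FALSE],
                 degenerate = degenerate, tissue = tissue),
            class = "ddg_table")
}

#' @export
print.ddg_table <- function(x, ...) {
  cat(sprintf("ddg_table [%s]: %d genes scored, %d degenerate\n",
              x$tissue, nrow(x$results), length(x$degenerate)))
  invisible(x)
}

#' Write / read the per-gene scan table as TSV
#' @param x a `ddg_table`.
#' @param path file path.
#' @export
write_ddg <- function(x, path) {
  write.table(x$results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ddg
#' @export
read_ddg <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Permutation adjustment of the minimum-p cutoff scan
#'
#' The minimum p-value over a cutoff grid is anti-conservative. This
#' computes the permutation p-value
#' `(1 + #{permutations with min-p <= observed}) / (n_perm + 1)`,
#' permuting the survival (time, event) pairs jointly against expression.
#'
#' @param gene_result a `gene_prognosis` from [scan_cutoff()].
#' @param expr,surv,cfg the inputs used to produce `gene_result`.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return adjusted p-value in (0, 1].
#' @export
permutation_adjust <- function(gene_result, expr, surv, cfg = pipeline_config(),
                               n_perm = 1000L, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  d <- align_surv(expr, surv)
  grid <- cutoff_grid(d$x, cfg)
  if (length(grid) == 0L) no_valid_cutoff("no admissible cutoff")
  set.seed(seed)
  n <- nrow(d)
  perm <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  minp <- .ddg_minp_perm_cpp(d$time, as.integer(d$event), d$x, grid, perm)
  minp <- minp[is.finite(minp)]
  (1 + sum(minp <= gene_result$wald_p)) / (length(minp) + 1)
}
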