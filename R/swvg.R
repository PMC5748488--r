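# Statistically weighted voting grouping (SWVg): each panel gene casts a
# binary high-risk vote through its frozen cutoff/design; votes are combined
# into a normalized weighted score (weights -log10 of the training Wald p)
# and a data-optimized score cutoff separates the low-risk (LR) and
# high-risk (HR) subgroups. Once fitted, the model is frozen: applying it to
# a new cohort uses expression alone, blinded to survival.

#' Binary high-risk vote of one gene
#'
#' Vote 1 assigns the patient to the high-risk side. Design 2 votes 1 when
#' expression is strictly above the cutoff; design 1 when it is at or below
#' (values exactly equal to the cutoff fall on the "at or below" side).
#'
#' @param expr_value numeric expression value(s).
#' @param cutoff gene's frozen cutoff.
#' @param design 1 or 2.
#' @return integer vote(s) in `{0, 1}`.
#' @export
gene_vote <- function(expr_value, cutoff, design) {
  stopifnot(design %in% c(1L, 2L))
  above <- expr_value > cutoff
  as.integer(if (design == 2L) above else !above)
}

#' Normalized weighted-voting score
#'
#' @param votes 0/1 vector, one vote per panel gene.
#' @param weights non-negative weights aligned with `votes`.
#' @return score `sum(w * v) / sum(w)` in `[0, 1]`.
#' @export
swvg_score <- function(votes, weights) {
  if (length(votes) != length(weights)) stop("votes and weights misaligned")
  if (any(weights < 0)) stop("negative weights")
  sw <- sum(weights)
  if (sw <= 0) stop("all-zero weights")
  sum(weights * votes) / sw
}

# Vote matrix (genes x samples) for a panel data.frame with columns
# gene_id, cutoff, design.
vote_matrix <- function(panel, matrix) {
  miss <- setdiff(panel$gene_id, rownames(matrix))
  if (length(miss)) stop("panel genes missing from expression matrix: ",
                         paste(miss, collapse = ", "))
  v <- vapply(seq_len(nrow(panel)), function(j)
    gene_vote(matrix[panel$gene_id[j], ], panel$cutoff[j], panel$design[j]),
    integer(ncol(matrix)))
  t(base::matrix(v, ncol = nrow(panel),
                 dimnames = list(colnames(matrix), panel$gene_id)))
}

#' Fit the weighted-voting classifier
#'
#' Candidate genes (all with training `wald_p <= alpha_sel`) are ordered by
#' ascending p. For every panel prefix of size m the normalized weighted
#' scores are computed with weights `-log10(p)`; score cutoffs are scanned
#' over the midpoints of distinct observed scores under the same group-size
#' admissibility rule as the expression cutoff grid, and the Wald p of the
#' resulting two-group survival split is recorded. The panel size and score
#' cutoff minimizing this p are frozen into the model (ties: smaller panel,
#' then cutoff closest to the median score).
#'
#' @param candidates a `ddg_table` from [batch_scan()] or its `results`
#'   data.frame (columns `gene_id, cutoff, design, wald_p`).
#' @param matrix training `expr_matrix`.
#' @param surv training survival table (`sample_id, os_years, event`).
#' @param cfg a [pipeline_config()].
#' @param max_panel optional cap on the panel size scanned.
#' @param cohort id stored in the model's training metadata.
#' @return an `swvg_model`: `genes` (data.frame `gene_id, cutoff, design,
#'   weight`), `score_cutoff`, `training_meta` (with the per-size selection
#'   trace).
#' @export
fit_swvg <- function(candidates, matrix, surv, cfg = pipeline_config(),
                     max_panel = NULL, cohort = "training") {
  cand <- if (inherits(candidates, "ddg_table")) candidates$results else candidates
  cand <- cand[cand$wald_p <= cfg$alpha_sel, , drop = FALSE]
  if (nrow(cand) == 0L) stop("no candidate gene passes alpha_sel = ", cfg$alpha_sel)
  cand <- cand[order(cand$wald_p, cand$gene_id), , drop = FALSE]
  cand$weight <- -log10(pmax(cand$wald_p, 1e-300))
  surv <- as.data.frame(surv)
  samples <- intersect(colnames(matrix), surv$sample_id)
  if (length(samples) == 0L) stop("no overlapping samples")
  V <- vote_matrix(cand, matrix[, samples, drop = FALSE])
  si <- match(samples, surv$sample_id)
  time <- surv$os_years[si]; event <- as.integer(surv$event[si])
  ord <- order(time)
  M <- if (is.null(max_panel)) nrow(cand) else min(max_panel, nrow(cand))
  trace <- data.frame(m = integer(0), score_cutoff = numeric(0), p = numeric(0))
  best <- NULL
  wsum <- cumsum(cand$weight)
  wV <- cand$weight * V  # row-wise scaling
  num <- apply(wV, 2L, cumsum)
  if (nrow(cand) == 1L) num <- base::matrix(num, nrow = 1L)
  for (m in seq_len(M)) {
    scores <- num[m, ] / wsum[m]
    grid <- cutoff_grid(scores, cfg)
    if (length(grid) == 0L) next
    sc <- .ddg_scan_gene_cpp(time[ord], event[ord], scores[ord], grid)
    sel <- ddg_select_cutoff(grid, sc, scores, "wald")
    if (is.null(sel$ok)) next
    trace <- rbind(trace, data.frame(m = m, score_cutoff = sel$cutoff, p = sel$p))
    if (is.null(best) || sel$p < best$p - 1e-12) {
      best <- list(m = m, cutoff = sel$cutoff, p = sel$p, beta = sel$beta)
    }
  }
  if (is.null(best)) {
    # No admissible score split at any panel size. If the top gene's votes
    # still form two groups, reduce to that single-gene classifier.
    v1 <- V[1L, ]
    if (length(unique(v1)) == 2L) {
      best <- list(m = 1L, cutoff = 0.5, p = cand$wald_p[1L], beta = NA_real_)
    } else {
      stop("degenerate scores: no admissible score cutoff at any panel size")
    }
  }
  panel <- cand[seq_len(best$m), c("gene_id", "cutoff", "design", "weight"),
                drop = FALSE]
  rownames(panel) <- NULL
  structure(list(genes = panel, score_cutoff = best$cutoff,
                 training_meta = list(cohort = cohort,
                                      alpha_sel = cfg$alpha_sel,
                                      train_p = best$p,
                                      trace = trace)),
            class = "swvg_model")
}

#' @export
print.swvg_model <- function(x, ...) {
  cat(sprintf("swvg_model: %d genes, score cutoff %.4f (training p = %.3g, cohort %s)\n",
              nrow(x$genes), x$score_cutoff,
              x$training_meta$train_p, x$training_meta$cohort))
  invisible(x)
}

#' Apply a frozen classifier to a cohort
#'
#' Labels are a pure function of the model and the expression matrix;
#' survival, when supplied, is used only for the post-hoc two-group summary.
#'
#' @param model an `swvg_model`.
#' @param matrix `expr_matrix` containing every panel gene (missing genes are
#'   an error). Samples with a missing (non-finite) value for any panel gene
#'   are flagged in `excluded` and dropped from the summary.
#' @param surv optional survival table for the post-hoc summary.
#' @param conf_level CI level of the summary.
#' @return a `stratification` object: `data` (per-sample `sample_id, score,
#'   label`), `summary` (NULL without survival; otherwise the
#'   [two_group_test()] result plus group sizes), `excluded`.
#' @export
apply_frozen <- function(model, matrix, surv = NULL, conf_level = 0.95) {
  panel <- model$genes
  miss <- setdiff(panel$gene_id, rownames(matrix))
  if (length(miss)) stop("panel genes missing from expression matrix: ",
                         paste(miss, collapse = ", "))
  X <- matrix[panel$gene_id, , drop = FALSE]
  bad <- colnames(X)[!apply(is.finite(X), 2L, all)]
  keep <- setdiff(colnames(X), bad)
  V <- vote_matrix(panel, X[, keep, drop = FALSE])
  scores <- as.numeric(crossprod(V, panel$weight)) / sum(panel$weight)
  names(scores) <- keep
  labels <- ifelse(scores > model$score_cutoff, "HR", "LR")
  data <- data.frame(sample_id = keep, score = unname(scores),
                     label = unname(labels), stringsAsFactors = FALSE)
  summary <- NULL
  if (!is.null(surv)) {
    surv <- as.data.frame(surv)
    i <- match(data$sample_id, surv$sample_id)
    ok <- !is.na(i)
    if (length(unique(data$label[ok])) == 2L) {
      tg <- two_group_test(surv$os_years[i[ok]], surv$event[i[ok]],
                           data$label[ok], conf_level = conf_level)
      summary <- c(tg, list(n_lr = sum(data$label[ok] == "LR"),
                            n_hr = sum(data$label[ok] == "HR")))
    } else {
      summary <- list(degenerate = TRUE,
                      n_lr = sum(data$label[ok] == "LR"),
                      n_hr = sum(data$label[ok] == "HR"))
    }
  }
  structure(list(data = data, summary = summary, excluded = bad,
                 model_cohort = model$training_meta$cohort),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat(sprintf("stratification: %d samples (%d LR, %d HR)\n",
              nrow(x$data), sum(x$data$label == "LR"), sum(x$data$label == "HR")))
  if (!is.null(x$summary) && is.null(x$summary$degenerate))
    cat(sprintf("  HR vs LR hazard ratio %.3g (%.3g-%.3g), Wald p = %.3g\n",
                x$summary$hazard_ratio, x$summary$ci_low, x$summary$ci_high,
                x$summary$wald_p))
  invisible(x)
}

#' Combine PT- and AT-based stratifications
#'
#' A patient is low-risk in the combined stratification iff low-risk in both
#' tissues: `LR_combined = LR_PT` intersect `LR_AT`; everyone else is
#' high-risk.
#'
#' @param labels_pt,labels_at named `"LR"`/`"HR"` vectors keyed by patient id
#'   (or `stratification` objects together with `pairing`).
#' @param pairing optional pairing table used to translate the sample-keyed
#'   labels of `stratification` objects to patient keys.
#' @return named character vector over the intersection of the two patient
#'   sets.
#' @export
combine_pt_at <- function(labels_pt, labels_at, pairing = NULL) {
  to_patient <- function(x, col) {
    if (inherits(x, "stratification")) {
      if (is.null(pairing)) stop("pairing required to combine stratification objects")
      lab <- setNames(x$data$label, x$data$sample_id)
      keep <- pairing[[col]] %in% names(lab)
      setNames(lab[pairing[[col]][keep]], pairing$patient_id[keep])
    } else x
  }
  a <- to_patient(labels_pt, "pt_sample")
  b <- to_patient(labels_at, "at_sample")
  common <- intersect(names(a), names(b))
  if (length(common) == 0L) stop("no patients shared between the two stratifications")
  out <- ifelse(a[common] == "LR" & b[common] == "LR", "LR", "HR")
  setNames(out, common)
}

#' Serialize / load a frozen model as JSON
#'
#' Numeric fields are written with full precision so that a round trip
#' reproduces the model bit-exactly.
#'
#' @param model an `swvg_model`.
#' @param path JSON file path.
#' @export
write_swvg_model <- function(model, path) {
  obj <- list(cohort = model$training_meta$cohort,
              alpha_sel = model$training_meta$alpha_sel,
              train_p = model$training_meta$train_p,
              genes = model$genes,
              score_cutoff = model$score_cutoff)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_swvg_model
#' @export
read_swvg_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  genes <- as.data.frame(obj$genes, stringsAsFactors = FALSE)
  genes$design <- as.integer(genes$design)
  structure(list(genes = genes, score_cutoff = obj$score_cutoff,
                 training_meta = list(cohort = obj$cohort,
                                      alpha_sel = obj$alpha_sel,
                                      train_p = obj$train_p,
                                      trace = NULL)),
            class = "swvg_model")
}

#' The 24-gene ribosomal panel fixture
#'
#' Gene symbols and array probe identifiers of the packaged 24-gene
#' hepatocellular-carcinoma prognostic panel, usable to restrict a scan to
#' the published panel.
#'
#' @return data.frame with columns `gene_id, probe_id`.
#' @export
ribosomal_panel <- function() {
  read.delim(system.file("extdata", "ribosomal_panel_24.tsv",
                         package = "pairsig"),
             header = TRUE, stringsAsFactors = FALSE)
}
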