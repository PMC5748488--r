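# Core containers: expression matrices (genes x samples, log2 scale),
# clinical/survival tables, and the PT/AT pairing that ties them together.

#' Validate and tag an expression matrix
#'
#' An expression matrix is a plain numeric matrix of log2 intensities with
#' unique, non-empty gene identifiers as rownames and sample identifiers as
#' colnames. All values must be finite.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @return the validated matrix (invisibly classed as `expr_matrix`).
#' @export
as_expr_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix is empty")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || any(!nzchar(gid)))
    stop("gene identifiers (rownames) missing or empty")
  if (is.null(sid) || any(!nzchar(sid)))
    stop("sample identifiers (colnames) missing or empty")
  if (anyDuplicated(gid))
    stop("duplicate gene identifiers: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample identifiers: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("non-finite expression values present")
  class(values) <- c("expr_matrix", class(unclass(values)))
  values
}

#' Read an expression matrix from tab-separated text
#'
#' Expected layout: header `gene_id<TAB>S1<TAB>S2...`, one gene per row,
#' numeric body. Duplicate gene rows are collapsed by maximum variance
#' (see [collapse_probes()]).
#'
#' @param path path to a TSV file.
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L)
    stop("expression file ", path, ": need a gene id column plus >= 1 sample")
  ids <- df[[1L]]
  body <- df[, -1L, drop = FALSE]
  num <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body)), USE.NAMES = TRUE))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(body)))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)) > 0L)
    stop(sprintf("expression file %s: non-numeric cell at row %d (gene '%s'), column '%s'",
                 path, bad[1, 1], ids[bad[1, 1]], colnames(body)[bad[1, 2]]))
  if (anyNA(num))
    stop("expression file ", path, ": missing values present")
  rownames(num) <- ids
  if (anyDuplicated(ids)) {
    map <- setNames(ids, make.unique(ids))
    rownames(num) <- names(map)
    num <- collapse_probes(as_expr_matrix(num), map)
  }
  as_expr_matrix(num)
}

#' Write an expression matrix as tab-separated text
#'
#' Values are written with full precision so that
#' `read_expression(write_expression(x))` round-trips bit-exactly.
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x),
                   format(x, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to one row per gene
#'
#' When several probes map to the same gene symbol the probe with the largest
#' variance across samples is retained (ties broken by the lexicographically
#' smallest probe id). The chosen probe id is recorded in the `"probe_id"`
#' attribute.
#'
#' @param matrix an `expr_matrix` whose rownames are probe ids.
#' @param probe_to_gene named character vector mapping probe id -> gene symbol.
#' @return an `expr_matrix` with one row per gene symbol.
#' @export
collapse_probes <- function(matrix, probe_to_gene) {
  if (length(probe_to_gene) == 0L) stop("empty probe-to-gene mapping")
  probes <- rownames(matrix)
  known <- probes[probes %in% names(probe_to_gene)]
  if (length(known) == 0L) stop("no probes of the matrix appear in the mapping")
  genes <- probe_to_gene[known]
  v <- apply(matrix[known, , drop = FALSE], 1L, var)
  ord <- order(genes, -v, known)  # per gene: max variance, then lexicographic
  keep <- ord[!duplicated(genes[ord])]
  chosen <- known[keep]
  out <- matrix[chosen, , drop = FALSE]
  rownames(out) <- unname(genes[chosen])
  out <- as_expr_matrix(out)
  attr(out, "probe_id") <- setNames(chosen, unname(genes[chosen]))
  out
}

#' Read a clinical table
#'
#' Mandatory columns: `sample_id, patient_id, tissue, os_years, event`;
#' any extra columns are carried along as covariates. `tissue` must be
#' `PT` or `AT`; `os_years >= 0`; `event` in `{0,1}`.
#'
#' @param path path to a TSV file.
#' @return validated `data.frame`.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  validate_clinical(df)
}

#' @rdname read_clinical
#' @param clin a clinical `data.frame` to validate in place.
#' @export
validate_clinical <- function(clin) {
  need <- c("sample_id", "patient_id", "tissue", "os_years", "event")
  miss <- setdiff(need, names(clin))
  if (length(miss)) stop("clinical table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(clin$sample_id))
    stop("duplicate sample_id in clinical table")
  if (!all(clin$tissue %in% c("PT", "AT")))
    stop("tissue must be 'PT' or 'AT'")
  if (!is.numeric(clin$os_years) || any(!is.finite(clin$os_years)) ||
      any(clin$os_years < 0))
    stop("os_years must be finite and non-negative")
  if (!all(clin$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (death)")
  # survival is a patient-level quantity: PT and AT rows must agree
  sp <- split(clin[, c("os_years", "event")], clin$patient_id)
  bad <- names(sp)[vapply(sp, function(d)
    length(unique(d$os_years)) > 1L || length(unique(d$event)) > 1L, logical(1))]
  if (length(bad)) stop("patients with inconsistent survival across samples: ",
                        paste(bad, collapse = ", "))
  clin
}

#' Derive the patient-level PT/AT pairing from a clinical table
#'
#' @param clin clinical `data.frame` (see [read_clinical()]).
#' @return `data.frame` with columns `patient_id, pt_sample, at_sample`
#'   (`at_sample` is `NA` for patients without an AT sample). Patients with
#'   an AT sample but no PT sample are dropped with a warning.
#' @export
pair_samples <- function(clin) {
  if (nrow(clin) == 0L) stop("empty clinical table")
  clin <- validate_clinical(clin)
  dup <- with(clin, table(patient_id, tissue))
  bad <- rownames(dup)[apply(dup, 1L, max) > 1L]
  if (length(bad))
    stop("patients with more than one sample of the same tissue: ",
         paste(bad, collapse = ", "))
  pt <- clin[clin$tissue == "PT", ]
  at <- clin[clin$tissue == "AT", ]
  orphan <- setdiff(at$patient_id, pt$patient_id)
  if (length(orphan))
    warning("patients with AT but no PT sample excluded: ",
            paste(orphan, collapse = ", "))
  out <- data.frame(patient_id = pt$patient_id,
                    pt_sample = pt$sample_id,
                    at_sample = at$sample_id[match(pt$patient_id, at$patient_id)],
                    stringsAsFactors = FALSE)
  out[order(out$patient_id), , drop = FALSE]
}

#' Bundle expression and clinical data into a paired cohort
#'
#' @param pt PT `expr_matrix`.
#' @param clin clinical table covering the samples of `pt` (and `at`).
#' @param at optional AT `expr_matrix`.
#' @return a `paired_cohort` list: `pt`, `at`, `clin`, `pairing`.
#' @export
paired_cohort <- function(pt, clin, at = NULL) {
  clin <- validate_clinical(clin)
  pairing <- pair_samples(clin)
  stopifnot(all(pairing$pt_sample %in% colnames(pt)))
  if (!is.null(at)) {
    ats <- pairing$at_sample[!is.na(pairing$at_sample)]
    if (!all(ats %in% colnames(at)))
      stop("AT samples in pairing missing from AT matrix: ",
           paste(setdiff(ats, colnames(at)), collapse = ", "))
  }
  structure(list(pt = pt, at = at, clin = clin, pairing = pairing),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("paired_cohort: %d patients, %d PT samples, %d AT samples, %d genes\n",
              nrow(x$pairing), ncol(x$pt),
              if (is.null(x$at)) 0L else ncol(x$at), nrow(x$pt)))
  invisible(x)
}

#' Pipeline configuration
#'
#' Thresholds used across the pipeline: `alpha_pre` for cross-tissue
#' common-prognostic-gene preselection, `alpha_sel` for panel-gene selection,
#' `deg_q` for differential-expression FDR, `conf_level` for confidence
#' intervals, and the admissibility floor for dichotomizing cutoffs
#' (`min_group_fraction`, `min_group_size` per side).
#'
#' @param alpha_pre preselection significance threshold (default 0.1).
#' @param alpha_sel panel selection threshold (default 0.05).
#' @param min_group_fraction minimum fraction of samples per side (default 0.1).
#' @param min_group_size absolute minimum per side (default 5).
#' @param deg_q FDR threshold for differential expression (default 0.05).
#' @param conf_level confidence level (default 0.95).
#' @param seed integer seed for the pipeline's stochastic stages.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha_pre = 0.1, alpha_sel = 0.05,
                            min_group_fraction = 0.1, min_group_size = 5L,
                            deg_q = 0.05, conf_level = 0.95, seed = 1L) {
  stopifnot(alpha_sel > 0, alpha_sel <= alpha_pre, alpha_pre < 1,
            min_group_fraction > 0, min_group_fraction < 0.5,
            min_group_size >= 1, deg_q > 0, deg_q < 1,
            conf_level > 0.5, conf_level < 1)
  structure(list(alpha_pre = alpha_pre, alpha_sel = alpha_sel,
                 min_group_fraction = min_group_fraction,
                 min_group_size = as.integer(min_group_size),
                 deg_q = deg_q, conf_level = conf_level,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write a clinical table as TSV
#' @param clin clinical `data.frame`.
#' @param path output path.
#' @export
write_clinical <- function(clin, path) {
  write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
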