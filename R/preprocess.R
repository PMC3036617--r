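#' Quantile-normalize a probe intensity matrix across arrays
#'
#' Forces every sample (column) to share the same empirical intensity
#' distribution: rank r in each column is replaced by the mean across
#' columns of the rank-r values; ties within a column receive the mean of
#' the target values they span, which makes the result independent of sort
#' stability. The total sum of the matrix is preserved. This is the
#' between-array normalization step of RMA.
#'
#' @param matrix numeric probe matrix (linear scale), samples in columns.
#' @return normalized matrix, same dimensions and dimnames.
#' @export
quantile_normalize <- function(matrix) {
  if (ncol(matrix) < 2) {
    warning("fewer than 2 samples: quantile normalization is the identity")
    return(matrix)
  }
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Summarize probes to EST-level log2 expression by median polish
#'
#' Per EST, fits the additive model
#' `log2(y_ps) = mu + probe_p + sample_s + r_ps`
#' by alternating row/column median sweeps (Tukey median polish, the
#' summarization engine of RMA), starting with the probe (row) sweep, and
#' reports `mu + sample_s` as that EST's log2 expression in each sample.
#' Probe affinities are absorbed into the row effects, so the summary is
#' robust to individual aberrant probes.
#'
#' @param matrix normalized probe matrix (linear scale).
#' @param design an `array_design`; every design probe must be present
#'   unless it has been filtered, in which case ESTs summarize over their
#'   remaining probes.
#' @param tol convergence tolerance on the log2 scale (default 0.01).
#' @param max_iter maximum sweep iterations (default 10).
#' @return numeric matrix, ESTs in rows (design order), samples in columns.
#' @export
median_polish_summarize <- function(matrix, design, tol = 0.01,
                                    max_iter = 10) {
  stopifnot(inherits(design, "array_design"))
  keep <- design$probes$probe_id %in% rownames(matrix)
  pr <- design$probes[keep, , drop = FALSE]
  if (!nrow(pr)) stop("no design probes present in matrix")
  lost <- setdiff(unique(design$probes$est_id), unique(pr$est_id))
  if (length(lost))
    stop("EST(s) with no probes in matrix: ",
         paste(utils::head(lost, 5), collapse = ", "))
  lg <- log2(matrix)
  ests <- intersect(design$est$est_id, unique(pr$est_id))
  idx <- split(match(pr$probe_id, rownames(matrix)),
               factor(pr$est_id, levels = ests))
  expr <- matrix(NA_real_, length(ests), ncol(matrix),
                 dimnames = list(ests, colnames(matrix)))
  for (k in seq_along(ests)) {
    y <- lg[idx[[k]], , drop = FALSE]
    if (nrow(y) == 1L) {
      expr[k, ] <- y[1, ]
    } else {
      fit <- stats::medpolish(y, eps = tol, maxiter = max_iter,
                              trace.iter = FALSE)
      expr[k, ] <- fit$overall + fit$col
    }
  }
  expr
}

#' Replicate-correlation quality control
#'
#' Computes within-species pairwise Pearson correlations of expression
#' profiles and flags samples whose mean correlation to the other replicates
#' of the same species falls below a threshold; such samples typically
#' reflect degraded RNA or failed hybridizations. Report-only: exclusion is
#' a pipeline option.
#'
#' @param expr EST-level log2 expression matrix.
#' @param sheet sample sheet covering the columns of `expr`.
#' @param threshold flag when mean within-species correlation < this
#'   (default 0.9).
#' @return list with `correlations` (named list of per-species correlation
#'   matrices), `mean_correlation` (named vector), and `flagged` (character
#'   vector of sample ids).
#' @export
sample_qc <- function(expr, sheet, threshold = 0.9) {
  sheet <- sheet[sheet$sample_id %in% colnames(expr), , drop = FALSE]
  cors <- list()
  mean_cor <- numeric()
  for (sp in unique(sheet$species)) {
    ids <- sheet$sample_id[sheet$species == sp]
    if (length(ids) < 3)
      stop("sample_qc needs >= 3 samples per species (", sp, ")")
    cm <- stats::cor(expr[, ids, drop = FALSE])
    cors[[sp]] <- cm
    mc <- (rowSums(cm) - 1) / (length(ids) - 1)
    mean_cor <- c(mean_cor, mc)
  }
  list(correlations = cors,
       mean_correlation = mean_cor,
       flagged = names(mean_cor)[mean_cor < threshold])
}
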