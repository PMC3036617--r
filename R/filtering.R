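#' Subset an array design to a set of ESTs and/or probes
#'
#' @param design an `array_design`.
#' @param est_ids ESTs to keep (default all).
#' @param drop_probes probe ids to drop (e.g. a CGH mask).
#' @return an `array_design` restricted to the requested ESTs/probes. Probe
#'   counts may fall below 8 after dropping; the object is then only valid
#'   as input to summarization/filter accounting, which is why the 8--11
#'   constructor check is not re-applied here.
#' @export
subset_design <- function(design, est_ids = design$est$est_id,
                          drop_probes = character()) {
  stopifnot(inherits(design, "array_design"))
  est <- design$est[design$est$est_id %in% est_ids, , drop = FALSE]
  probes <- design$probes[design$probes$est_id %in% est_ids &
                            !(design$probes$probe_id %in% drop_probes), ,
                          drop = FALSE]
  cnt <- table(factor(probes$est_id, levels = est$est_id))
  est$n_probes <- as.integer(cnt[est$est_id])
  structure(list(est = est, probes = probes), class = "array_design")
}

#' Standard-deviation filter on EST signal
#'
#' Removes noisy ESTs: an EST is dropped when the standard deviation of its
#' unlogged signal across arrays exceeds a fraction (default 30%) of the
#' median unlogged signal of that EST. The rule operates on the unlogged
#' (2^x) scale of the normalized log2 expression values.
#'
#' @param expr EST-level log2 expression matrix.
#' @param threshold fraction of the per-EST median (default 0.30).
#' @return list with `kept` and `removed` character vectors of EST ids.
#' @export
sd_filter <- function(expr, threshold = 0.30) {
  if (ncol(expr) < 2) stop("sd_filter needs >= 2 samples")
  un <- 2^expr
  med <- apply(un, 1, stats::median)
  if (any(med <= 0)) stop("non-positive median signal; input must be log2 of positive intensities")
  sds <- apply(un, 1, stats::sd)
  removed <- rownames(expr)[sds > threshold * med]
  list(kept = setdiff(rownames(expr), removed), removed = removed)
}

#' Annotate a design with CGH-mask retention counts
#'
#' For each EST, counts how many of its probes survive removal of a
#' cross-species (CGH) probe mask: probes that failed to hybridize against
#' the second species' genomic DNA and would otherwise report sequence
#' divergence rather than expression.
#'
#' @param design an `array_design`.
#' @param mask character vector of masked probe ids. Ids not present in the
#'   design are reported with a warning and ignored.
#' @return data frame: `est_id`, `n_probes` (design), `n_masked`,
#'   `retained`.
#' @export
apply_cgh_mask <- function(design, mask) {
  stopifnot(inherits(design, "array_design"))
  unknown <- setdiff(mask, design$probes$probe_id)
  if (length(unknown))
    warning(length(unknown), " mask probe id(s) not in design (ignored)")
  mask <- setdiff(mask, unknown)
  hit <- design$probes$probe_id %in% mask
  n_masked <- tapply(hit, factor(design$probes$est_id,
                                 levels = design$est$est_id), sum)
  data.frame(est_id = design$est$est_id,
             n_probes = design$est$n_probes,
             n_masked = as.integer(n_masked),
             retained = design$est$n_probes - as.integer(n_masked),
             stringsAsFactors = FALSE)
}

#' Probe-retention filter
#'
#' Keeps only ESTs retaining at least `min_probes` probes after masking.
#' The cutoff is an absolute count (default 8, the conventional minimum for
#' reliable probe-set summaries), applied equally to short probe sets: an
#' 8-probe EST that loses any probe is removed.
#'
#' @param masked the annotated design from [apply_cgh_mask()].
#' @param min_probes minimum retained probes (default 8).
#' @return list with `kept`, `removed`, and `lost_tally` (named counts of
#'   ESTs losing exactly 0, 1, 2, 3 or >3 probes among kept ESTs' inputs).
#' @export
retention_filter <- function(masked, min_probes = 8) {
  keep <- masked$retained >= min_probes
  lost <- masked$n_masked
  tally <- c(`0` = sum(lost == 0), `1` = sum(lost == 1),
             `2` = sum(lost == 2), `3` = sum(lost == 3),
             `>3` = sum(lost > 3))
  list(kept = masked$est_id[keep], removed = masked$est_id[!keep],
       lost_tally = tally)
}

#' Apply both filters with exact accounting
#'
#' Runs the standard-deviation filter first and the CGH retention filter
#' second (on the SD survivors), and returns a report whose counts satisfy
#' `n_input - n_removed_sd - n_removed_retention = n_remaining`.
#'
#' @param expr EST-level log2 expression matrix.
#' @param design an `array_design` covering the rows of `expr`.
#' @param mask CGH probe mask (default none).
#' @param sd_threshold SD filter threshold (default 0.30); `Inf` disables.
#' @param min_probes retention cutoff (default 8).
#' @return list with `expr` (filtered matrix), `kept`, and `report` (class
#'   `filter_report`).
#' @export
filter_ests <- function(expr, design, mask = character(),
                        sd_threshold = 0.30, min_probes = 8) {
  n_input <- nrow(expr)
  sdres <- if (is.finite(sd_threshold)) sd_filter(expr, sd_threshold)
           else list(kept = rownames(expr), removed = character())
  masked <- apply_cgh_mask(design, mask)
  masked <- masked[masked$est_id %in% sdres$kept, , drop = FALSE]
  ret <- retention_filter(masked, min_probes)
  kept <- ret$kept
  report <- structure(list(
    n_input = n_input,
    n_removed_sd = length(sdres$removed),
    n_removed_retention = length(ret$removed),
    n_remaining = length(kept),
    removed_sd = sdres$removed,
    removed_retention = ret$removed,
    lost_tally = ret$lost_tally,
    retained_probes = stats::setNames(masked$retained, masked$est_id)
  ), class = "filter_report")
  stopifnot(report$n_input - report$n_removed_sd -
              report$n_removed_retention == report$n_remaining)
  list(expr = expr[kept, , drop = FALSE], kept = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$n_input, "ESTs in;",
      x$n_removed_sd, "removed by SD filter;",
      x$n_removed_retention, "removed by probe-retention filter;",
      x$n_remaining, "remaining\n")
  invisible(x)
}
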