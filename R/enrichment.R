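#' Expected Z proportion under a random genomic distribution
#'
#' The fraction of the annotated array background that is Z-linked: the
#' proportion of sex-biased genes expected on Z if sex bias were distributed
#' at random over annotated loci.
#'
#' @param background_z,background_a background counts of Z-linked and
#'   autosomal loci.
#' @return list with `proportion` (full precision) and `rounded` (3 dp).
#' @export
expected_proportion <- function(background_z, background_a) {
  tot <- background_z + background_a
  if (tot <= 0) stop("background total must be positive")
  p <- background_z / tot
  list(proportion = p, rounded = round(p, 3))
}

# two-sided Fisher exact p by the method of small p-values: sum the
# hypergeometric probabilities of all tables with the observed margins that
# are no more probable than the observed table
.fisher_p_two_sided <- function(k, m, n, draw) {
  lo <- max(0L, draw - n)
  hi <- min(draw, m)
  probs <- stats::dhyper(lo:hi, m, n, draw)
  p0 <- stats::dhyper(k, m, n, draw)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

#' Fisher exact test of Z enrichment against the array background
#'
#' Tests whether an observed set of sex-biased loci is distributed between
#' the Z chromosome and the autosomes differently from the array background,
#' using the 2x2 table
#' `[[obs_z, obs_a], [background_z - obs_z, background_a - obs_a]]`.
#' The two-sided p sums hypergeometric probabilities of all tables with the
#' same margins that are no more probable than the observed one. The odds
#' ratio is the sample cross-product ratio; when a cell is zero a
#' Haldane-corrected version (+0.5 to each cell) is reported separately.
#'
#' @param obs_z,obs_a observed Z-linked / autosomal counts.
#' @param background_z,background_a array background counts (must dominate
#'   the observed counts).
#' @return object of class `enrichment_result`: list with `observed_z`,
#'   `observed_a`, `observed_prop_z`, `expected_prop_z`, `background_z`,
#'   `background_a`, `p_value`, `odds_ratio`, `odds_ratio_corrected`.
#' @export
fisher_enrichment <- function(obs_z, obs_a, background_z, background_a) {
  if (obs_z > background_z || obs_a > background_a)
    stop("observed counts exceed background counts")
  if (obs_z + obs_a == 0) stop("empty observed set")
  p <- .fisher_p_two_sided(obs_z, background_z, background_a, obs_z + obs_a)
  rest_z <- background_z - obs_z
  rest_a <- background_a - obs_a
  or <- (obs_z * rest_a) / (obs_a * rest_z)
  orc <- ((obs_z + 0.5) * (rest_a + 0.5)) /
    ((obs_a + 0.5) * (rest_z + 0.5))
  structure(list(
    observed_z = obs_z, observed_a = obs_a,
    observed_prop_z = obs_z / (obs_z + obs_a),
    expected_prop_z = expected_proportion(background_z, background_a)$proportion,
    background_z = background_z, background_a = background_a,
    p_value = p, odds_ratio = or,
    odds_ratio_corrected = if (any(c(obs_z, obs_a, rest_z, rest_a) == 0)) orc
                           else NA_real_
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: %d Z / %d autosomal observed (prop Z %.3f, expected %.3f), Fisher p = %.3g\n",
    x$observed_z, x$observed_a, x$observed_prop_z, x$expected_prop_z,
    x$p_value))
  invisible(x)
}

#' Genomic-distribution report for sex-biased genes
#'
#' For the male-biased and female-biased unambiguous gene sets separately:
#' observed Z / autosomal / no-annotation counts, the observed and expected
#' Z proportions, and the Fisher exact enrichment test against the array
#' background. Unannotated genes are reported for the histogram but excluded
#' from the 2x2 test. The background is counted at the EST level by default
#' (every annotated probe set on the array), optionally at the gene level.
#'
#' @param gene_calls a [collapse_genes()] result.
#' @param design the full `array_design` (the background).
#' @param evalue_threshold E-value cutoff for background classification.
#' @param background `"est"` (default) or `"gene"`.
#' @return list with `background` (counts), `expected_prop_z`, and per
#'   direction (`male`, `female`) either an `enrichment_result` plus a
#'   `counts` vector (Z/autosomal/none), or a skip note when the direction
#'   set is empty or unannotated.
#' @export
distribution_report <- function(gene_calls, design, evalue_threshold = 1e-20,
                                background = c("est", "gene")) {
  background <- match.arg(background)
  cls <- classify_chromosome(design$est$chromosome, design$est$evalue,
                             evalue_threshold)
  if (background == "gene") {
    gkey <- ifelse(is.na(design$est$gene_id), design$est$est_id,
                   design$est$gene_id)
    cls <- vapply(split(cls, gkey), function(v) v[1], "")
  }
  bg_z <- sum(cls == "Z")
  bg_a <- sum(cls == "autosomal")
  out <- list(background = c(Z = bg_z, autosomal = bg_a,
                             none = sum(cls == "none")),
              expected_prop_z = expected_proportion(bg_z, bg_a)$proportion)
  g <- gene_calls$genes[gene_calls$genes$direction != "ambiguous", ,
                        drop = FALSE]
  for (dir in c("male", "female")) {
    gd <- g[g$direction == dir, , drop = FALSE]
    counts <- c(Z = sum(gd$chromosome_class == "Z"),
                autosomal = sum(gd$chromosome_class == "autosomal"),
                none = sum(gd$chromosome_class == "none"))
    if (nrow(gd) == 0) {
      out[[dir]] <- list(counts = counts, test = NULL,
                         note = "empty direction set; test skipped")
    } else if (counts["Z"] + counts["autosomal"] == 0) {
      out[[dir]] <- list(counts = counts, test = NULL,
                         note = "no annotated genes; test skipped")
    } else {
      out[[dir]] <- list(counts = counts,
                         test = fisher_enrichment(counts[["Z"]],
                                                  counts[["autosomal"]],
                                                  bg_z, bg_a),
                         note = NULL)
    }
  }
  out
}
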