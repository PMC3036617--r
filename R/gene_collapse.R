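#' Chromosome class of an annotation under the E-value rule
#'
#' An EST counts as Z-linked or autosomal only when its BLAST best hit is
#' significant at `evalue <= threshold`; weaker or absent hits are "none"
#' (no annotation).
#'
#' @param chromosome character vector of chromosome names (`"Z"`, autosome
#'   names, `"none"` or `NA`).
#' @param evalue numeric vector of E-values (`NA` = no hit).
#' @param threshold significance cutoff (default 1e-20).
#' @return character vector over `{"Z", "autosomal", "none"}`.
#' @export
classify_chromosome <- function(chromosome, evalue, threshold = 1e-20) {
  ok <- !is.na(evalue) & evalue <= threshold &
    !is.na(chromosome) & chromosome != "none"
  ifelse(ok & chromosome == "Z", "Z", ifelse(ok, "autosomal", "none"))
}

#' Collapse significant ESTs to non-redundant genes
#'
#' Groups significant ESTs by shared gene id (ESTs without a gene id are
#' their own singleton genes), assigns a per-gene direction -- `male` or
#' `female` when all member ESTs agree, `ambiguous` when both directions
#' occur -- a chromosome class under the E-value rule, and the arithmetic
#' mean fold change over member ESTs.
#'
#' @param est_calls data frame of significant ESTs with columns `est_id`,
#'   `direction` (`male`/`female`), `fc`.
#' @param design an `array_design` supplying gene ids and annotation.
#' @param evalue_threshold E-value cutoff for chromosome classification.
#' @return object of class `gene_calls`: list with `genes` (data frame:
#'   `gene_id`, `n_ests`, `est_ids`, `direction`, `majority_direction`,
#'   `chromosome_class`, `mean_fc`), and counts `n_genes`, `n_multi`,
#'   `n_ambiguous`.
#' @export
collapse_genes <- function(est_calls, design, evalue_threshold = 1e-20) {
  stopifnot(inherits(design, "array_design"),
            all(c("est_id", "direction", "fc") %in% names(est_calls)))
  ann <- design$est[match(est_calls$est_id, design$est$est_id), ]
  if (anyNA(ann$est_id))
    stop("est_call id(s) not in design: ",
         paste(utils::head(est_calls$est_id[is.na(ann$est_id)], 5),
               collapse = ", "))
  gkey <- ifelse(is.na(ann$gene_id), est_calls$est_id, ann$gene_id)
  cls <- classify_chromosome(ann$chromosome, ann$evalue, evalue_threshold)
  idx <- split(seq_len(nrow(est_calls)), gkey)
  rows <- lapply(names(idx), function(g) {
    i <- idx[[g]]
    dirs <- est_calls$direction[i]
    n_m <- sum(dirs == "male"); n_f <- sum(dirs == "female")
    direction <- if (n_m > 0 && n_f > 0) "ambiguous"
                 else if (n_m > 0) "male" else "female"
    majority <- if (n_m > n_f) "male" else if (n_f > n_m) "female" else "tie"
    ccls <- cls[i]
    ucls <- unique(ccls)
    if (length(ucls) > 1) {
      warning("gene ", g, " members map to different chromosome classes")
      tb <- sort(table(ccls), decreasing = TRUE)
      chosen <- if (length(tb) > 1 && tb[1] == tb[2]) "none" else names(tb)[1]
    } else chosen <- ucls
    data.frame(gene_id = g, n_ests = length(i),
               est_ids = paste(est_calls$est_id[i], collapse = ","),
               direction = direction, majority_direction = majority,
               chromosome_class = chosen,
               mean_fc = mean(est_calls$fc[i]),
               stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  if (is.null(genes))
    genes <- data.frame(gene_id = character(), n_ests = integer(),
                        est_ids = character(), direction = character(),
                        majority_direction = character(),
                        chromosome_class = character(), mean_fc = numeric(),
                        stringsAsFactors = FALSE)
  structure(list(genes = genes,
                 n_genes = nrow(genes),
                 n_multi = sum(genes$n_ests > 1),
                 n_ambiguous = sum(genes$direction == "ambiguous")),
            class = "gene_calls")
}

#' @export
print.gene_calls <- function(x, ...) {
  cat("gene_calls:", x$n_genes, "non-redundant genes (",
      x$n_multi, "multi-EST,", x$n_ambiguous, "ambiguous )\n")
  invisible(x)
}

#' Direction-wise summary of sex-biased ESTs and genes
#'
#' Builds the standard bookkeeping table: per direction, the number of
#' significant ESTs, the number of unambiguous genes, each as a percentage
#' of all sex-biased ESTs (resp. of all unambiguous sex-biased genes), and
#' the mean fold change over the non-redundant genes of that direction.
#' Percentages are additionally reported rounded to two significant digits,
#' the precision such tables are printed at.
#'
#' @param gene_calls a [collapse_genes()] result.
#' @param est_calls the significant-EST data frame given to
#'   [collapse_genes()].
#' @return data frame with rows `male`/`female` and columns `n_ests`,
#'   `n_genes`, `pct_ests`, `pct_genes`, `pct_ests_rounded`,
#'   `pct_genes_rounded`, `mean_fc_genes`.
#' @export
summarize_table1 <- function(gene_calls, est_calls) {
  g <- gene_calls$genes
  n_est_tot <- nrow(est_calls)
  unamb <- g[g$direction != "ambiguous", , drop = FALSE]
  n_gene_tot <- nrow(unamb)
  row_for <- function(dir) {
    ne <- sum(est_calls$direction == dir)
    gd <- unamb[unamb$direction == dir, , drop = FALSE]
    ng <- nrow(gd)
    pe <- if (n_est_tot) 100 * ne / n_est_tot else NA_real_
    pg <- if (n_gene_tot) 100 * ng / n_gene_tot else NA_real_
    data.frame(direction = dir, n_ests = ne, n_genes = ng,
               pct_ests = pe, pct_genes = pg,
               pct_ests_rounded = signif(pe, 2),
               pct_genes_rounded = signif(pg, 2),
               mean_fc_genes = if (ng) mean(gd$mean_fc) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(row_for("male"), row_for("female"))
}
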