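# Independent oracles used by the tests. These are deliberately naive,
# loop-based implementations kept separate from the package code paths they
# check.

# Plain two-way median polish, iterated to convergence.
oracle_median_polish <- function(y, tol = 1e-10, max_iter = 500) {
  overall <- 0
  row_eff <- rep(0, nrow(y))
  col_eff <- rep(0, ncol(y))
  r <- y
  for (it in seq_len(max_iter)) {
    rmed <- apply(r, 1, median)
    r <- r - rmed
    row_eff <- row_eff + rmed
    cm <- median(col_eff)
    overall <- overall + cm
    col_eff <- col_eff - cm
    cmed <- apply(r, 2, median)
    r <- sweep(r, 2, cmed)
    col_eff <- col_eff + cmed
    rm2 <- median(row_eff)
    overall <- overall + rm2
    row_eff <- row_eff - rm2
    if (max(abs(rmed)) < tol && max(abs(cmed)) < tol) break
  }
  list(overall = overall, row = row_eff, col = col_eff, residuals = r)
}

# Two-sided Fisher exact p by explicit enumeration of every table with the
# observed margins, from first principles (log factorials, no dhyper).
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; n <- r1 + r2
  lfac <- lfactorial
  tab_logp <- function(x) {
    # table [[x, r1-x], [c1-x, r2-(c1-x)]]
    lfac(r1) + lfac(r2) + lfac(c1) + lfac(c2) - lfac(n) -
      (lfac(x) + lfac(r1 - x) + lfac(c1 - x) + lfac(c2 - r1 + x))
  }
  lo <- max(0, r1 - c2)
  hi <- min(r1, c1)
  lp <- vapply(lo:hi, tab_logp, numeric(1))
  p0 <- tab_logp(a)
  sum(exp(lp[lp <= p0 + 1e-7]))
}

# Brute-force evaluation of the s0 scan criterion over the same candidates.
oracle_s0_scan <- function(r, s) {
  cands <- unname(quantile(s, seq(0, 0.95, by = 0.05)))
  br <- unique(quantile(s, seq(0, 1, by = 0.05)))
  win <- cut(s, breaks = br, include.lowest = TRUE)
  best <- NULL; best_cv <- Inf
  for (alpha in cands) {
    da <- r / (s + alpha)
    mads <- c()
    for (w in levels(win)) {
      v <- da[win == w]
      if (length(v)) mads <- c(mads, mad(v))
    }
    cv <- sd(mads) / mean(mads)
    if (is.finite(cv) && cv < best_cv) { best_cv <- cv; best <- alpha }
  }
  best
}

# Tiny design builder: n ESTs, k probes each, optional annotation vectors.
toy_design <- function(n, k = 11, gene_id = NA, chromosome = NA, evalue = NA) {
  ids <- sprintf("E%04d", seq_len(n))
  array_design(ids,
               lapply(ids, function(e) paste0(e, "_p", seq_len(k))),
               gene_id = gene_id, chromosome = chromosome, evalue = evalue)
}

# Gene-call fixture builder: data frame of significant EST calls plus the
# matching design, from a per-gene specification list with fields
# n_est_male, n_est_female (counts of member ESTs by direction).
build_call_fixture <- function(spec_genes, chromosome = "Z",
                               evalue = 1e-30) {
  est_id <- character(); gene <- character(); dir <- character()
  for (i in seq_along(spec_genes)) {
    g <- spec_genes[[i]]
    nm <- g$n_est_male %||% 0
    nf <- g$n_est_female %||% 0
    k <- nm + nf
    ids <- sprintf("G%04d_e%d", i, seq_len(k))
    est_id <- c(est_id, ids)
    gene <- c(gene, rep(sprintf("G%04d", i), k))
    dir <- c(dir, rep(c("male", "female"), c(nm, nf)))
  }
  design <- array_design(
    est_id,
    lapply(est_id, function(e) paste0(e, "_p", 1:8)),
    gene_id = gene, chromosome = chromosome, evalue = evalue)
  calls <- data.frame(est_id = est_id, direction = dir,
                      fc = ifelse(dir == "male", 1.1, 0.8),
                      stringsAsFactors = FALSE)
  list(design = design, calls = calls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
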