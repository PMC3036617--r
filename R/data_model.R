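#' Construct an array design
#'
#' An array design maps every probe on the array to the EST (probe set) it
#' interrogates, and every EST to its optional gene annotation: a gene id
#' shared between redundant ESTs, a chromosome assignment, and the BLAST
#' E-value supporting that assignment. ESTs without a gene id are treated as
#' non-redundant genes of their own throughout the pipeline.
#'
#' @param est_id character vector of EST ids (unique).
#' @param probe_ids list of character vectors, one per EST, each of length
#'   8--11; probe ids must be globally unique.
#' @param gene_id character vector or `NA`; shared values mark redundant ESTs.
#' @param chromosome character vector; `"Z"` marks sex linkage, any other
#'   name is taken as an autosome, `"none"` (or `NA`) as unannotated.
#' @param evalue numeric vector of BLAST best-hit E-values, or `NA` when the
#'   EST has no hit. The E <= 1e-20 significance rule is applied downstream
#'   by [classify_chromosome()], not here.
#'
#' @return An object of class `array_design`: a list with elements `est`
#'   (data frame: `est_id`, `gene_id`, `chromosome`, `evalue`, `n_probes`)
#'   and `probes` (data frame: `probe_id`, `est_id`).
#' @export
array_design <- function(est_id, probe_ids, gene_id = NA_character_,
                         chromosome = NA_character_, evalue = NA_real_) {
  n <- length(est_id)
  stopifnot(is.list(probe_ids), length(probe_ids) == n)
  if (anyDuplicated(est_id))
    stop("duplicate est_id: ", paste(unique(est_id[duplicated(est_id)]), collapse = ", "))
  gene_id    <- rep_len(as.character(gene_id), n)
  chromosome <- rep_len(as.character(chromosome), n)
  evalue     <- rep_len(as.numeric(evalue), n)
  if (any(!is.na(evalue) & evalue < 0)) stop("negative evalue")
  counts <- lengths(probe_ids)
  bad <- which(counts < 8L | counts > 11L)
  if (length(bad))
    stop("probe count outside 8-11 for EST(s): ",
         paste(est_id[bad], collapse = ", "))
  all_probes <- unlist(probe_ids, use.names = FALSE)
  dup <- unique(all_probes[duplicated(all_probes)])
  if (length(dup))
    stop("probe id(s) assigned to more than one EST: ",
         paste(utils::head(dup, 5), collapse = ", "))
  structure(
    list(
      est = data.frame(est_id = as.character(est_id), gene_id = gene_id,
                       chromosome = chromosome, evalue = evalue,
                       n_probes = counts, stringsAsFactors = FALSE),
      probes = data.frame(probe_id = all_probes,
                          est_id = rep(as.character(est_id), counts),
                          stringsAsFactors = FALSE)
    ),
    class = "array_design"
  )
}

#' @export
print.array_design <- function(x, ...) {
  cat("array_design:", nrow(x$est), "ESTs,", nrow(x$probes), "probes\n")
  cat("  annotated Z:", sum(x$est$chromosome %in% "Z"),
      "| with gene_id:", sum(!is.na(x$est$gene_id)), "\n")
  invisible(x)
}

#' Read / write an array design table
#'
#' The design file is UTF-8 TSV with a single header row and columns
#' `est_id`, `probe_ids` (comma-joined, in probe order), `gene_id`,
#' `chromosome`, `evalue`; the last three may be empty.
#'
#' @param path file path.
#' @return [read_design()] returns an `array_design`; [write_design()]
#'   returns `path` invisibly.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = "")
  need <- c("est_id", "probe_ids", "gene_id", "chromosome", "evalue")
  if (!all(need %in% names(df)))
    stop("design file lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  array_design(
    est_id     = df$est_id,
    probe_ids  = strsplit(df$probe_ids, ",", fixed = TRUE),
    gene_id    = df$gene_id,
    chromosome = df$chromosome,
    evalue     = suppressWarnings(as.numeric(df$evalue))
  )
}

#' @rdname read_design
#' @param design an `array_design`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "array_design"))
  pid <- split(design$probes$probe_id, factor(design$probes$est_id,
                                              levels = design$est$est_id))
  out <- data.frame(
    est_id     = design$est$est_id,
    probe_ids  = vapply(pid, paste, "", collapse = ","),
    gene_id    = design$est$gene_id,
    chromosome = design$est$chromosome,
    evalue     = ifelse(is.na(design$est$evalue), NA,
                        formatC(design$est$evalue, format = "e", digits = 6)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

# shared reader for probe_id/est_id-keyed numeric TSV matrices
.read_matrix_tsv <- function(path, key) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1] != key)
    stop("first column must be '", key, "', found '", names(df)[1], "'")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  rownames(m) <- df[[1]]
  if (anyDuplicated(rownames(m))) stop("duplicate row key in ", path)
  m
}

.write_matrix_tsv <- function(m, path, key, digits) {
  fm <- matrix(sprintf(paste0("%.", digits, "f"), m), nrow = nrow(m),
               dimnames = dimnames(m))
  df <- data.frame(rownames(m), fm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- key
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write probe-level intensity matrices
#'
#' Probe matrices are TSV files: first column `probe_id`, one column per
#' sample, entries strictly positive linear-scale intensities. Values are
#' written at a fixed decimal precision so that write -> read round-trips
#' are exact at that precision.
#'
#' @param path file path.
#' @param design optional `array_design`; when given, probe ids not in the
#'   design are an error.
#' @return a numeric matrix with probe ids as row names.
#' @export
read_probe_matrix <- function(path, design = NULL) {
  m <- .read_matrix_tsv(path, "probe_id")
  if (any(!is.finite(m)) || any(m <= 0))
    stop("probe intensities must be finite and > 0 (log2 must be defined)")
  if (!is.null(design)) {
    unknown <- setdiff(rownames(m), design$probes$probe_id)
    if (length(unknown))
      stop("probe id(s) not in design: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  m
}

#' @rdname read_probe_matrix
#' @param matrix numeric matrix, probe ids as row names.
#' @param digits decimal places written (default 6).
#' @export
write_probe_matrix <- function(matrix, path, digits = 6) {
  if (any(!is.finite(matrix)) || any(matrix <= 0))
    stop("probe intensities must be finite and > 0")
  .write_matrix_tsv(matrix, path, "probe_id", digits)
}

#' Read / write EST-level log2 expression matrices
#'
#' Same TSV layout as probe matrices but keyed by `est_id`; entries are
#' log2 expression values and may be negative.
#'
#' @inheritParams read_probe_matrix
#' @export
read_expression <- function(path) .read_matrix_tsv(path, "est_id")

#' @rdname read_expression
#' @param matrix numeric matrix, EST ids as row names.
#' @param digits decimal places written (default 6).
#' @export
write_expression <- function(matrix, path, digits = 6)
  .write_matrix_tsv(matrix, path, "est_id", digits)

#' Read / write the sample sheet
#'
#' TSV with columns `sample_id`, `species`, `sex` (`male`/`female`) and an
#' optional `population` column.
#'
#' @param path file path.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = "")
  need <- c("sample_id", "species", "sex")
  if (!all(need %in% names(df)))
    stop("sample sheet lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  if (!all(df$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (is.null(df$population)) df$population <- NA_character_
  df
}

#' @rdname read_sample_sheet
#' @param sheet sample-sheet data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a CGH probe mask (one probe id per line, no header)
#' @param path file path.
#' @export
read_mask <- function(path) {
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname read_mask
#' @param mask character vector of probe ids.
#' @export
write_mask <- function(mask, path) {
  writeLines(mask, path)
  invisible(path)
}

#' Cross-validate a design, probe matrix and sample sheet
#'
#' Report-only consistency check run before any analysis stage: finds design
#' probes missing from the matrix, matrix probes unknown to the design,
#' matrix samples absent from the sheet (and vice versa), and species/sex
#' cells with fewer than 2 replicates.
#'
#' @param design an `array_design`.
#' @param matrix a probe matrix.
#' @param sheet a sample sheet.
#' @return data frame of issues (`type`, `id`, `detail`); zero rows when the
#'   trio is consistent.
#' @export
validate_experiment <- function(design, matrix, sheet) {
  issues <- list()
  add <- function(type, id, detail)
    issues[[length(issues) + 1L]] <<- data.frame(type = type, id = id,
                                                 detail = detail,
                                                 stringsAsFactors = FALSE)
  miss <- setdiff(design$probes$probe_id, rownames(matrix))
  for (p in miss) add("missing_probe", p, "design probe absent from matrix")
  unk <- setdiff(rownames(matrix), design$probes$probe_id)
  for (p in unk) add("unknown_probe", p, "matrix probe absent from design")
  orphan <- setdiff(colnames(matrix), sheet$sample_id)
  for (s in orphan) add("orphan_sample", s, "matrix sample absent from sheet")
  in_mat <- sheet[sheet$sample_id %in% colnames(matrix), , drop = FALSE]
  if (nrow(in_mat)) {
    tab <- table(in_mat$species, in_mat$sex)
    for (sp in rownames(tab)) for (sx in c("male", "female")) {
      k <- if (sx %in% colnames(tab)) tab[sp, sx] else 0L
      if (k < 2L)
        add("low_replication", sp,
            sprintf("only %d %s sample(s) in matrix", k, sx))
    }
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(type = character(), id = character(),
                  detail = character(), stringsAsFactors = FALSE)
}
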