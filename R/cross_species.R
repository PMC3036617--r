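#' Compare sex-biased gene calls between two species
#'
#' Partitions the union of the two species' sex-biased gene sets into:
#' genes biased toward the same sex in both species (`shared_same_direction`),
#' genes with reversed direction (`reversed`), genes ambiguous in both
#' (`shared_ambiguous`), genes ambiguous in one species whose majority
#' direction disagrees with the other species' call
#' (`discordant_ambiguous`), and genes called in only one species
#' (`unique_a`, `unique_b`). A gene ambiguous in one species but directional
#' in the other joins `shared_same_direction` when the directional call
#' matches the ambiguous gene's majority direction. Genes of A whose member
#' ESTs were entirely filtered away in species B can be supplied as
#' `untestable_b`; they are reported separately rather than counted as
#' evidence of species-specific bias.
#'
#' Both call sets must come from the same array design so gene ids share a
#' namespace.
#'
#' @param calls_a,calls_b [collapse_genes()] results for the two species.
#' @param untestable_b gene ids not testable in species B (filtered out).
#' @return object of class `species_comparison`: list of gene-id sets
#'   (`shared_same_direction`, `reversed`, `shared_ambiguous`,
#'   `discordant_ambiguous`, `unique_a`, `unique_b`, `untestable_in_b`),
#'   plus `class_counts` (per-category chromosome-class tables, classes
#'   taken from species A where available, else B).
#' @export
compare_species <- function(calls_a, calls_b, untestable_b = character()) {
  a <- calls_a$genes
  b <- calls_b$genes
  cls <- c(stats::setNames(a$chromosome_class, a$gene_id),
           stats::setNames(b$chromosome_class,
                           b$gene_id)[setdiff(b$gene_id, a$gene_id)])
  dir_a <- stats::setNames(a$direction, a$gene_id)
  dir_b <- stats::setNames(b$direction, b$gene_id)
  maj_a <- stats::setNames(a$majority_direction, a$gene_id)
  maj_b <- stats::setNames(b$majority_direction, b$gene_id)
  both <- intersect(a$gene_id, b$gene_id)
  shared <- reversed <- shared_amb <- discordant <- character()
  for (g in both) {
    da <- dir_a[[g]]; db <- dir_b[[g]]
    if (da == "ambiguous" && db == "ambiguous") {
      shared_amb <- c(shared_amb, g)
    } else if (da == "ambiguous" || db == "ambiguous") {
      maj <- if (da == "ambiguous") maj_a[[g]] else maj_b[[g]]
      oth <- if (da == "ambiguous") db else da
      if (maj == oth) shared <- c(shared, g)
      else discordant <- c(discordant, g)
    } else if (da == db) {
      shared <- c(shared, g)
    } else {
      reversed <- c(reversed, g)
    }
  }
  unique_a <- setdiff(a$gene_id, union(b$gene_id, untestable_b))
  untest <- intersect(setdiff(a$gene_id, b$gene_id), untestable_b)
  unique_b <- setdiff(b$gene_id, a$gene_id)
  sets <- list(shared_same_direction = shared, reversed = reversed,
               shared_ambiguous = shared_amb,
               discordant_ambiguous = discordant,
               unique_a = unique_a, unique_b = unique_b,
               untestable_in_b = untest)
  class_counts <- lapply(sets, function(ids) {
    v <- cls[ids]
    c(Z = sum(v == "Z"), autosomal = sum(v == "autosomal"),
      none = sum(v == "none"))
  })
  structure(c(sets, list(class_counts = class_counts)),
            class = "species_comparison")
}

#' @export
print.species_comparison <- function(x, ...) {
  cat("species_comparison:\n")
  for (nm in c("shared_same_direction", "reversed", "shared_ambiguous",
               "discordant_ambiguous", "unique_a", "unique_b",
               "untestable_in_b"))
    cat(sprintf("  %-22s %d\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Overlap between two id sets
#'
#' Used e.g. to verify that genes differing between populations are not the
#' same genes that differ between the sexes, i.e. that the sex signal is not
#' a sampling-site artifact.
#'
#' @param set_1,set_2 character vectors of gene or EST ids.
#' @return list with `count` and `ids` (the intersection).
#' @export
overlap_check <- function(set_1, set_2) {
  ids <- intersect(set_1, set_2)
  list(count = length(ids), ids = ids)
}
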