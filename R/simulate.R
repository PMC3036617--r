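#' Simulation configuration
#'
#' Defines a two-species probe-level expression experiment with known ground
#' truth. The defaults emulate the study design the pipeline targets: a
#' 23,136-EST songbird array scaled down to 2,000 ESTs, 11 probes per EST
#' with a small fraction of shorter probe sets, ~4.6% Z-linked ESTs, six
#' replicates per sex per species, a male-biased dosage effect on a third of
#' Z-linked genes (incomplete dosage compensation in the ZW female), a small
#' minority of autosomal sex-biased genes in either direction, and ~3.9%
#' probe dropout in the second species from failed cross-species
#' hybridization.
#'
#' @param n_ests number of ESTs (probe sets) on the array.
#' @param short_frac fraction of ESTs carrying 8--10 probes instead of 11.
#' @param frac_z fraction of ESTs annotated to the Z chromosome.
#' @param frac_unannotated fraction of ESTs with no chromosome annotation.
#' @param n_per_sex replicates per sex per species.
#' @param frac_z_uncompensated fraction of Z-linked genes with a male dosage
#'   effect (i.e. escaping compensation).
#' @param dosage_log2fc male - female log2 effect for uncompensated Z genes.
#' @param frac_autosomal_biased fraction of autosomal ESTs sex-biased.
#' @param autosomal_effect_log2 absolute log2 effect for autosomal biased
#'   genes; sign is random so female bias occurs.
#' @param frac_effect_shared probability a true effect is present in both
#'   species (otherwise it is private to one species, chosen at random).
#' @param baseline_mean,baseline_sd log2 baseline expression distribution.
#' @param probe_affinity_sd sd of per-probe multiplicative affinity (log2).
#' @param noise_sd sd of per-observation residual noise (log2).
#' @param redundancy_rate fraction of annotated ESTs placed in two-EST genes.
#' @param cgh_dropout_frac fraction of probes masked for species B.
#' @param mask_depression log2 units by which masked probes are depressed in
#'   species B relative to their EST baseline.
#' @param mask_noise_sd extra noise sd on masked-probe signal.
#' @param species labels for the two species.
#' @param seed integer seed; the same seed reproduces the experiment
#'   byte-for-byte.
#'
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_ests = 2000,
                       short_frac = 148 / 23136,
                       frac_z = 0.046,
                       frac_unannotated = 4107 / 23136,
                       n_per_sex = 6,
                       frac_z_uncompensated = 0.33,
                       dosage_log2fc = log2(1.2),
                       frac_autosomal_biased = 0.002,
                       autosomal_effect_log2 = 0.6,
                       frac_effect_shared = 0.5,
                       baseline_mean = 8.0,
                       baseline_sd = 1.5,
                       probe_affinity_sd = 0.7,
                       noise_sd = 0.25,
                       redundancy_rate = 0.1,
                       cgh_dropout_frac = 9827 / 254430,
                       mask_depression = 3.0,
                       mask_noise_sd = 1.0,
                       species = c("speciesA", "speciesB"),
                       seed = 1L) {
  cfg <- as.list(environment())
  fr <- c("short_frac", "frac_z", "frac_unannotated", "frac_z_uncompensated",
          "frac_autosomal_biased", "frac_effect_shared", "redundancy_rate",
          "cgh_dropout_frac")
  for (f in fr)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0,1]")
  for (s in c("baseline_sd", "probe_affinity_sd", "noise_sd", "mask_noise_sd"))
    if (cfg[[s]] < 0) stop(s, " must be >= 0")
  if (cfg$n_per_sex < 2) stop("n_per_sex must be >= 2")
  if (cfg$n_ests < 1) stop("n_ests must be >= 1")
  if (length(cfg$species) != 2) stop("exactly two species labels required")
  structure(cfg, class = "sim_config")
}

# run code under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a two-species probe-level experiment with known truth
#'
#' Generates an array design, sample sheet, one probe intensity matrix per
#' species, a CGH probe mask for species B, and a truth table recording
#' which ESTs carry a real sex effect, of what size and in which species.
#'
#' The generative model, on the log2 scale, for probe `p` of EST `i` in
#' sample `s`:
#' `signal = baseline_i + effect_i * [s male] + affinity_p + eps`,
#' `eps ~ N(0, noise_sd)`; intensities are `2^signal`. Baselines and probe
#' affinities are properties of the array and are shared between species.
#' Sex effects act at the EST (transcript) level, as expected for a dosage
#' mechanism. Probes in the CGH mask keep their intensities in species A
#' but in species B are replaced by a depressed, noisier background draw,
#' emulating failed cross-species hybridization -- the mask filter, not the
#' generator, is responsible for removing them.
#'
#' @param config a [sim_config()].
#' @return list with elements `design` (`array_design`), `sheet`
#'   (sample sheet for both species), `probes` (named list of two probe
#'   matrices), `cgh_mask` (character vector of masked probe ids), and
#'   `truth` (data frame: `est_id`, `gene_id`, `chromosome`, `direction`,
#'   `effect_log2`, `compensated`, `in_speciesA`, `in_speciesB`).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, .simulate_impl(config))
}

.simulate_impl <- function(cfg) {
  n <- cfg$n_ests
  wid <- max(5L, nchar(n))
  est_id <- sprintf("EST%0*d", wid, seq_len(n))

  # probe counts: most ESTs 11 probes, a small fraction 8-10
  n_probes <- rep(11L, n)
  n_short <- rbinom(1, n, cfg$short_frac)
  if (n_short > 0) {
    short <- sample.int(n, n_short)
    n_probes[short] <- sample(8:10, n_short, replace = TRUE)
  }
  probe_ids <- lapply(seq_len(n), function(i)
    sprintf("%s_p%02d", est_id[i], seq_len(n_probes[i])))

  # chromosome classes drawn per EST
  u <- runif(n)
  chrom <- ifelse(u < cfg$frac_z, "Z",
                  ifelse(u < cfg$frac_z + cfg$frac_unannotated, "none",
                         as.character(sample(1:28, n, replace = TRUE))))
  annotated <- chrom != "none"
  evalue <- rep(NA_real_, n)
  evalue[annotated] <- 10^-runif(sum(annotated), 21, 60)

  # gene ids: annotated ESTs mostly singletons, a fraction paired into
  # two-EST genes; pair members inherit the first member's chromosome
  gene_id <- rep(NA_character_, n)
  ann_idx <- which(annotated)
  gene_id[ann_idx] <- sprintf("G%0*d", wid, seq_along(ann_idx))
  n_pairs <- floor(length(ann_idx) * cfg$redundancy_rate / 2)
  if (n_pairs > 0) {
    paired <- sample(ann_idx, 2 * n_pairs)
    first <- paired[seq_len(n_pairs)]
    second <- paired[n_pairs + seq_len(n_pairs)]
    gene_id[second] <- gene_id[first]
    chrom[second] <- chrom[first]
    evalue[second] <- 10^-runif(n_pairs, 21, 60)
  }

  # true sex effects, assigned per gene so redundant ESTs agree
  effect <- rep(0, n)
  gkey <- ifelse(is.na(gene_id), est_id, gene_id)
  z_genes <- unique(gkey[chrom == "Z"])
  n_unc <- round(length(z_genes) * cfg$frac_z_uncompensated)
  unc_genes <- if (n_unc > 0) sample(z_genes, n_unc) else character()
  effect[gkey %in% unc_genes] <- cfg$dosage_log2fc
  auto_idx <- which(!chrom %in% c("Z", "none"))
  auto_genes <- unique(gkey[auto_idx])
  n_ab <- rbinom(1, length(auto_genes), cfg$frac_autosomal_biased)
  if (n_ab > 0) {
    ab_genes <- sample(auto_genes, n_ab)
    sgn <- sample(c(-1, 1), n_ab, replace = TRUE)
    for (k in seq_len(n_ab))
      effect[gkey %in% ab_genes[k]] <- sgn[k] * cfg$autosomal_effect_log2
  }

  # species sharing of effects (per gene)
  biased_genes <- unique(gkey[effect != 0])
  in_a <- in_b <- rep(TRUE, n)
  if (length(biased_genes)) {
    shared <- runif(length(biased_genes)) < cfg$frac_effect_shared
    only_a <- !shared & (runif(length(biased_genes)) < 0.5)
    only_b <- !shared & !only_a
    in_a[gkey %in% biased_genes[only_b]] <- FALSE
    in_b[gkey %in% biased_genes[only_a]] <- FALSE
  }
  in_a_eff <- effect * in_a
  in_b_eff <- effect * in_b

  design <- array_design(est_id, probe_ids, gene_id, chrom, evalue)

  # array-level probe properties, shared between species
  baseline <- rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
  all_probes <- design$probes$probe_id
  probe_est <- match(design$probes$est_id, est_id)
  affinity <- rnorm(length(all_probes), 0, cfg$probe_affinity_sd)

  # sample sheet: species B samples carry balanced population labels for
  # the population-vs-sex cross-check
  ns <- cfg$n_per_sex
  mk_sheet <- function(sp, with_pop) {
    ids <- sprintf("%s_%s%d", sp, rep(c("m", "f"), each = ns),
                   rep(seq_len(ns), 2))
    pop <- NA_character_
    if (with_pop)
      pop <- rep(rep_len(c("pop1", "pop2"), ns), 2)
    data.frame(sample_id = ids, species = sp,
               sex = rep(c("male", "female"), each = ns),
               population = pop, stringsAsFactors = FALSE)
  }
  sheet <- rbind(mk_sheet(cfg$species[1], FALSE), mk_sheet(cfg$species[2], TRUE))

  # CGH mask over all probes
  n_mask <- rbinom(1, length(all_probes), cfg$cgh_dropout_frac)
  cgh_mask <- if (n_mask > 0) sort(sample(all_probes, n_mask)) else character()

  draw_species <- function(sp, eff, masked) {
    ss <- sheet[sheet$species == sp, , drop = FALSE]
    is_male <- as.numeric(ss$sex == "male")
    mu <- outer(baseline[probe_est], rep(1, nrow(ss))) +
      outer(eff[probe_est], is_male) +
      affinity
    if (length(masked)) {
      mi <- match(masked, all_probes)
      # failed hybridization: depressed background, no sex signal
      mu[mi, ] <- baseline[probe_est[mi]] - cfg$mask_depression
      mu[mi, ] <- mu[mi, ] +
        matrix(rnorm(length(mi) * nrow(ss), 0, cfg$mask_noise_sd),
               length(mi))
    }
    sig <- mu + matrix(rnorm(length(mu), 0, cfg$noise_sd), nrow(mu))
    m <- 2^sig
    dimnames(m) <- list(all_probes, ss$sample_id)
    m
  }
  probes <- list(draw_species(cfg$species[1], in_a_eff, character()),
                 draw_species(cfg$species[2], in_b_eff, cgh_mask))
  names(probes) <- cfg$species

  truth <- data.frame(
    est_id = est_id, gene_id = gene_id, chromosome = chrom,
    direction = ifelse(effect > 0, "male", ifelse(effect < 0, "female", "none")),
    effect_log2 = effect,
    compensated = ifelse(chrom == "Z", !(gkey %in% unc_genes), NA),
    in_speciesA = in_a, in_speciesB = in_b,
    stringsAsFactors = FALSE
  )

  list(design = design, sheet = sheet, probes = probes,
       cgh_mask = cgh_mask, truth = truth)
}

#' Read / write a simulation truth table
#'
#' TSV round-trip of the ground-truth table produced by
#' [simulate_experiment()].
#'
#' @param truth truth data frame.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  out$effect_log2 <- sprintf("%.10g", out$effect_log2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = "")
  df$effect_log2 <- as.numeric(df$effect_log2)
  for (cc in c("compensated", "in_speciesA", "in_speciesB"))
    if (cc %in% names(df)) df[[cc]] <- as.logical(df[[cc]])
  df
}
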