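# Simulation configuration for synthetic labeling experiments.

# Standard amino-acid alphabet; sequences are drawn from the 19 letters
# excluding Q so that an unplanted sequence can never contain a valid
# KFERQ-like window (a valid window must begin or end with Q).
.AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AA_BACKGROUND <- setdiff(.AA_STANDARD, "Q")
# Residues in no KFERQ composition class and not Q: safe filler/flank letters.
.AA_NEUTRAL <- c("A", "C", "G", "H", "M", "N", "P", "S", "T", "W", "Y")

#' Configuration for a synthetic labeling experiment
#'
#' Bundles every parameter of the synthetic-data generator: the protein-class
#' structure, the base half-life distribution, genotype-by-class effects on
#' half-life and abundance, the labeling design (replicates and time points),
#' and the measurement-noise model.
#'
#' The default design mirrors a fly-head dynamic-labeling study: three
#' biological replicates sampled after 120 h and 264 h of labeling, protein
#' half-lives log-normal with median 48 h spanning hours to weeks, and a
#' fixed asymptotic label fraction (`plateau`) absorbing precursor-pool
#' effects.
#'
#' @param n_proteins_per_class Integer count of proteins per class; either a
#'   single count applied to every class or a named vector over
#'   `class_labels`.
#' @param class_labels Character vector of protein-class tags
#'   (e.g. `"mito"`, `"ribosome"`, `"er_perox"`, `"ev"`, `"other"`).
#' @param genotype_effects Named list, one element per genotype, each a named
#'   numeric vector mapping class label to a multiplicative half-life factor
#'   (unlisted classes default to 1). The genotypes of the simulation are the
#'   names of this list.
#' @param abundance_effects Named list mirroring `genotype_effects` but
#'   holding additive log2 abundance shifts (unlisted classes default to 0).
#' @param halflife_log_mean,halflife_log_sd Parameters (log-hours) of the
#'   log-normal base half-life distribution.
#' @param halflife_min_h Floor (hours) applied to the base half-life draws.
#'   Proteins turning over much faster than the first labeling time point
#'   are fully labeled at every sampled time and carry no kinetic
#'   information, so they are not simulated (default 8 h against the
#'   120 h / 264 h design).
#' @param n_replicates Number of biological replicates per genotype.
#' @param label_times_h Labeling durations in hours, strictly increasing.
#' @param noise_sd_fraction SD of additive Gaussian noise on the label
#'   fraction (values are then clamped to \[0, 1\]).
#' @param abundance_noise_sd_log2 Replicate SD of log2 intensity.
#' @param plateau Asymptotic label fraction, in (0, 1].
#' @param peptides_per_protein Number of pseudo-peptides fanned out per
#'   protein measurement (1 gives one protein-level row).
#' @param shared_peptide_fraction Fraction of proteins whose first peptide is
#'   also attributed to a second protein, to exercise shared-peptide
#'   filtering.
#' @param seed Integer seed; mandatory for reproducibility.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_proteins_per_class = 10, seed = 1)
#' cfg$label_times_h
#' @export
sim_config <- function(n_proteins_per_class = 50,
                       class_labels = c("mito", "ribosome", "er_perox",
                                        "ev", "other"),
                       genotype_effects = list(control = numeric(0),
                                               mutant = numeric(0)),
                       abundance_effects = list(),
                       halflife_log_mean = log(48),
                       halflife_log_sd = 1,
                       halflife_min_h = 8,
                       n_replicates = 3,
                       label_times_h = c(120, 264),
                       noise_sd_fraction = 0.05,
                       abundance_noise_sd_log2 = 0.25,
                       plateau = 1,
                       peptides_per_protein = 1,
                       shared_peptide_fraction = 0,
                       seed = 1L) {
  if (length(class_labels) < 1L || anyDuplicated(class_labels))
    stop("invalid 'class_labels': must be a non-empty set of unique labels")
  if (length(n_proteins_per_class) == 1L && is.null(names(n_proteins_per_class)))
    n_proteins_per_class <- stats::setNames(
      rep(as.integer(n_proteins_per_class), length(class_labels)), class_labels)
  if (!all(class_labels %in% names(n_proteins_per_class)))
    stop("invalid 'n_proteins_per_class': missing counts for class(es) ",
         paste(setdiff(class_labels, names(n_proteins_per_class)), collapse = ", "))
  n_proteins_per_class <- as.integer(n_proteins_per_class[class_labels])
  names(n_proteins_per_class) <- class_labels
  if (any(is.na(n_proteins_per_class)) || any(n_proteins_per_class < 1L))
    stop("invalid 'n_proteins_per_class': all counts must be >= 1")
  if (!is.list(genotype_effects) || is.null(names(genotype_effects)) ||
      any(!nzchar(names(genotype_effects))))
    stop("invalid 'genotype_effects': must be a named list (one per genotype)")
  for (g in names(genotype_effects)) {
    fx <- genotype_effects[[g]]
    if (length(fx) && (is.null(names(fx)) || any(fx <= 0)))
      stop("invalid 'genotype_effects' for genotype '", g,
           "': factors must be named by class and > 0")
    if (length(fx) && !all(names(fx) %in% class_labels))
      stop("invalid 'genotype_effects' for genotype '", g,
           "': unknown class(es) ",
           paste(setdiff(names(fx), class_labels), collapse = ", "))
  }
  for (g in names(abundance_effects)) {
    fx <- abundance_effects[[g]]
    if (length(fx) && (is.null(names(fx)) || !all(names(fx) %in% class_labels)))
      stop("invalid 'abundance_effects' for genotype '", g,
           "': shifts must be named by known class labels")
    if (!g %in% names(genotype_effects))
      stop("invalid 'abundance_effects': genotype '", g,
           "' absent from 'genotype_effects'")
  }
  if (!is.numeric(halflife_log_sd) || halflife_log_sd < 0)
    stop("invalid 'halflife_log_sd': must be >= 0")
  if (!is.numeric(halflife_min_h) || halflife_min_h <= 0)
    stop("invalid 'halflife_min_h': must be > 0")
  if (!is.numeric(n_replicates) || n_replicates < 1L)
    stop("invalid 'n_replicates': must be >= 1")
  if (length(label_times_h) < 1L || any(label_times_h <= 0) ||
      is.unsorted(label_times_h, strictly = TRUE))
    stop("invalid 'label_times_h': must be strictly positive and strictly increasing")
  if (noise_sd_fraction < 0)
    stop("invalid 'noise_sd_fraction': must be >= 0")
  if (abundance_noise_sd_log2 < 0)
    stop("invalid 'abundance_noise_sd_log2': must be >= 0")
  if (!is.numeric(plateau) || plateau <= 0 || plateau > 1)
    stop("invalid 'plateau': must be in (0, 1]")
  if (!is.numeric(peptides_per_protein) || peptides_per_protein < 1L)
    stop("invalid 'peptides_per_protein': must be >= 1")
  if (shared_peptide_fraction < 0 || shared_peptide_fraction > 1)
    stop("invalid 'shared_peptide_fraction': must be in [0, 1]")
  if (is.null(seed) || is.na(seed))
    stop("invalid 'seed': an integer seed is mandatory")
  structure(list(
    n_proteins_per_class = n_proteins_per_class,
    class_labels = class_labels,
    genotype_effects = genotype_effects,
    abundance_effects = abundance_effects,
    halflife_log_mean = halflife_log_mean,
    halflife_log_sd = halflife_log_sd,
    halflife_min_h = halflife_min_h,
    n_replicates = as.integer(n_replicates),
    label_times_h = as.numeric(label_times_h),
    noise_sd_fraction = noise_sd_fraction,
    abundance_noise_sd_log2 = abundance_noise_sd_log2,
    plateau = plateau,
    peptides_per_protein = as.integer(peptides_per_protein),
    shared_peptide_fraction = shared_peptide_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic labeling experiment configuration\n")
  cat("  proteins: ", sum(x$n_proteins_per_class), " (",
      paste(sprintf("%s=%d", names(x$n_proteins_per_class),
                    x$n_proteins_per_class), collapse = ", "), ")\n", sep = "")
  cat("  genotypes:", paste(names(x$genotype_effects), collapse = ", "), "\n")
  cat("  design: ", x$n_replicates, " replicates x t = {",
      paste(x$label_times_h, collapse = ", "), "} h\n", sep = "")
  cat("  half-life: log-normal(meanlog = ", signif(x$halflife_log_mean, 4),
      ", sdlog = ", signif(x$halflife_log_sd, 4), "), plateau = ",
      x$plateau, "\n", sep = "")
  cat("  noise: fraction sd = ", x$noise_sd_fraction,
      ", abundance log2 sd = ", x$abundance_noise_sd_log2, "\n", sep = "")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# look up per-class effect values with a default for unlisted classes
.effect_lookup <- function(fx, classes, default) {
  out <- rep(default, length(classes))
  if (length(fx)) {
    hit <- match(classes, names(fx))
    out[!is.na(hit)] <- fx[hit[!is.na(hit)]]
  }
  out
}
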