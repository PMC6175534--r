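# Ground-truthed synthetic data: proteome, labeling measurements, abundance.

#' Simulate a ground-truthed proteome
#'
#' Draws a protein set according to a [sim_config()]: per-class protein ids,
#' base half-lives from the configured log-normal, per-genotype true
#' half-lives (base times the genotype-by-class factor), per-genotype true
#' log2 abundances (a protein baseline plus the configured class shift), and
#' random amino-acid sequences. Sequences are drawn from the 19 standard
#' residues excluding glutamine, so a freshly simulated proteome contains no
#' KFERQ-like motif until [plant_motifs()] inserts one.
#'
#' @param config A [sim_config()].
#' @return An object of class `ground_truth`: a list with elements
#'   `proteins` (id, class), `half_life` (long table protein x genotype with
#'   true `t_half_h`), `abundance` (long table with true `log2_abundance`),
#'   `sequences` (named character), `motif_positions` (named list of 0-based
#'   planted starts, initially empty), and the `config`.
#' @examples
#' truth <- simulate_proteome(sim_config(n_proteins_per_class = 5, seed = 7))
#' head(truth$half_life)
#' @export
simulate_proteome <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be a sim_config object")
  set.seed(config$seed)
  classes <- rep(config$class_labels, times = config$n_proteins_per_class)
  n <- length(classes)
  protein_id <- sprintf("P%05d", seq_len(n))
  base_t_half <- pmax(stats::rlnorm(n, config$halflife_log_mean,
                                    config$halflife_log_sd),
                      config$halflife_min_h)
  base_log2_ab <- stats::rnorm(n, mean = 20, sd = 2)
  genotypes <- names(config$genotype_effects)

  half_life <- do.call(rbind, lapply(genotypes, function(g) {
    fac <- .effect_lookup(config$genotype_effects[[g]], classes, 1)
    data.frame(protein_id = protein_id, class_label = classes, genotype = g,
               t_half_h = base_t_half * fac, stringsAsFactors = FALSE)
  }))
  abundance <- do.call(rbind, lapply(genotypes, function(g) {
    shift <- .effect_lookup(config$abundance_effects[[g]], classes, 0)
    data.frame(protein_id = protein_id, class_label = classes, genotype = g,
               log2_abundance = base_log2_ab + shift, stringsAsFactors = FALSE)
  }))
  rownames(half_life) <- rownames(abundance) <- NULL

  seq_len_aa <- sample(300:600, n, replace = TRUE)
  sequences <- vapply(seq_len_aa, function(L)
    paste(sample(.AA_BACKGROUND, L, replace = TRUE), collapse = ""), "")
  names(sequences) <- protein_id

  structure(list(
    proteins = data.frame(protein_id = protein_id, class_label = classes,
                          stringsAsFactors = FALSE),
    half_life = half_life,
    abundance = abundance,
    sequences = sequences,
    motif_positions = stats::setNames(vector("list", n), protein_id),
    config = config
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Synthetic ground truth:", nrow(x$proteins), "proteins,",
      length(unique(x$half_life$genotype)), "genotypes\n")
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$proteins$class_label)),
                                  table(x$proteins$class_label)), collapse = ", "), "\n")
  n_mot <- sum(lengths(x$motif_positions) > 0)
  cat("  proteins with planted KFERQ-like motifs:", n_mot, "\n")
  invisible(x)
}

#' Simulate fraction-newly-synthesized measurements
#'
#' For every protein x genotype x replicate x labeling time (x pseudo-peptide)
#' the observed label fraction is
#' `clamp(plateau * (1 - exp(-log(2) * t / t_half)) + eps, 0, 1)` with
#' `eps ~ Normal(0, noise_sd_fraction)`. Clamping events are counted in the
#' `"n_clamped"` attribute. When `peptides_per_protein > 1`, measurements fan
#' out over pseudo-peptides; `shared_peptide_fraction` additionally attributes
#' one peptide of a random subset of proteins to a second protein, recorded in
#' the `"peptide_gene_map"` attribute (a peptide -> protein table) together
#' with the `"shared_rows"` count that [filter_shared_peptides()] should
#' remove.
#'
#' @param truth A `ground_truth` from [simulate_proteome()].
#' @param config The same [sim_config()] used to build `truth`.
#' @return A data.frame of label measurements with columns `protein_id`,
#'   `isoform_group`, `peptide`, `genotype`, `replicate`, `time_h`,
#'   `fraction_new`, plus attributes `n_clamped`, `peptide_gene_map`,
#'   `shared_rows`.
#' @export
simulate_labeling <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  set.seed((config$seed %% 1000000L) * 2003L + 101L)
  hl <- truth$half_life
  reps <- paste0("rep", seq_len(config$n_replicates))
  times <- config$label_times_h
  npep <- config$peptides_per_protein

  design <- expand.grid(replicate = reps, time_h = times,
                        pep = seq_len(npep), stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(hl)), each = nrow(design))
  out <- data.frame(
    protein_id = hl$protein_id[idx],
    isoform_group = hl$protein_id[idx],
    peptide = paste0(hl$protein_id[idx], "_pep",
                     rep(design$pep, times = nrow(hl))),
    genotype = hl$genotype[idx],
    replicate = rep(design$replicate, times = nrow(hl)),
    time_h = rep(design$time_h, times = nrow(hl)),
    stringsAsFactors = FALSE
  )
  th <- hl$t_half_h[idx]
  f_true <- config$plateau * (1 - exp(-log(2) * out$time_h / th))
  f_obs <- f_true + stats::rnorm(nrow(out), 0, config$noise_sd_fraction)
  n_clamped <- sum(f_obs < 0 | f_obs > 1)
  out$fraction_new <- pmin(pmax(f_obs, 0), 1)

  # shared peptides: attribute the first peptide of selected proteins to a
  # randomly chosen partner protein as well
  ids <- truth$proteins$protein_id
  pep_map <- unique(data.frame(peptide = out$peptide,
                               protein_id = out$protein_id,
                               stringsAsFactors = FALSE))
  n_shared <- round(config$shared_peptide_fraction * length(ids))
  if (n_shared > 0 && length(ids) > 1) {
    donors <- sample(ids, n_shared)
    for (d in donors) {
      partner <- sample(setdiff(ids, d), 1L)
      pep_map <- rbind(pep_map,
                       data.frame(peptide = paste0(d, "_pep1"),
                                  protein_id = partner,
                                  stringsAsFactors = FALSE))
    }
    pep_map <- unique(pep_map)
  }
  multi <- names(which(table(pep_map$peptide) > 1L))
  shared_rows <- sum(out$peptide %in% multi)

  attr(out, "n_clamped") <- n_clamped
  attr(out, "peptide_gene_map") <- pep_map
  attr(out, "shared_rows") <- shared_rows
  out
}

#' Simulate abundance intensity measurements
#'
#' Per protein x genotype x replicate x time point, intensity is
#' `2 ^ (true_log2_abundance + Normal(0, abundance_noise_sd_log2))`; always
#' strictly positive.
#'
#' @inheritParams simulate_labeling
#' @return A data.frame with columns `protein_id`, `genotype`, `replicate`,
#'   `time_h`, `intensity`.
#' @export
simulate_abundance <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  set.seed((config$seed %% 1000000L) * 2003L + 202L)
  ab <- truth$abundance
  reps <- paste0("rep", seq_len(config$n_replicates))
  times <- config$label_times_h
  design <- expand.grid(replicate = reps, time_h = times,
                        stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(ab)), each = nrow(design))
  out <- data.frame(
    protein_id = ab$protein_id[idx],
    genotype = ab$genotype[idx],
    replicate = rep(design$replicate, times = nrow(ab)),
    time_h = rep(design$time_h, times = nrow(ab)),
    stringsAsFactors = FALSE
  )
  noise <- stats::rnorm(nrow(out), 0, config$abundance_noise_sd_log2)
  out$intensity <- 2^(ab$log2_abundance[idx] + noise)
  out
}

# draw one valid KFERQ-like window (anchor Q plus 4 residues meeting the
# composition rules); basic+hydrophobic combos restricted so counts fit in 4
.random_kferq_window <- function() {
  combo <- sample(c("11", "12", "21"), 1L)
  nb <- as.integer(substr(combo, 1, 1))
  nh <- as.integer(substr(combo, 2, 2))
  core <- c(sample(c("K", "R"), nb, replace = TRUE),
            sample(c("F", "I", "L", "V"), nh, replace = TRUE),
            sample(c("D", "E"), 1L))
  filler <- 4L - length(core)
  if (filler > 0L)
    core <- c(core, sample(.AA_NEUTRAL, filler, replace = TRUE))
  core <- sample(core)
  if (stats::runif(1) < 0.5)
    paste(c("Q", core), collapse = "")
  else
    paste(c(core, "Q"), collapse = "")
}

#' Plant KFERQ-like motifs into a synthetic proteome
#'
#' Overwrites a five-residue window of `n_with_motif` randomly chosen
#' proteins with a randomly composed valid KFERQ-like window, and neutralizes
#' the four residues beyond the anchoring glutamine (setting them to
#' non-basic/non-hydrophobic/non-acidic letters) so that the planted window
#' is the only valid window it creates. All remaining sequences contain no
#' glutamine and therefore no valid window. Planted 0-based starts are
#' recorded in `motif_positions`.
#'
#' @param truth A `ground_truth`.
#' @param n_with_motif Number of proteins to receive one motif each.
#' @param seed Integer seed for the placement randomness.
#' @return The modified `ground_truth`.
#' @export
plant_motifs <- function(truth, n_with_motif, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  ids <- truth$proteins$protein_id
  if (n_with_motif > length(ids))
    stop("n_with_motif (", n_with_motif, ") exceeds protein count (",
         length(ids), ")")
  if (n_with_motif == 0L) return(truth)
  set.seed(as.integer(seed))
  chosen <- sample(ids, n_with_motif)
  for (id in chosen) {
    s <- truth$sequences[[id]]
    L <- nchar(s)
    if (L <= 5L) stop("sequence for ", id, " too short to plant a motif")
    win <- .random_kferq_window()
    start <- sample(seq_len(L - 4L), 1L)  # 1-based window start
    substr(s, start, start + 4L) <- win
    # neutralize the 4 residues beyond the anchor Q so no second anchored
    # window becomes valid
    if (substr(win, 5, 5) == "Q") {
      flank <- if (start + 5L <= L) seq(start + 5L, min(start + 8L, L)) else integer(0)
    } else {
      flank <- if (start > 1L) seq(max(start - 4L, 1L), start - 1L) else integer(0)
    }
    for (i in flank)
      substr(s, i, i) <- sample(.AA_NEUTRAL, 1L)
    truth$sequences[[id]] <- s
    truth$motif_positions[[id]] <- c(truth$motif_positions[[id]], start - 1L)
  }
  truth
}
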