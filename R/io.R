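# Tab-separated input/output for measurement tables, group lists and truth.

#' Write a table as tab-separated text
#'
#' One-line header, no quoting, no row names — the on-disk format used for
#' all measurement, estimate and result tables.
#'
#' @param x A data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a label-measurement table
#'
#' Expects the columns written by [simulate_labeling()] (`isoform_group` and
#' `peptide` are optional and default to the protein id / blank). Validates
#' the core invariants: `fraction_new` in \[0, 1\], `time_h` > 0.
#'
#' @param path TSV file path.
#' @return A validated data.frame of label measurements.
#' @export
read_label_measurements <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "genotype", "replicate", "time_h", "fraction_new")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("label measurement file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(x$isoform_group)) x$isoform_group <- x$protein_id
  if (is.null(x$peptide)) x$peptide <- ""
  if (any(!is.finite(x$fraction_new)) ||
      any(x$fraction_new < 0 | x$fraction_new > 1))
    stop("fraction_new outside [0, 1] in ", path)
  if (any(x$time_h <= 0)) stop("non-positive time_h in ", path)
  x
}

#' Read and validate an abundance-measurement table
#'
#' @param path TSV file path with columns `protein_id`, `genotype`,
#'   `replicate`, `time_h`, `intensity`.
#' @return A validated data.frame.
#' @export
read_abundance_measurements <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "genotype", "replicate", "time_h", "intensity")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("abundance file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (any(!is.finite(x$intensity)) || any(x$intensity <= 0))
    stop("non-positive intensity in ", path)
  x
}

#' Write a synthetic ground truth to disk
#'
#' Writes `truth.tsv` (per protein x genotype: class, true half-life, true
#' log2 abundance, planted motif starts as a comma-separated list),
#' `sequences.fasta`, and `config.txt` (key: value echo of the simulation
#' configuration).
#'
#' @param truth A `ground_truth`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- merge(truth$half_life, truth$abundance,
               by = c("protein_id", "class_label", "genotype"))
  mot <- vapply(truth$motif_positions[tab$protein_id],
                function(p) paste(p, collapse = ","), "")
  tab$planted_motif_starts <- unname(mot)
  tab <- tab[order(tab$protein_id, tab$genotype), ]
  write_tsv(tab, file.path(dir, "truth.tsv"))
  aa <- Biostrings::AAStringSet(truth$sequences)
  Biostrings::writeXStringSet(aa, file.path(dir, "sequences.fasta"))
  cfg <- truth$config
  scalar <- vapply(cfg, function(v) is.atomic(v) && is.null(names(v)), TRUE)
  lines <- c(
    vapply(names(cfg)[scalar], function(k)
      paste0(k, ": ", paste(cfg[[k]], collapse = ",")), ""),
    vapply(names(cfg)[!scalar], function(k)
      paste0(k, ": ", paste(utils::capture.output(utils::str(cfg[[k]])),
                            collapse = " ")), "")
  )
  writeLines(lines, file.path(dir, "config.txt"))
  invisible(dir)
}
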