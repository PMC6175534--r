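# Abundance fold changes and significance at the second labeling time point.

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around [stats::p.adjust()] with `method = "BH"`,
#' controlling the false discovery rate across the supplied tests.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed and
#'   propagated).
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# equal-variance two-group test on log2 intensities == two-group linear
# model with a fixed genotype effect; variance floor handles noise-free data
.pooled_test <- function(x, y, var_floor = 1e-12) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  sp2 <- (sum((x - m1)^2) + sum((y - m2)^2)) / (n1 + n2 - 2)
  se2 <- sp2 * (1 / n1 + 1 / n2)
  if (!is.finite(se2) || se2 <= 0) {
    if (isTRUE(all.equal(m1, m2))) return(1)
    se2 <- var_floor * mean(c(abs(m1), abs(m2)))^2 + var_floor
  }
  tstat <- (m1 - m2) / sqrt(se2)
  2 * stats::pt(-abs(tstat), n1 + n2 - 2)
}

#' Abundance fold change and significance between genotypes
#'
#' Compares per-protein log2 intensities between a mutant and a control
#' genotype at one labeling time point (by default the latest one present,
#' where genotype differences are most marked). The per-protein p-value
#' comes from a two-group linear model on log2 intensities (a fixed genotype
#' effect, equivalent to the pooled-variance t test); q-values are
#' Benjamini-Hochberg adjusted across all testable proteins and drive the
#' three-way call at the given FDR.
#'
#' Proteins with a single replicate in either genotype get their fold change
#' reported but no p/q (untestable); their call is `NA`.
#'
#' @param measurements Abundance data.frame (`protein_id`, `genotype`,
#'   `replicate`, `time_h`, `intensity`).
#' @param mutant,control Genotype labels.
#' @param time_h Time point to compare at; default `NULL` uses the maximum
#'   time present (the second/last labeling time).
#' @param fdr False discovery rate for the increased/decreased calls
#'   (default 0.05).
#' @return Data.frame of class `abundance_result`: `protein_id`,
#'   `n_mutant`, `n_control`, `log2_fc`, `fc`, `p`, `q`, `call`.
#' @export
abundance_test <- function(measurements, mutant, control, time_h = NULL,
                           fdr = 0.05) {
  need <- c("protein_id", "genotype", "replicate", "time_h", "intensity")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("measurements lack column(s): ", paste(miss, collapse = ", "))
  if (any(measurements$intensity <= 0)) stop("intensities must be positive")
  if (is.null(time_h)) time_h <- max(measurements$time_h)
  d <- measurements[measurements$time_h == time_h &
                      measurements$genotype %in% c(mutant, control), ]
  if (!nrow(d)) stop("no measurements at time_h = ", time_h,
                     " for the requested genotypes")
  d$log2_int <- log2(d$intensity)
  ids <- sort(unique(d$protein_id))
  xs <- split(d$log2_int[d$genotype == mutant],
              d$protein_id[d$genotype == mutant])
  ys <- split(d$log2_int[d$genotype == control],
              d$protein_id[d$genotype == control])
  res <- lapply(ids, function(id) {
    x <- xs[[id]]; y <- ys[[id]]
    n1 <- length(x); n2 <- length(y)
    if (n1 == 0 || n2 == 0)
      return(NULL)
    lfc <- mean(x) - mean(y)
    p <- if (n1 >= 2 && n2 >= 2) .pooled_test(x, y) else NA_real_
    data.frame(protein_id = id, n_mutant = n1, n_control = n2,
               log2_fc = lfc, fc = 2^lfc, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$q <- bh_adjust(out$p)
  out$call <- ifelse(is.na(out$q), NA_character_,
                     ifelse(out$q < fdr & out$fc > 1, "increased",
                            ifelse(out$q < fdr & out$fc < 1, "decreased",
                                   "unchanged")))
  attr(out, "time_h") <- time_h
  attr(out, "fdr") <- fdr
  class(out) <- c("abundance_result", "data.frame")
  out
}
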