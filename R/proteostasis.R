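# Core inference: joined fold-change records, quadrant classification,
# group mean fold-change tests (nested ANOVA), prevalence enrichment
# (Fisher exact / chi-squared), cross-genotype correlations.

#' Join turnover and abundance fold changes per protein
#'
#' Inner join on `protein_id` of a turnover fold-change table (from
#' [turnover_fold_change()], optionally augmented with
#' [per_protein_turnover_test()] results) and an abundance result table
#' (from [abundance_test()]). Only proteins present in both are retained.
#'
#' @param turnover Data.frame with `protein_id`, `fc` (half-life fold
#'   change), optionally `p` and `direction`.
#' @param abundance Data.frame with `protein_id`, `fc`, optionally `call`.
#' @return Data.frame of class `fc_table`: `protein_id`, `fc_halflife`,
#'   `turnover_p`, `turnover_direction`, `fc_abundance`, `abundance_call`.
#'   Join counts are in attributes `n_turnover`, `n_abundance`, `n_joined`.
#' @export
build_fc_table <- function(turnover, abundance) {
  for (nm in c("turnover", "abundance")) {
    d <- get(nm)
    if (is.null(d$protein_id) || is.null(d$fc))
      stop("'", nm, "' needs columns protein_id and fc")
    if (anyDuplicated(d$protein_id))
      stop("duplicate protein_id in '", nm, "' table")
  }
  tu <- data.frame(protein_id = turnover$protein_id,
                   fc_halflife = turnover$fc,
                   turnover_p = if (!is.null(turnover$p)) turnover$p else NA_real_,
                   turnover_direction = if (!is.null(turnover$direction))
                     turnover$direction else NA_character_,
                   stringsAsFactors = FALSE)
  ab <- data.frame(protein_id = abundance$protein_id,
                   fc_abundance = abundance$fc,
                   abundance_call = if (!is.null(abundance$call))
                     abundance$call else NA_character_,
                   stringsAsFactors = FALSE)
  out <- merge(tu, ab, by = "protein_id")
  out <- out[order(out$protein_id), ]
  rownames(out) <- NULL
  attr(out, "n_turnover") <- nrow(tu)
  attr(out, "n_abundance") <- nrow(ab)
  attr(out, "n_joined") <- nrow(out)
  class(out) <- c("fc_table", "data.frame")
  out
}

#' Classify proteins into turnover/abundance quadrants
#'
#' The turnover axis splits at a half-life fold change of 1 (`> 1` =
#' slower); the abundance axis splits at a fold change of 1 in
#' `"fc_threshold"` mode, or uses the significance call (`increased` vs
#' everything else) in `"significance"` mode. A fold change of exactly 1 is
#' assigned to the non-slower / non-increased side (the tie rule; measure
#' zero under noise).
#'
#' @param fc_halflife,fc_abundance Numeric fold-change vectors.
#' @param abundance_call Character vector of calls, required for
#'   `"significance"` mode.
#' @param mode `"fc_threshold"` or `"significance"`.
#' @return Character vector of quadrant labels, e.g. `"slower/increased"`.
#' @export
quadrant_classify <- function(fc_halflife, fc_abundance,
                              abundance_call = NULL,
                              mode = c("fc_threshold", "significance")) {
  mode <- match.arg(mode)
  slower <- fc_halflife > 1
  increased <- if (mode == "fc_threshold") fc_abundance > 1
               else !is.na(abundance_call) & abundance_call == "increased"
  paste0(ifelse(slower, "slower", "faster"), "/",
         ifelse(increased, "increased", "decreased"))
}

#' Quadrant counts and percentages for a protein group
#'
#' Tabulates the four quadrants over the group members present in a joined
#' fold-change table, plus the composite region "slower turnover and
#' increased-or-unchanged abundance" in both operational readings: by fold
#' change (`fc_abundance >= 1` counts as increased-or-unchanged... strictly,
#' not decreased means `fc_abundance > 1` or the tie) and by significance
#' (abundance call not `"decreased"`).
#'
#' @param records An `fc_table`.
#' @param members Optional character vector restricting to a group (default:
#'   all records).
#' @param mode Quadrant mode passed to [quadrant_classify()].
#' @param group Group name carried into the summary.
#' @return Object of class `quadrant_summary`: list with `group`, `n`,
#'   `counts`, `percentages` (both named by quadrant),
#'   `pct_slower_incr_or_unch_fc` and `pct_slower_incr_or_unch_sig`.
#' @export
quadrant_percentages <- function(records, members = NULL,
                                 mode = c("fc_threshold", "significance"),
                                 group = "all") {
  mode <- match.arg(mode)
  d <- as.data.frame(records)
  if (!is.null(members)) {
    members <- .normalize_ids(members)
    d <- d[.normalize_ids(d$protein_id) %in% members, ]
  }
  quads <- c("slower/increased", "slower/decreased",
             "faster/increased", "faster/decreased")
  if (!nrow(d)) {
    counts <- stats::setNames(integer(4), quads)
    return(structure(list(group = group, n = 0L, counts = counts,
                          percentages = counts * NA_real_,
                          pct_slower_incr_or_unch_fc = NA_real_,
                          pct_slower_incr_or_unch_sig = NA_real_),
                     class = "quadrant_summary"))
  }
  q <- quadrant_classify(d$fc_halflife, d$fc_abundance, d$abundance_call, mode)
  counts <- table(factor(q, levels = quads))
  n <- nrow(d)
  slower <- d$fc_halflife > 1
  comp_fc <- mean(slower & d$fc_abundance >= 1) * 100
  comp_sig <- if (all(is.na(d$abundance_call))) NA_real_
              else mean(slower & !is.na(d$abundance_call) &
                          d$abundance_call != "decreased") * 100
  structure(list(group = group, n = n,
                 counts = stats::setNames(as.integer(counts), quads),
                 percentages = stats::setNames(100 * as.integer(counts) / n, quads),
                 pct_slower_incr_or_unch_fc = comp_fc,
                 pct_slower_incr_or_unch_sig = comp_sig),
            class = "quadrant_summary")
}

#' @export
print.quadrant_summary <- function(x, ...) {
  cat("Quadrant summary for group '", x$group, "' (n = ", x$n, ")\n", sep = "")
  for (q in names(x$counts))
    cat(sprintf("  %-18s %4d  (%5.1f%%)\n", q, x$counts[[q]],
                x$percentages[[q]]))
  cat(sprintf("  slower & increased-or-unchanged: %.1f%% (fc), %s (significance)\n",
              x$pct_slower_incr_or_unch_fc,
              if (is.na(x$pct_slower_incr_or_unch_sig)) "NA"
              else sprintf("%.1f%%", x$pct_slower_incr_or_unch_sig)))
  invisible(x)
}

#' Nested-ANOVA test of a group's mean turnover fold change
#'
#' Two-level nested analysis of variance on per-replicate half-lives:
#' genotype is the fixed effect, protein is nested within genotype, and the
#' genotype mean square is tested against the protein-within-genotype mean
#' square (replicate variation forms the residual stratum and does not enter
#' the test). Sums of squares are computed directly:
#' `SS_genotype = sum_j N_j (M_j - M)^2` over genotype means,
#' `SS_protein(genotype) = sum_i n_i (m_i - M_j(i))^2` over protein cells.
#' The group mean fold change is the arithmetic mean over proteins of
#' (mutant mean half-life / control mean half-life), reported with its SD.
#'
#' @param rep_halflives Long data.frame (`protein_id`, `genotype`,
#'   `t_half`), one row per replicate, e.g. from [replicate_halflives()];
#'   non-finite half-lives are dropped.
#' @param mutant,control Genotype labels.
#' @param members Optional group membership to filter `protein_id` on.
#' @param group Group name carried into the result.
#' @return Object of class `group_mean_fc_test`: `group`, `n` (proteins with
#'   both genotypes), `mean_fc`, `sd_fc`, `F`, `df1`, `df2`, `p`, `ss`
#'   (named sums of squares), `flag`.
#' @export
group_mean_fc_test <- function(rep_halflives, mutant, control,
                               members = NULL, group = "all") {
  d <- as.data.frame(rep_halflives)
  if (!is.null(members))
    d <- d[.normalize_ids(d$protein_id) %in% .normalize_ids(members), ]
  d <- d[d$genotype %in% c(mutant, control) & is.finite(d$t_half), ]
  if (!nrow(d)) stop("no finite replicate half-lives for this comparison")
  cell <- paste(d$genotype, d$protein_id, sep = "|")
  cell_n <- tapply(d$t_half, cell, length)
  cell_mean <- tapply(d$t_half, cell, mean)
  cell_gen <- vapply(strsplit(names(cell_n), "|", fixed = TRUE), `[[`, "", 1L)
  gen_n <- tapply(d$t_half, d$genotype, length)
  gen_mean <- tapply(d$t_half, d$genotype, mean)
  grand <- mean(d$t_half)
  ss_gen <- sum(gen_n * (gen_mean - grand)^2)
  ss_prot <- sum(cell_n * (cell_mean - gen_mean[cell_gen])^2)
  ss_res <- sum((d$t_half - cell_mean[cell])^2)
  df1 <- length(gen_n) - 1L
  df2 <- length(cell_n) - length(gen_n)
  if (df1 < 1L || df2 < 1L)
    stop("nested ANOVA needs >= 2 genotypes and >= 2 proteins per genotype")
  ms_gen <- ss_gen / df1
  ms_prot <- ss_prot / df2
  if (ms_prot <= 0) {
    p <- 1; Fstat <- NA_real_; flag <- "degenerate_variance"
  } else {
    Fstat <- ms_gen / ms_prot
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    flag <- "ok"
  }
  # per-protein fold changes over proteins present in both genotypes
  pm <- tapply(d$t_half[d$genotype == mutant],
               d$protein_id[d$genotype == mutant], mean)
  pc <- tapply(d$t_half[d$genotype == control],
               d$protein_id[d$genotype == control], mean)
  common <- intersect(names(pm), names(pc))
  fcs <- pm[common] / pc[common]
  structure(list(group = group, n = length(common),
                 mean_fc = mean(fcs), sd_fc = stats::sd(fcs),
                 F = Fstat, df1 = df1, df2 = df2, p = p,
                 ss = c(genotype = ss_gen, protein_within_genotype = ss_prot,
                        residual = ss_res),
                 flag = flag),
            class = "group_mean_fc_test")
}

#' @export
print.group_mean_fc_test <- function(x, ...) {
  cat("Nested ANOVA, group '", x$group, "': mean FC = ",
      sprintf("%.3f +/- %.3f", x$mean_fc, x$sd_fc),
      " (n = ", x$n, " proteins)\n", sep = "")
  cat(sprintf("  F(%d, %d) = %.3f, p = %.3g%s\n", x$df1, x$df2,
              ifelse(is.na(x$F), NaN, x$F), x$p,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Prevalence enrichment of an outcome in a protein group
#'
#' Builds the 2x2 table (group membership x outcome) and tests whether the
#' outcome prevalence differs between the group and the rest of the dataset.
#' The Fisher exact test (two-sided) is used when any expected cell count is
#' below `expected_min` or the total is at most `fisher_max_n`; otherwise a
#' chi-squared test of homogeneity (without continuity correction). A zero
#' row or column margin makes the comparison vacuous: p = 1, flagged. The
#' odds ratio is `ad/bc`, with the Haldane 0.5 correction when any cell is
#' zero.
#'
#' @param outcome_in Logical vector: outcome flag for each in-group protein.
#' @param outcome_out Logical vector: outcome flag for each out-group
#'   protein.
#' @param group,outcome Labels carried into the result.
#' @param expected_min Expected-count threshold for the exact test
#'   (default 5).
#' @param fisher_max_n Total-size threshold below which the exact test is
#'   always used (default 1000).
#' @return Object of class `enrichment_result`: `group`, `outcome`, `table`
#'   (2x2 counts), `odds_ratio`, `p`, `test_used`
#'   (`"fisher"`/`"chi2"`/`"none"`), `flag`.
#' @export
prevalence_enrichment <- function(outcome_in, outcome_out, group = "group",
                                  outcome = "outcome", expected_min = 5,
                                  fisher_max_n = 1000) {
  outcome_in <- as.logical(outcome_in); outcome_out <- as.logical(outcome_out)
  if (anyNA(outcome_in) || anyNA(outcome_out))
    stop("outcome flags must be TRUE/FALSE without NA")
  a <- sum(outcome_in); b <- length(outcome_in) - a
  cc <- sum(outcome_out); dd <- length(outcome_out) - cc
  tab <- matrix(c(a, b, cc, dd), nrow = 2, byrow = TRUE,
                dimnames = list(c("in_group", "out_group"),
                                c("outcome", "no_outcome")))
  n <- sum(tab)
  or <- if (any(tab == 0))
    ((a + 0.5) * (dd + 0.5)) / ((b + 0.5) * (cc + 0.5))
  else (a * dd) / (b * cc)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(structure(list(group = group, outcome = outcome, table = tab,
                          odds_ratio = or, p = 1, test_used = "none",
                          flag = "zero_margin"),
                     class = "enrichment_result"))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / n
  use_fisher <- any(expected < expected_min) || n <= fisher_max_n
  if (use_fisher) {
    p <- stats::fisher.test(tab)$p.value
    test <- "fisher"
  } else {
    p <- stats::chisq.test(tab, correct = FALSE)$p.value
    test <- "chi2"
  }
  structure(list(group = group, outcome = outcome, table = tab,
                 odds_ratio = or, p = p, test_used = test, flag = "ok"),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Enrichment of '", x$outcome, "' in group '", x$group, "' (",
      x$test_used, " test)\n", sep = "")
  print(x$table)
  cat(sprintf("  odds ratio = %.3f, p = %.4g%s\n", x$odds_ratio, x$p,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' Correlation of fold changes between two datasets
#'
#' Pearson (default) or Spearman correlation of log2 fold changes over the
#' proteins common to two fold-change tables, optionally restricted to a
#' group.
#'
#' @param fc_a,fc_b Data.frames with `protein_id` and `fc` columns.
#' @param members Optional group restriction.
#' @param method `"pearson"` or `"spearman"`.
#' @param pair Label for the dataset pair.
#' @return Object of class `correlation_result`: `pair`, `n`, `r`, `p`,
#'   `method`, `testable` (FALSE when fewer than 3 common proteins, in which
#'   case `r` and `p` are `NA`).
#' @export
cross_mutant_correlation <- function(fc_a, fc_b, members = NULL,
                                     method = c("pearson", "spearman"),
                                     pair = "A vs B") {
  method <- match.arg(method)
  a <- data.frame(protein_id = fc_a$protein_id, fc_a = fc_a$fc,
                  stringsAsFactors = FALSE)
  b <- data.frame(protein_id = fc_b$protein_id, fc_b = fc_b$fc,
                  stringsAsFactors = FALSE)
  d <- merge(a, b, by = "protein_id")
  if (!is.null(members))
    d <- d[.normalize_ids(d$protein_id) %in% .normalize_ids(members), ]
  d <- d[is.finite(d$fc_a) & is.finite(d$fc_b) & d$fc_a > 0 & d$fc_b > 0, ]
  if (nrow(d) < 3)
    return(structure(list(pair = pair, n = nrow(d), r = NA_real_,
                          p = NA_real_, method = method, testable = FALSE),
                     class = "correlation_result"))
  ct <- stats::cor.test(log2(d$fc_a), log2(d$fc_b), method = method,
                        exact = FALSE)
  structure(list(pair = pair, n = nrow(d), r = unname(ct$estimate),
                 p = ct$p.value, method = method, testable = TRUE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (!x$testable)
    cat("Correlation ", x$pair, ": untestable (n = ", x$n, ")\n", sep = "")
  else
    cat(sprintf("Correlation %s: r = %.3f (n = %d, %s), p = %.3g\n",
                x$pair, x$r, x$n, x$method, x$p))
  invisible(x)
}

#' Scatter plot of turnover vs abundance fold changes
#'
#' Log2-log2 scatter with the "slower turnover, increased abundance"
#' quadrant axes drawn and optional group highlighting.
#'
#' @param x An `fc_table`.
#' @param members Optional character vector of protein ids to highlight.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fc_table <- function(x, members = NULL, ...) {
  lx <- log2(x$fc_halflife); ly <- log2(x$fc_abundance)
  graphics::plot(lx, ly, pch = 16, col = "grey60", cex = 0.6,
                 xlab = "log2 FC half-life", ylab = "log2 FC abundance", ...)
  graphics::abline(h = 0, v = 0, lty = 2)
  if (!is.null(members)) {
    sel <- .normalize_ids(x$protein_id) %in% .normalize_ids(members)
    graphics::points(lx[sel], ly[sel], pch = 16, col = "firebrick", cex = 0.7)
  }
  invisible(x)
}
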