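# First-order turnover kinetics: half-life estimation, QC, fold changes.
#
# Model: fraction_new(t) = plateau * (1 - exp(-k * t)), a single-pool
# first-order labeling curve with a fixed asymptote. The degradation rate k
# is fit by least squares over all pooled measurements of a protein within a
# genotype; t_half = ln(2) / k.

# default cap for degenerate fits: half-life floor of 0.1 h
.K_MAX_DEFAULT <- log(2) / 0.1

# One-dimensional least-squares fit of k. The SSR is nearly flat over most
# of (0, k_max] once kt saturates, so a plain golden-section search on the
# full interval can miss the narrow basin; instead the basin is located on a
# log-spaced rate grid, refined with optimize() between the neighbouring
# grid points, and polished with safeguarded Newton steps on the gradient
# (machine precision on noise-free data).
.fit_k <- function(t, f, plateau, k_max = .K_MAX_DEFAULT) {
  if (all(f <= 0)) return(list(k = 0, flag = "all_zero"))
  if (all(f >= plateau)) return(list(k = k_max, flag = "saturated"))
  ssr <- function(k) sum((f - plateau * (1 - exp(-k * t)))^2)
  grid <- exp(seq(log(1e-8), log(k_max), length.out = 120))
  best <- which.min(vapply(grid, ssr, 0))
  lo <- grid[max(best - 1L, 1L)]
  hi <- grid[min(best + 1L, length(grid))]
  k <- stats::optimize(ssr, c(lo, hi), tol = lo * 1e-8)$minimum
  for (i in 1:40) {
    e <- exp(-k * t)
    r <- f - plateau * (1 - e)
    g <- -2 * sum(r * plateau * t * e)
    h <- 2 * sum((plateau * t * e)^2) + 2 * sum(r * plateau * t^2 * e)
    if (!is.finite(g) || !is.finite(h) || h <= 0) break
    k_new <- min(max(k - g / h, 0), k_max)
    if (abs(k_new - k) <= 1e-15 * max(k, 1e-12)) { k <- k_new; break }
    k <- k_new
  }
  flag <- if (k >= k_max * (1 - 1e-9)) "rate_capped" else "ok"
  list(k = k, flag = flag)
}

# Closed-form single-point inversion: t_half = t*ln2 / (-ln(1 - f/plateau)).
.t_half_single_point <- function(t, f, plateau, k_max = .K_MAX_DEFAULT) {
  if (f <= 0) return(Inf)
  if (f >= plateau) return(log(2) / k_max)
  t * log(2) / (-log(1 - f / plateau))
}

#' Fit per-protein, per-genotype half-lives from labeling measurements
#'
#' The central estimator: for every analysis unit (the `isoform_group` when
#' present, else `protein_id`) and genotype, the degradation rate `k` is the
#' least-squares fit of `fraction_new = plateau * (1 - exp(-k * time_h))`
#' over all pooled measurements, and `t_half = log(2) / k`. Per-replicate
#' half-lives are obtained by refitting within each replicate (replicates
#' with a single point fall back to the closed-form inversion); the
#' coefficient of variation of these replicate half-lives drives quality
#' control: `passed_qc` requires `cv < cv_threshold` and at least
#' `min_measurements` pooled measurements.
#'
#' Degenerate inputs are flagged, not thrown: all-zero fractions give
#' `k = 0` (infinite half-life), fractions at or above the plateau at every
#' time give `k` capped at `log(2)/0.1` per hour, and units with too few
#' measurements are retained with `NA` estimates and flag
#' `"too_few_measurements"`.
#'
#' @param measurements Data.frame with columns `protein_id`, `genotype`,
#'   `replicate`, `time_h`, `fraction_new` (optionally `isoform_group`,
#'   `peptide`).
#' @param plateau Fixed asymptotic label fraction in (0, 1]. This absorbs
#'   precursor-pool effects (e.g. dietary amino-acid recycling) as a single
#'   constant.
#' @param min_measurements Minimum pooled measurements per unit x genotype
#'   (default 6; use 15 for sparser multi-strain designs).
#' @param cv_threshold Replicate-CV exclusion threshold; a CV at or above it
#'   fails QC (default 0.25).
#' @param k_max Upper bound on the rate for degenerate fits.
#' @return An object of class `turnover_fit` with components `estimates`
#'   (one row per unit x genotype: `protein_id`, `genotype`, `k`, `t_half`,
#'   `n_measurements`, `cv`, `passed_qc`, `flag`), `replicate_t_half` (named
#'   list of per-replicate half-life vectors keyed `"<id>|<genotype>"`), the
#'   fitted `data`, and the call.
#' @seealso [apply_cv_filter()], [turnover_fold_change()],
#'   [per_protein_turnover_test()]
#' @examples
#' m <- data.frame(protein_id = "P1", genotype = "control",
#'                 replicate = rep(c("r1", "r2", "r3"), each = 2),
#'                 time_h = rep(c(120, 264), 3),
#'                 fraction_new = rep(c(0.5, 0.78), 3))
#' fit <- turnover_fit(m)
#' coef(fit)
#' @export
turnover_fit <- function(measurements, plateau = 1, min_measurements = 6,
                         cv_threshold = 0.25, k_max = .K_MAX_DEFAULT) {
  need <- c("protein_id", "genotype", "replicate", "time_h", "fraction_new")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("measurements lack column(s): ", paste(miss, collapse = ", "))
  if (plateau <= 0 || plateau > 1) stop("'plateau' must be in (0, 1]")
  m <- as.data.frame(measurements, stringsAsFactors = FALSE)
  m$unit <- if (!is.null(m$isoform_group)) m$isoform_group else m$protein_id

  key <- paste(m$unit, m$genotype, sep = "|")
  groups <- split(seq_len(nrow(m)), key)
  est <- vector("list", length(groups))
  rep_th <- vector("list", length(groups))
  fitted_k <- numeric(nrow(m))
  for (i in seq_along(groups)) {
    rows <- groups[[i]]
    t <- m$time_h[rows]; f <- m$fraction_new[rows]
    n <- length(rows)
    if (n < min_measurements) {
      est[[i]] <- data.frame(protein_id = m$unit[rows[1]],
                             genotype = m$genotype[rows[1]],
                             k = NA_real_, t_half = NA_real_,
                             n_measurements = n, cv = NA_real_,
                             passed_qc = FALSE, flag = "too_few_measurements",
                             stringsAsFactors = FALSE)
      rep_th[[i]] <- numeric(0)
      fitted_k[rows] <- NA_real_
      next
    }
    fit <- .fit_k(t, f, plateau, k_max)
    th <- if (fit$k > 0) log(2) / fit$k else Inf
    by_rep <- split(rows, m$replicate[rows])
    r_th <- vapply(by_rep, function(rr) {
      tt <- m$time_h[rr]; ff <- m$fraction_new[rr]
      if (length(rr) >= 2) {
        rk <- .fit_k(tt, ff, plateau, k_max)$k
        if (rk > 0) log(2) / rk else Inf
      } else {
        mean(vapply(seq_along(rr), function(j)
          .t_half_single_point(tt[j], ff[j], plateau, k_max), 0))
      }
    }, 0)
    cv <- if (all(is.finite(r_th)) && mean(r_th) > 0)
      stats::sd(r_th) / mean(r_th) else NA_real_
    # exclusion at the threshold itself (cv >= threshold fails); the tiny
    # relative guard keeps the boundary decision stable under refit rounding
    passed <- n >= min_measurements && is.finite(cv) &&
      cv < cv_threshold * (1 - 1e-9)
    est[[i]] <- data.frame(protein_id = m$unit[rows[1]],
                           genotype = m$genotype[rows[1]],
                           k = fit$k, t_half = th, n_measurements = n,
                           cv = cv, passed_qc = passed, flag = fit$flag,
                           stringsAsFactors = FALSE)
    rep_th[[i]] <- r_th
    fitted_k[rows] <- fit$k
  }
  estimates <- do.call(rbind, est)
  rownames(estimates) <- NULL
  names(rep_th) <- names(groups)
  m$fitted <- ifelse(is.na(fitted_k), NA_real_,
                     plateau * (1 - exp(-fitted_k * m$time_h)))
  structure(list(estimates = estimates, replicate_t_half = rep_th,
                 data = m, plateau = plateau,
                 min_measurements = min_measurements,
                 cv_threshold = cv_threshold, k_max = k_max,
                 call = match.call()),
            class = "turnover_fit")
}

#' @export
print.turnover_fit <- function(x, ...) {
  e <- x$estimates
  cat("First-order turnover fit (plateau =", x$plateau, ")\n")
  cat("  units x genotypes:", nrow(e), " (",
      length(unique(e$protein_id)), "units,",
      length(unique(e$genotype)), "genotypes )\n")
  cat("  passed QC (cv <", x$cv_threshold, ", n >=", x$min_measurements,
      "):", sum(e$passed_qc), "\n")
  ok <- is.finite(e$t_half)
  if (any(ok))
    cat("  median half-life:", signif(stats::median(e$t_half[ok]), 4), "h\n")
  invisible(x)
}

#' @export
summary.turnover_fit <- function(object, ...) {
  e <- object$estimates
  by_g <- split(e, e$genotype)
  tab <- do.call(rbind, lapply(names(by_g), function(g) {
    d <- by_g[[g]]
    ok <- is.finite(d$t_half)
    data.frame(genotype = g, n_units = nrow(d), n_passed_qc = sum(d$passed_qc),
               median_t_half = stats::median(d$t_half[ok & d$passed_qc]),
               median_cv = stats::median(d$cv, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  structure(list(by_genotype = tab, plateau = object$plateau,
                 cv_threshold = object$cv_threshold), class = "summary.turnover_fit")
}

#' @export
print.summary.turnover_fit <- function(x, ...) {
  cat("Turnover fit summary (plateau =", x$plateau,
      ", CV threshold =", x$cv_threshold, ")\n")
  print(x$by_genotype, row.names = FALSE)
  invisible(x)
}

#' Extract fitted half-lives as a units-by-genotype matrix
#' @param object A `turnover_fit`.
#' @param ... Unused.
#' @return Numeric matrix of `t_half` (hours), rows = analysis units,
#'   columns = genotypes; `NA` for units without an estimate.
#' @export
coef.turnover_fit <- function(object, ...) {
  e <- object$estimates
  units <- sort(unique(e$protein_id))
  gens <- sort(unique(e$genotype))
  out <- matrix(NA_real_, length(units), length(gens),
                dimnames = list(units, gens))
  out[cbind(match(e$protein_id, units), match(e$genotype, gens))] <- e$t_half
  out
}

#' @export
fitted.turnover_fit <- function(object, ...) object$data$fitted

#' @export
residuals.turnover_fit <- function(object, ...)
  object$data$fraction_new - object$data$fitted

#' Predict label fractions from a turnover fit
#' @param object A `turnover_fit`.
#' @param newdata Data.frame with `protein_id`, `genotype`, `time_h`.
#' @param ... Unused.
#' @return Numeric vector of predicted fraction-newly-synthesized values.
#' @export
predict.turnover_fit <- function(object, newdata, ...) {
  e <- object$estimates
  i <- match(paste(newdata$protein_id, newdata$genotype, sep = "|"),
             paste(e$protein_id, e$genotype, sep = "|"))
  k <- e$k[i]
  object$plateau * (1 - exp(-k * newdata$time_h))
}

#' Plot observed and fitted labeling curves for one protein
#' @param x A `turnover_fit`.
#' @param protein_id,genotype Unit to display (defaults: first fitted unit,
#'   all genotypes).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.turnover_fit <- function(x, protein_id = NULL, genotype = NULL, ...) {
  d <- x$data
  if (is.null(protein_id)) protein_id <- d$unit[1]
  d <- d[d$unit == protein_id, ]
  if (!is.null(genotype)) d <- d[d$genotype %in% genotype, ]
  if (!nrow(d)) stop("no measurements for ", protein_id)
  gens <- unique(d$genotype)
  cols <- stats::setNames(seq_along(gens) + 1L, gens)
  graphics::plot(d$time_h, d$fraction_new, col = cols[d$genotype],
                 xlab = "labeling time (h)", ylab = "fraction newly synthesized",
                 ylim = c(0, 1), main = protein_id, ...)
  tt <- seq(0, max(d$time_h) * 1.1, length.out = 100)
  for (g in gens) {
    e <- x$estimates
    k <- e$k[e$protein_id == protein_id & e$genotype == g]
    if (length(k) == 1 && is.finite(k))
      graphics::lines(tt, x$plateau * (1 - exp(-k * tt)), col = cols[g])
  }
  graphics::legend("bottomright", legend = gens, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Per-replicate half-lives in long format
#'
#' @param fit A `turnover_fit`.
#' @return Data.frame `protein_id`, `genotype`, `replicate`, `t_half`.
#' @export
replicate_halflives <- function(fit) {
  stopifnot(inherits(fit, "turnover_fit"))
  keys <- names(fit$replicate_t_half)
  out <- do.call(rbind, lapply(keys, function(kk) {
    v <- fit$replicate_t_half[[kk]]
    if (!length(v)) return(NULL)
    parts <- strsplit(kk, "|", fixed = TRUE)[[1]]
    data.frame(protein_id = parts[1], genotype = parts[2],
               replicate = names(v), t_half = unname(v),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(protein_id = character(), genotype = character(),
                      replicate = character(), t_half = numeric())
  rownames(out) <- NULL
  out
}

#' Remove measurements from peptides shared between genes
#'
#' Peptides attributable to more than one gene are ambiguous and dropped;
#' rows with a blank peptide (protein-level measurements) pass through
#' untouched.
#'
#' @param measurements Label-measurement data.frame with a `peptide` column.
#' @param peptide_gene_map Data.frame with columns `peptide` and a gene/
#'   protein id column (`protein_id` or `gene_id`), one row per attribution.
#' @return The filtered measurements; the number of removed rows is reported
#'   in a message and in the `"n_removed"` attribute.
#' @export
filter_shared_peptides <- function(measurements, peptide_gene_map) {
  pep <- measurements$peptide
  if (is.null(pep)) pep <- rep("", nrow(measurements))
  map <- as.data.frame(peptide_gene_map, stringsAsFactors = FALSE)
  gene_col <- intersect(c("protein_id", "gene_id"), names(map))[1]
  if (is.na(gene_col) || is.null(map$peptide))
    stop("peptide_gene_map needs columns 'peptide' and 'protein_id'/'gene_id'")
  nonblank <- nzchar(pep)
  unmapped <- setdiff(unique(pep[nonblank]), map$peptide)
  if (length(unmapped))
    stop("peptide(s) missing from map: ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  n_genes <- table(unique(map[c("peptide", gene_col)])$peptide)
  shared <- names(n_genes)[n_genes > 1L]
  drop <- nonblank & pep %in% shared
  out <- measurements[!drop, , drop = FALSE]
  message("filter_shared_peptides: removed ", sum(drop),
          " measurement(s) from ", length(shared), " shared peptide(s)")
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Apply the replicate-CV quality filter to a genotype comparison
#'
#' A protein is retained only when its replicate CV is below the threshold
#' (strictly: a CV exactly at the threshold is excluded) in both the mutant
#' and the control genotype, and both estimates exist.
#'
#' @param fit A `turnover_fit` covering both genotypes.
#' @param mutant,control Genotype labels.
#' @return List with `retained` (character vector of protein ids) and
#'   `ledger` (data.frame `protein_id`, `reason` for every exclusion).
#' @export
apply_cv_filter <- function(fit, mutant, control) {
  stopifnot(inherits(fit, "turnover_fit"))
  e <- fit$estimates
  ids <- unique(e$protein_id)
  em <- e[e$genotype == mutant, ]
  ec <- e[e$genotype == control, ]
  reason <- character(0); rid <- character(0)
  keep <- character(0)
  for (id in ids) {
    rm_ <- em[em$protein_id == id, ]
    rc_ <- ec[ec$protein_id == id, ]
    r <- NULL
    if (!nrow(rm_)) r <- "missing_in_mutant"
    else if (!nrow(rc_)) r <- "missing_in_control"
    else if (!rm_$passed_qc[1])
      r <- if (rm_$flag[1] == "too_few_measurements")
        "too_few_measurements_mutant" else "cv_failed_mutant"
    else if (!rc_$passed_qc[1])
      r <- if (rc_$flag[1] == "too_few_measurements")
        "too_few_measurements_control" else "cv_failed_control"
    if (is.null(r)) keep <- c(keep, id)
    else { rid <- c(rid, id); reason <- c(reason, r) }
  }
  list(retained = keep,
       ledger = data.frame(protein_id = rid, reason = reason,
                           stringsAsFactors = FALSE))
}

#' Turnover (half-life) fold changes between genotypes
#'
#' Fold change = mutant half-life / control half-life; values above 1 mean
#' slower turnover in the mutant. Only proteins passing QC in both genotypes
#' are evaluated; proteins whose control (or mutant) half-life is zero or
#' infinite are excluded with a reason.
#'
#' @param fit A `turnover_fit`.
#' @param mutant,control Genotype labels.
#' @return Data.frame `protein_id`, `t_half_mutant`, `t_half_control`, `fc`,
#'   with excluded proteins in the `"excluded"` attribute.
#' @export
turnover_fold_change <- function(fit, mutant, control) {
  stopifnot(inherits(fit, "turnover_fit"))
  cvres <- apply_cv_filter(fit, mutant, control)
  e <- fit$estimates
  em <- e[e$genotype == mutant, ]
  ec <- e[e$genotype == control, ]
  im <- match(cvres$retained, em$protein_id)
  ic <- match(cvres$retained, ec$protein_id)
  thm <- em$t_half[im]; thc <- ec$t_half[ic]
  # capped/saturated/all-zero fits sit at an arbitrary bound, not a
  # measurement; fold changes against them are undefined
  bad_c <- !is.finite(thc) | thc <= 0 | ec$flag[ic] != "ok"
  bad_m <- !is.finite(thm) | em$flag[im] != "ok"
  ok <- !bad_c & !bad_m
  mk <- function(ids, why)
    data.frame(protein_id = ids, reason = rep(why, length(ids)),
               stringsAsFactors = FALSE)
  excl <- rbind(cvres$ledger,
                mk(cvres$retained[bad_c], "control_t_half_degenerate"),
                mk(cvres$retained[bad_m & !bad_c], "mutant_t_half_degenerate"))
  out <- data.frame(protein_id = cvres$retained[ok],
                    t_half_mutant = thm[ok], t_half_control = thc[ok],
                    fc = thm[ok] / thc[ok], stringsAsFactors = FALSE)
  attr(out, "excluded") <- excl
  out
}

# Welch two-sample t test with a variance floor so that separated constant
# groups give a tiny positive p instead of an error.
.welch_test <- function(x, y, var_floor = 1e-12) {
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (!is.finite(se2) || se2 <= 0) {
    if (isTRUE(all.equal(m1, m2))) return(list(p = 1, t = 0))
    se2 <- var_floor * mean(c(abs(m1), abs(m2)))^2 + var_floor
  }
  tstat <- (m1 - m2) / sqrt(se2)
  df <- if (v1 + v2 > 0)
    se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  else n1 + n2 - 2
  if (!is.finite(df) || df <= 0) df <- n1 + n2 - 2
  list(p = 2 * stats::pt(-abs(tstat), df), t = tstat)
}

#' Per-protein turnover significance tests
#'
#' Two-sided unequal-variance (Welch) t test on per-replicate half-lives,
#' mutant vs control. Proteins with fewer than `min_reps` finite replicate
#' values in either genotype are reported as untestable rather than
#' non-significant.
#'
#' @param fit A `turnover_fit`.
#' @param mutant,control Genotype labels.
#' @param min_reps Minimum finite replicate half-lives per genotype
#'   (default 3).
#' @param var_floor Variance floor for degenerate (zero-variance) groups.
#' @return Data.frame `protein_id`, `p`, `direction`
#'   (`"slower"`/`"faster"`/`"none"`), `testable`, `n_mutant`, `n_control`.
#' @export
per_protein_turnover_test <- function(fit, mutant, control, min_reps = 3,
                                      var_floor = 1e-12) {
  stopifnot(inherits(fit, "turnover_fit"))
  ids <- unique(fit$estimates$protein_id)
  res <- lapply(ids, function(id) {
    x <- fit$replicate_t_half[[paste(id, mutant, sep = "|")]]
    y <- fit$replicate_t_half[[paste(id, control, sep = "|")]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < min_reps || length(y) < min_reps)
      return(data.frame(protein_id = id, p = NA_real_, direction = "none",
                        testable = FALSE, n_mutant = length(x),
                        n_control = length(y), stringsAsFactors = FALSE))
    w <- .welch_test(x, y, var_floor)
    dir <- if (mean(x) > mean(y)) "slower"
           else if (mean(x) < mean(y)) "faster" else "none"
    data.frame(protein_id = id, p = w$p, direction = dir, testable = TRUE,
               n_mutant = length(x), n_control = length(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
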