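# Independent reference implementations used as oracles. These deliberately
# share no code with the package: direct enumeration and textbook formulas.

# Two-sided Fisher exact p for a 2x2 table by exhaustive hypergeometric
# enumeration with binomial coefficients (sum of all tables, at fixed
# margins, whose probability does not exceed the observed one).
oracle_fisher_p <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  prob <- vapply(xs, function(x)
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1), 0)
  p_obs <- prob[match(a, xs)]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by the definition: q_(i) = min over j >= i of
# p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Brute-force KFERQ-like window check: scalar, letter-by-letter counting.
oracle_kferq_valid <- function(win, strict = FALSE) {
  ch <- strsplit(toupper(win), "")[[1]]
  if (length(ch) != 5) stop("need 5 letters")
  std <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
  if (any(!ch %in% std)) return(FALSE)
  check4 <- function(res) {
    nb <- sum(res == "K") + sum(res == "R")
    nh <- sum(res == "F") + sum(res == "I") + sum(res == "L") + sum(res == "V")
    na_ <- sum(res == "D") + sum(res == "E")
    ok <- nb >= 1 && nb <= 2 && nh >= 1 && nh <= 2 && na_ == 1
    if (strict) ok <- ok && (nb + nh + na_) == 4
    ok
  }
  (ch[5] == "Q" && check4(ch[1:4])) || (ch[1] == "Q" && check4(ch[2:5]))
}

# Nested ANOVA via R's linear-model machinery (sequential sums of squares):
# genotype then protein-within-genotype; F tests genotype MS against the
# protein-within-genotype MS.
oracle_nested_anova <- function(d) {
  d$genotype <- factor(d$genotype)
  d$protein_id <- factor(d$protein_id)
  a <- stats::anova(stats::lm(t_half ~ genotype + genotype:protein_id, data = d))
  ss <- a[["Sum Sq"]]; df <- a[["Df"]]
  Fstat <- (ss[1] / df[1]) / (ss[2] / df[2])
  list(ss_genotype = ss[1], ss_protein = ss[2], ss_residual = ss[3],
       F = Fstat, p = stats::pf(Fstat, df[1], df[2], lower.tail = FALSE))
}

# small noise-free simulation shared by several tests
noisefree_config <- function(seed = 1, n = 15) {
  sim_config(
    n_proteins_per_class = n, class_labels = c("mito", "other"),
    genotype_effects = list(control = numeric(0), mutant = c(mito = 1.45)),
    noise_sd_fraction = 0, abundance_noise_sd_log2 = 0, seed = seed)
}
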