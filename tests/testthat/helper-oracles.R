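# Independent oracles and fixture builders used across the suite.

# Exact Hardy-Weinberg p-value by direct enumeration: probability of each
# heterozygote count from the log-factorial formula
#   P(h) = n! / (nAA! h! naa!) * 2^h * nA! na! / (2n)!
# conditional on the observed allele counts, two-sided by summing all
# configurations with probability <= the observed one.
hwe_enumeration_p <- function(n_major_hom, n_het, n_minor_hom) {
  n <- n_major_hom + n_het + n_minor_hom
  n_rare <- 2L * min(n_major_hom, n_minor_hom) + n_het
  if (n_rare == 0L || n_rare == 2L * n) return(1.0)
  hs <- seq.int(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  logp <- vapply(hs, function(h) {
    rare_hom <- (n_rare - h) / 2
    common_hom <- n - h - rare_hom
    lfactorial(n) - lfactorial(common_hom) - lfactorial(h) -
      lfactorial(rare_hom) + h * log(2) +
      lfactorial(n_rare) + lfactorial(2 * n - n_rare) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_het, hs)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

# r^2 directly from phased haplotype counts (for fixtures built from known
# phase with no double heterozygotes, where phase is unambiguous)
phased_r2 <- function(hapA, hapB) {
  tab <- table(hapA, hapB)
  pA <- mean(hapA == rownames(tab)[1])
  pB <- mean(hapB == colnames(tab)[1])
  pAB <- mean(hapA == rownames(tab)[1] & hapB == colnames(tab)[1])
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# genotype_table from per-marker genotype count vectors c(AA, Aa, aa)
geno_from_counts <- function(..., alleles = c("A", "a")) {
  counts <- list(...)
  n <- sum(counts[[1]])
  subjects <- sprintf("S%02d", seq_len(n))
  markers <- names(counts)
  a1 <- matrix(NA_character_, n, length(markers),
               dimnames = list(subjects, markers))
  a2 <- a1
  for (j in seq_along(counts)) {
    ct <- counts[[j]]
    a1[, j] <- rep(c(alleles[1], alleles[1], alleles[2]), ct)
    a2[, j] <- rep(c(alleles[1], alleles[2], alleles[2]), ct)
  }
  genotype_table(subjects, markers, a1, a2)
}

# small phenotype covariate frame for GLM/mediation tests
make_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(subject = sprintf("S%03d", seq_len(n)),
             age = runif(n, 6, 17),
             gender = sample(c("M", "F"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# random named vectors sharing subjects with a covariate frame
named_over <- function(values, cov) {
  names(values) <- cov$subject
  values
}

# OLS t and p for the last column of a design matrix, computed from the
# normal equations and the t distribution from first principles
normal_equations_tp <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  tstat <- beta[ncol(X)] / se[ncol(X)]
  list(beta = beta[ncol(X)], t = tstat, df = df,
       p = 2 * pt(abs(tstat), df, lower.tail = FALSE))
}

# standard MA1-style planted triad spec
ma1_path_spec <- function(a = -0.45, b = -0.25, c_prime = 0.20,
                          hemi = "lh", region = "isthmuscingulate") {
  data.frame(marker = "rs5796555", hemi = hemi, region = region,
             feature = "volume", a = a, b = b, c_prime = c_prime,
             stringsAsFactors = FALSE)
}

# simulate a small cohort and return the assembled (x, m, y, covariates)
# series for mediation-level tests
simulate_triad_series <- function(seed, a = -0.45, b = -0.25,
                                  c_prime = 0.20, n = 58L) {
  spec <- cohort_spec(n_subjects = n, path_spec = ma1_path_spec(a, b, c_prime),
                      regions = c("isthmuscingulate", "inferiorparietal"),
                      seed = seed)
  coh <- simulate_cohort(spec)
  cc <- carrier_code(coh$genotypes, "rs5796555")
  nf <- normalize_feature(coh$morphometry, "lh", "isthmuscingulate", "volume")
  y <- coh$phenotypes$ap_score
  names(y) <- coh$phenotypes$subject
  list(x = cc$values, m = nf$values, y = y, cov = coh$phenotypes,
       cohort = coh)
}
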