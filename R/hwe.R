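#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Tests whether observed genotype counts at a biallelic marker deviate from
#' Hardy-Weinberg proportions. The exact method conditions on the observed
#' allele counts and sums the probabilities of all heterozygote
#' configurations no more probable than the observed one (the standard
#' two-sided exact convention); the chi-square method compares observed
#' counts with p^2 : 2pq : q^2 expectations on 1 degree of freedom.
#'
#' @param n_major_hom,n_het,n_minor_hom non-negative genotype counts.
#' @param method `"exact"` (default) or `"chisq"`.
#' @return A two-sided p-value in `[0, 1]`.
#' @export
hwe_test <- function(n_major_hom, n_het, n_minor_hom,
                     method = c("exact", "chisq")) {
  method <- match.arg(method)
  counts <- c(n_major_hom, n_het, n_minor_hom)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be >= 1")
  n_minor <- 2L * n_minor_hom + n_het
  n_major <- 2L * n_major_hom + n_het
  if (n_minor == 0L || n_major == 0L) return(1.0)  # monomorphic
  if (method == "chisq") {
    p <- n_major / (2 * n)
    q <- 1 - p
    expd <- n * c(p^2, 2 * p * q, q^2)
    stat <- sum((counts - expd)^2 / expd)
    return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  .hwe_exact(n_major_hom, n_het, n_minor_hom)
}

# Exact test conditional on allele counts via the ratio recurrence
# P(h+2)/P(h) = 4 n_hom_rare(h) n_hom_common(h) / ((h+2)(h+1)),
# walking from the mode outward; numerically stable without factorials.
.hwe_exact <- function(n_major_hom, n_het, n_minor_hom) {
  n <- n_major_hom + n_het + n_minor_hom
  n_rare <- 2L * min(n_major_hom, n_minor_hom) + n_het
  obs_het <- n_het
  # possible heterozygote counts share the parity of the rare allele count
  h_min <- n_rare %% 2L
  h_max <- min(n_rare, 2L * n - n_rare)
  hs <- seq.int(h_min, h_max, by = 2L)
  probs <- numeric(length(hs))
  # start at the (approximate) mode to avoid underflow, then recurse
  q <- n_rare / (2 * n)
  mode_guess <- round(2 * n * q * (1 - q))
  start <- hs[which.min(abs(hs - mode_guess))]
  i0 <- match(start, hs)
  probs[i0] <- 1
  if (i0 < length(hs)) {
    for (i in seq.int(i0, length(hs) - 1L)) {
      h <- hs[i]
      rare_hom <- (n_rare - h) / 2
      common_hom <- n - h - rare_hom
      probs[i + 1L] <- probs[i] * 4 * rare_hom * common_hom /
        ((h + 2) * (h + 1))
    }
  }
  if (i0 > 1L) {
    for (i in seq.int(i0, 2L)) {
      h <- hs[i]
      rare_hom <- (n_rare - h) / 2 + 1
      common_hom <- n - (h - 2) - rare_hom
      probs[i - 1L] <- probs[i] * h * (h - 1) /
        (4 * rare_hom * common_hom)
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(obs_het, hs)]
  # tiny relative slack so ties in probability count as "as extreme"
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}
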