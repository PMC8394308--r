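#' Pairwise linkage disequilibrium r-squared
#'
#' Estimates the squared allelic correlation between two biallelic markers
#' from unphased genotypes. Two-locus haplotype frequencies are obtained by
#' expectation-maximisation (the only phase-ambiguous configuration being
#' the double heterozygote), and `r^2 = D^2 / (pA qA pB qB)` with `D` the
#' departure of the AB haplotype frequency from linkage equilibrium.
#' Subjects missing a call at either marker are excluded pairwise.
#'
#' @param table a [genotype_table()].
#' @param markerA,markerB marker names.
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   haplotype-frequency change.
#' @return A list with `r2` (`NA` when either marker is monomorphic among
#'   the jointly called subjects), `n` (subjects used), `monomorphic` flag
#'   and `iterations`.
#' @export
ld_r2 <- function(table, markerA, markerB, max_iter = 1000L, tol = 1e-10) {
  ca <- .marker_calls(table, markerA)
  cb <- .marker_calls(table, markerB)
  ok <- !is.na(ca$a1) & !is.na(cb$a1)
  n <- sum(ok)
  if (n < 2L)
    stop("fewer than 2 subjects with complete calls at both markers")
  ga <- .allele_dosage(ca$a1[ok], ca$a2[ok])
  gb <- .allele_dosage(cb$a1[ok], cb$a2[ok])
  if (is.null(ga) || is.null(gb))
    return(list(r2 = NA_real_, n = n, monomorphic = TRUE, iterations = 0L))
  if (identical(markerA, markerB))
    return(list(r2 = 1.0, n = n, monomorphic = FALSE, iterations = 0L))
  tab <- base::table(factor(ga, 0:2), factor(gb, 0:2))
  pA <- mean(ga) / 2
  pB <- mean(gb) / 2
  # haplotype freqs: h = (AB, Ab, aB, ab), initialised at equilibrium
  h <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cnt <- .ld_expected_counts(tab, h)
    hn <- cnt / sum(cnt)
    done <- max(abs(hn - h)) < tol
    h <- hn
    if (done || iter >= max_iter) break
  }
  pA <- h[1] + h[2]
  pB <- h[1] + h[3]
  D <- h[1] - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- if (denom > 0) D * D / denom else NA_real_
  list(r2 = r2, n = n, monomorphic = FALSE, iterations = iter)
}

# E-step: expected haplotype counts (AB, Ab, aB, ab) given the 3x3
# genotype-dosage table and current haplotype frequencies
.ld_expected_counts <- function(tab, h) {
  cnt <- numeric(4)
  for (i in 0:2) for (j in 0:2) {
    nij <- tab[i + 1L, j + 1L]
    if (nij == 0) next
    if (i == 1L && j == 1L) {
      cis <- h[1] * h[4]; trans <- h[2] * h[3]
      w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
      cnt <- cnt + nij * c(w, 1 - w, 1 - w, w)
    } else {
      cnt <- cnt + nij * .phase_unambiguous(i, j)
    }
  }
  cnt
}

# haplotype composition for a two-locus genotype with dosages (i, j),
# not both heterozygous: the split into two haplotypes is then unique
.phase_unambiguous <- function(i, j) {
  a <- c(rep(1L, i), rep(0L, 2L - i))
  b <- c(rep(1L, j), rep(0L, 2L - j))
  g <- numeric(4)
  for (k in 1:2) {
    idx <- if (a[k] == 1L && b[k] == 1L) 1L
    else if (a[k] == 1L) 2L
    else if (b[k] == 1L) 3L
    else 4L
    g[idx] <- g[idx] + 1
  }
  g
}

# dosage of the (lexicographically first) allele per subject, or NULL
# if the marker is monomorphic among these subjects
.allele_dosage <- function(a1, a2) {
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) < 2L) return(NULL)
  ref <- alleles[1]
  (a1 == ref) + (a2 == ref)
}
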