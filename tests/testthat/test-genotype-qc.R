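test_that("exact HWE test matches the enumeration oracle to 1e-12", {
  configs <- list(c(25, 25, 8), c(30, 0, 0), c(10, 20, 10), c(1, 1, 1),
                  c(50, 7, 1), c(20, 18, 20), c(0, 5, 25), c(28, 26, 4))
  set.seed(99)
  for (r in 1:20) {
    n <- sample(5:60, 1)
    x <- as.vector(stats::rmultinom(1, n, prob = c(0.5, 0.35, 0.15)))
    configs[[length(configs) + 1]] <- x
  }
  for (cf in configs) {
    if (sum(cf) == 0) next
    expect_equal(hwe_test(cf[1], cf[2], cf[3], method = "exact"),
                 hwe_enumeration_p(cf[1], cf[2], cf[3]),
                 tolerance = 1e-12,
                 label = paste("counts", paste(cf, collapse = ",")))
  }
})

test_that("chi-square HWE test equals the hand-computed statistic", {
  # counts (25, 30, 9): expected under HWE from the observed allele freqs
  obs <- c(25, 30, 9)
  n <- sum(obs)
  p <- (2 * obs[1] + obs[2]) / (2 * n)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((obs - expd)^2 / expd)
  expect_equal(hwe_test(25, 30, 9, method = "chisq"),
               pchisq(stat, df = 1, lower.tail = FALSE), tolerance = 1e-12)
  # perfect HWE proportions: statistic 0, p = 1
  expect_equal(hwe_test(10, 20, 10, method = "chisq"), 1.0)
  # no variation
  expect_equal(hwe_test(30, 0, 0), 1.0)
  expect_error(hwe_test(0, 0, 0), "total")
})

test_that("exact and chi-square p-values converge on large HWE cohorts", {
  # the exact test orders outcomes by conditional probability while the
  # chi-square orders by the statistic, so individual draws can disagree
  # by a few hundredths even at large n; typical (median) agreement is
  # what convergence buys
  set.seed(7)
  for (maf in c(0.12, 0.3, 0.48)) {
    gaps <- replicate(100, {
      g <- rbinom(5000, 2, maf)
      cts <- tabulate(g + 1, 3)
      abs(hwe_test(cts[1], cts[2], cts[3], method = "exact") -
            hwe_test(cts[1], cts[2], cts[3], method = "chisq"))
    })
    expect_lt(median(gaps), 0.02)
  }
})

test_that("marker summaries report MAF, HWE and monomorphism correctly", {
  g <- geno_from_counts(m1 = c(25, 25, 8), m2 = c(58, 0, 0))
  s1 <- summarize_marker(g, "m1")
  expect_equal(s1$maf, (25 + 16) / 116)
  expect_equal(s1$major_allele, "A")
  expect_equal(s1$minor_allele, "a")
  expect_equal(s1$hwe_p, hwe_enumeration_p(25, 25, 8), tolerance = 1e-12)
  expect_equal(s1$n_called, 58)
  s2 <- summarize_marker(g, "m2")
  expect_true(s2$monomorphic)
  expect_equal(s2$maf, 0.0)
  expect_equal(s2$hwe_p, 1.0)
  expect_error(summarize_marker(g, "nope"), "nope")
  # MAF = 0.5 tie: minor allele is the lexicographically smaller label
  g3 <- geno_from_counts(m = c(10, 20, 10), alleles = c("T", "C"))
  expect_equal(summarize_marker(g3, "m")$minor_allele, "C")
})

test_that("carrier coding flags heterozygotes and minor homozygotes", {
  g <- geno_from_counts(m = c(3, 2, 1))
  cc <- carrier_code(g, "m")
  expect_true(all(cc$values %in% c(0, 1)))
  expect_equal(cc$n_carriers, 2 + 1)   # n_het + n_minor_hom, exactly
  expect_equal(unname(cc$values), c(0, 0, 0, 1, 1, 1))
  expect_error(carrier_code(geno_from_counts(m = c(5, 0, 0)), "m"),
               "monomorphic")
})

test_that("carrier fraction approaches 1 - p^2 on a large HWE cohort", {
  # deletion-allele marker at major frequency 0.71: carriers = 1 - 0.71^2
  mk <- data.frame(marker = "rs5796555", major = "-", minor = "A",
                   maf = 0.29, stringsAsFactors = FALSE)
  spec <- cohort_spec(n_subjects = 20000L, markers = mk,
                      regions = "insula", seed = 123)
  g <- simulate_genotypes(spec)
  cc <- carrier_code(g, "rs5796555")
  expect_equal(mean(cc$values), 1 - 0.71^2, tolerance = 0.015)
  s <- summarize_marker(g, "rs5796555")
  expect_equal(s$minor_allele, "A")
  expect_lt(abs(s$maf - 0.29), 3 * sqrt(0.29 * 0.71 / (2 * 20000)))
})

test_that("ld_r2 is 1 for self, invariant to labels, and 0 in the limit", {
  set.seed(42)
  n <- 4000
  gA <- rbinom(n, 2, 0.3); gB <- rbinom(n, 2, 0.4)  # independent markers
  mk_mat <- function(g, al) {
    a1 <- ifelse(g >= 1, al[2], al[1])
    a2 <- ifelse(g == 2, al[2], al[1])
    list(a1 = a1, a2 = a2)
  }
  A <- mk_mat(gA, c("C", "T")); B <- mk_mat(gB, c("G", "A"))
  g <- genotype_table(sprintf("S%04d", 1:n), c("mA", "mB"),
                      cbind(A$a1, B$a1), cbind(A$a2, B$a2))
  expect_equal(ld_r2(g, "mA", "mA")$r2, 1.0)
  r_indep <- ld_r2(g, "mA", "mB")
  expect_lt(r_indep$r2, 0.005)
  expect_equal(r_indep$n, n)
  # swapping allele labels at one marker leaves r^2 unchanged
  A2 <- mk_mat(2 - gA, c("T", "C"))
  g2 <- genotype_table(sprintf("S%04d", 1:n), c("mA", "mB"),
                       cbind(A2$a1, B$a1), cbind(A2$a2, B$a2))
  expect_equal(ld_r2(g2, "mA", "mB")$r2, r_indep$r2, tolerance = 1e-9)
  # subject reordering leaves r^2 unchanged
  o <- sample(n)
  g3 <- genotype_table(sprintf("S%04d", 1:n), c("mA", "mB"),
                       cbind(A$a1, B$a1)[o, ], cbind(A$a2, B$a2)[o, ])
  expect_equal(ld_r2(g3, "mA", "mB")$r2, r_indep$r2, tolerance = 1e-12)
})

test_that("EM r2 equals the phased-count oracle without double heterozygotes", {
  # 10 subjects = 20 phased haplotypes chosen so that no subject is
  # heterozygous at both loci; phase is then unambiguous
  hapA <- c("A","A","A","A","A","A","a","a","a","a",
            "A","A","A","A","a","a","a","a","a","a")
  hapB <- c("B","B","B","b","b","b","b","b","b","b",
            "B","B","B","B","B","b","b","b","b","b")
  # pair haplotypes into subjects avoiding double hets
  ord <- order(hapA, hapB)
  hA <- hapA[ord]; hB <- hapB[ord]
  a1 <- hA[seq(1, 19, 2)]; a2 <- hA[seq(2, 20, 2)]
  b1 <- hB[seq(1, 19, 2)]; b2 <- hB[seq(2, 20, 2)]
  double_het <- (a1 != a2) & (b1 != b2)
  expect_false(any(double_het))
  g <- genotype_table(sprintf("S%02d", 1:10), c("mA", "mB"),
                      cbind(a1, b1), cbind(a2, b2))
  r <- ld_r2(g, "mA", "mB")
  expect_equal(r$r2, phased_r2(hA, hB), tolerance = 1e-8)
  # monomorphic marker: undefined and flagged, not 0
  gm <- genotype_table(sprintf("S%02d", 1:10), c("mA", "mB"),
                       cbind(rep("A", 10), b1), cbind(rep("A", 10), b2))
  rm_ <- ld_r2(gm, "mA", "mB")
  expect_true(rm_$monomorphic)
  expect_true(is.na(rm_$r2))
})

test_that("genotype CSV round-trips including missing calls", {
  g <- geno_from_counts(m1 = c(3, 2, 1), m2 = c(2, 2, 2))
  g$allele1[2, 1] <- NA; g$allele2[2, 1] <- NA
  g <- genotype_table(g$subjects, g$markers, g$allele1, g$allele2)
  f <- tempfile(fileext = ".csv")
  write_genotype_csv(g, f)
  g2 <- read_genotype_csv(f)
  expect_equal(g2$allele1[g$subjects, g$markers], g$allele1)
  expect_equal(g2$allele2[g$subjects, g$markers], g$allele2)
  expect_true(is.na(g2$allele1["S02", "m1"]))
  # missing calls propagate through carrier coding
  cc <- carrier_code(g2, "m1")
  expect_true(is.na(cc$values[["S02"]]))
  # summaries count missingness instead of dropping it silently
  expect_equal(summarize_marker(g2, "m1")$n_missing, 1)
})

test_that("table constructor rejects malformed genotype input", {
  expect_error(genotype_table(c("S1", "S1"), "m",
                              matrix("A", 2, 1), matrix("A", 2, 1)),
               "duplicate subject")
  expect_error(genotype_table(c("S1", "S2"), "m",
                              matrix(c("A", "C"), 2, 1),
                              matrix(c("T", "G"), 2, 1)),
               "more than 2 allele")
  expect_error(genotype_table("S1", "m", matrix("A", 1, 1),
                              matrix(NA_character_, 1, 1)),
               "half-missing")
})

test_that("minimal VCF reader maps GT calls onto allele labels", {
  skip_if_not_installed("vcfR")
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
           "12\t100\trsX\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
           "12\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0/1\t./.\t0/0")
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  g <- read_genotype_vcf(f)
  expect_equal(g$markers, c("rsX", "12:200"))
  expect_equal(unname(g$allele1[, "rsX"]), c("G", "G", "A"))
  expect_equal(unname(g$allele2[, "rsX"]), c("G", "A", "A"))
  expect_true(is.na(g$allele1["S2", "12:200"]))
  s <- summarize_marker(g, "rsX")
  expect_equal(s$maf, 3 / 6)
})
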