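#' Default marker panel for synthetic cohorts
#'
#' Six biallelic markers with the minor-allele frequencies of the study
#' panel, including a deletion ("-") allele treated as an ordinary label.
#'
#' @return data.frame (marker, major, minor, maf).
#' @export
default_markers <- function() {
  data.frame(
    marker = c("rs5796555", "rs1012586", "rs2268119", "rs2216128",
               "rs11609779", "rs2192973"),
    major = c("-", "G", "A", "A", "C", "G"),
    minor = c("A", "C", "T", "G", "T", "A"),
    maf = c(0.29, 0.34, 0.27, 0.26, 0.16, 0.22),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic cohort
#'
#' Captures everything needed to draw a seeded cohort with the structure
#' the analysis chain assumes: genotypes in Hardy-Weinberg equilibrium at
#' given minor-allele frequencies (optionally with two-locus LD), regional
#' morphometry with planted genotype effects, covariates, and a behavioral
#' outcome generated from a linear single-mediator model on the
#' standardized scale.
#'
#' @param n_subjects cohort size (default 58).
#' @param markers data.frame (marker, major, minor, maf); defaults to
#'   [default_markers()].
#' @param ld_blocks optional data.frame (markerA, markerB, r2) of target
#'   pairwise LD; listed pairs are drawn from two-locus haplotypes.
#' @param regions region tokens per hemisphere (default the 31-region
#'   list, giving 62 ROIs).
#' @param features features to emit (default all three).
#' @param path_spec optional data.frame (marker, hemi, region, feature, a,
#'   b, c_prime) of planted standardized triads; all rows must share one
#'   marker (a single causal variable drives the one outcome).
#' @param cov_effect_m,cov_effect_y standardized age/gender effects on the
#'   mediators and the outcome (default 0.1 each, so covariate adjustment
#'   is exercised).
#' @param age_range years, default `c(6, 17)`.
#' @param male_fraction default 42/58.
#' @param seed integer seed (mandatory).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 58L, markers = default_markers(),
                        ld_blocks = NULL, regions = dk_regions_31(),
                        features = c("thickness", "area", "volume"),
                        path_spec = NULL, cov_effect_m = 0.1,
                        cov_effect_y = 0.1, age_range = c(6, 17),
                        male_fraction = 42 / 58, seed) {
  if (missing(seed)) stop("seed is mandatory in cohort_spec()")
  if (any(markers$maf <= 0 | markers$maf > 0.5))
    stop("minor-allele frequencies must lie in (0, 0.5]")
  if (!is.null(path_spec)) {
    need <- c("marker", "hemi", "region", "feature", "a", "b", "c_prime")
    if (!all(need %in% names(path_spec)))
      stop("path_spec needs columns: ", paste(need, collapse = ", "))
    if (length(unique(path_spec$marker)) > 1L)
      stop("all planted triads must share a single causal marker")
    if (length(unique(path_spec$c_prime)) > 1L)
      stop("planted triads share one outcome; c_prime must be identical")
    if (any(abs(path_spec$a) >= 1) || any(abs(path_spec$b) >= 1) ||
        any(abs(path_spec$c_prime) >= 1))
      stop("generating standardized paths must have magnitude < 1")
    if (!all(path_spec$marker %in% markers$marker))
      stop("path_spec marker not in marker panel")
    implied_c <- path_spec$c_prime[1] + sum(path_spec$a * path_spec$b)
    if (abs(implied_c) >= 1)
      stop("implied total effect |c| >= 1: unidentifiable standardized scale")
  }
  structure(list(n_subjects = as.integer(n_subjects), markers = markers,
                 ld_blocks = ld_blocks, regions = regions,
                 features = features, path_spec = path_spec,
                 cov_effect_m = cov_effect_m, cov_effect_y = cov_effect_y,
                 age_range = age_range, male_fraction = male_fraction,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# de-standardization constants: normalized-scale location/spread per
# feature (ratios for volume/area, mm for thickness) and global scales.
# The exact magnitudes are arbitrary plausible values; planted effects are
# written on the normalized scale and multiplied back by the subject's
# global, so pipeline normalization recovers them exactly.
.morph_constants <- function() {
  list(volume = c(loc = 3.5e-3, scale = 3.5e-4),
       area = c(loc = 1.5e-2, scale = 1.5e-3),
       thickness = c(loc = 2.5, scale = 0.15),
       icv = c(mean = 1.45e6, sd = 1.2e5),
       total_sa = c(mean = 1.7e5, sd = 1.5e4))
}

#' Draw genotypes under Hardy-Weinberg equilibrium
#'
#' Each marker's genotypes are two independent allele draws at its minor
#' frequency (subjects independent). Marker pairs listed in `ld_blocks`
#' are instead drawn as two-locus haplotypes whose frequencies imply the
#' target `r^2` (positive-D construction
#' `D = sqrt(r2 * pA qA pB qB)`).
#'
#' @param spec a [cohort_spec()].
#' @return A [genotype_table()].
#' @export
simulate_genotypes <- function(spec) {
  set.seed(spec$seed)
  .simulate_genotypes_impl(spec)
}

.simulate_genotypes_impl <- function(spec) {
  mk <- spec$markers
  n <- spec$n_subjects
  subjects <- sprintf("S%03d", seq_len(n))
  a1 <- matrix(NA_character_, n, nrow(mk),
               dimnames = list(subjects, mk$marker))
  a2 <- a1
  in_block <- character()
  if (!is.null(spec$ld_blocks)) {
    for (k in seq_len(nrow(spec$ld_blocks))) {
      bl <- spec$ld_blocks[k, ]
      ia <- match(bl$markerA, mk$marker); ib <- match(bl$markerB, mk$marker)
      if (is.na(ia) || is.na(ib))
        stop("ld_blocks marker not in panel: ", bl$markerA, "/", bl$markerB)
      pA <- mk$maf[ia]; pB <- mk$maf[ib]
      D <- sqrt(bl$r2 * pA * (1 - pA) * pB * (1 - pB))
      h <- c(mm = pA * pB + D, mM = pA * (1 - pB) - D,
             Mm = (1 - pA) * pB - D, MM = (1 - pA) * (1 - pB) + D)
      if (any(h < 0))
        stop("target r2 ", bl$r2, " infeasible at MAFs ", pA, ", ", pB)
      hapA <- c(mk$minor[ia], mk$minor[ia], mk$major[ia], mk$major[ia])
      hapB <- c(mk$minor[ib], mk$major[ib], mk$minor[ib], mk$major[ib])
      for (copy in 1:2) {
        draw <- sample.int(4L, n, replace = TRUE, prob = h)
        if (copy == 1L) {
          a1[, ia] <- hapA[draw]; a1[, ib] <- hapB[draw]
        } else {
          a2[, ia] <- hapA[draw]; a2[, ib] <- hapB[draw]
        }
      }
      in_block <- c(in_block, bl$markerA, bl$markerB)
    }
  }
  for (j in seq_len(nrow(mk))) {
    if (mk$marker[j] %in% in_block) next
    al <- c(mk$minor[j], mk$major[j])
    pr <- c(mk$maf[j], 1 - mk$maf[j])
    a1[, j] <- sample(al, n, replace = TRUE, prob = pr)
    a2[, j] <- sample(al, n, replace = TRUE, prob = pr)
  }
  genotype_table(subjects, mk$marker, a1, a2)
}

#' Simulate a full cohort: genotypes, morphometry, phenotypes
#'
#' Generates genotypes under HWE, age and gender covariates, regional
#' morphometry and a behavioral outcome. For planted triads the mediator
#' is `M = a*X + cov effects + noise` and the outcome
#' `Y = c'*X + sum(b_i * M_i) + cov effects + noise` on the standardized
#' population scale, with X the standardized minor-allele-carrier code;
#' residual variances are chosen so every generated variable has unit
#' population variance, making the planted `a`, `b`, `c_prime` directly
#' comparable to fitted standardized coefficients. Unplanted ROIs are
#' independent noise. Morphometry is written back on a positive
#' mm/mm^2/mm^3 scale with per-subject globals so that normalization in
#' the analysis recovers the planted structure exactly.
#'
#' @param spec a [cohort_spec()].
#' @return A list with `genotypes` ([genotype_table()]), `morphometry`
#'   ([morphometry_table()]), `phenotypes` ([phenotype_table()]) and
#'   `truth` (the generating values actually used).
#' @export
simulate_cohort <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_subjects
  geno <- .simulate_genotypes_impl(spec)
  subjects <- geno$subjects
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  gender <- ifelse(stats::runif(n) < spec$male_fraction, "M", "F")
  # population-standardized covariates used in the generating model
  age_s <- (age - mean(spec$age_range)) /
    sqrt(diff(spec$age_range)^2 / 12)
  gen_s <- (as.numeric(gender == "M") - spec$male_fraction) /
    sqrt(spec$male_fraction * (1 - spec$male_fraction))
  gm <- spec$cov_effect_m
  gy <- spec$cov_effect_y
  cst <- .morph_constants()
  icv <- abs(stats::rnorm(n, cst$icv["mean"], cst$icv["sd"]))
  tsa <- abs(stats::rnorm(n, cst$total_sa["mean"], cst$total_sa["sd"]))
  globals <- data.frame(subject = subjects, icv = icv, total_sa = tsa)

  ps <- spec$path_spec
  m_std <- NULL
  y_std <- NULL
  if (!is.null(ps) && nrow(ps) > 0L) {
    cc <- carrier_code(geno, ps$marker[1])
    pcar <- mean(cc$values)
    if (pcar == 0 || pcar == 1)
      stop("simulated marker ", ps$marker[1], " is monomorphic in the ",
           "carrier coding; re-seed or raise n_subjects")
    x_s <- (cc$values - pcar) / sqrt(pcar * (1 - pcar))
    m_std <- matrix(NA_real_, n, nrow(ps))
    for (k in seq_len(nrow(ps))) {
      a <- ps$a[k]
      s2 <- 1 - a^2 - gm^2 - gm^2
      if (s2 <= 0) stop("mediator residual variance <= 0; reduce |a|")
      m_std[, k] <- a * x_s + gm * age_s + gm * gen_s +
        stats::rnorm(n, 0, sqrt(s2))
    }
    b <- ps$b
    c_prime <- ps$c_prime[1]
    sig <- c_prime * x_s + m_std %*% b + gy * age_s + gy * gen_s
    v_sig <- .signal_variance(ps$a, b, c_prime, gm, gy)
    if (v_sig >= 1)
      stop("structural variance of the outcome >= 1; shrink the paths")
    y_std <- as.numeric(sig) + stats::rnorm(n, 0, sqrt(1 - v_sig))
  }

  vals <- list()
  i <- 0L
  for (hemi in c("lh", "rh")) for (reg in spec$regions)
    for (f in spec$features) {
      i <- i + 1L
      planted <- !is.null(ps) &&
        any(ps$hemi == hemi & ps$region == reg & ps$feature == f)
      if (planted) {
        k <- which(ps$hemi == hemi & ps$region == reg & ps$feature == f)[1]
        std <- m_std[, k]
      } else {
        std <- stats::rnorm(n)
      }
      co <- cst[[f]]
      norm_scale <- co["loc"] + co["scale"] * std
      raw <- switch(f,
                    volume = norm_scale * icv,
                    area = norm_scale * tsa,
                    thickness = norm_scale)
      vals[[i]] <- data.frame(subject = subjects, hemi = hemi,
                              region = reg, feature = f,
                              value = as.numeric(raw),
                              stringsAsFactors = FALSE)
    }
  morph <- morphometry_table(do.call(rbind, vals), globals)
  if (is.null(y_std)) y_std <- stats::rnorm(n)
  pheno <- phenotype_table(subjects, ap_score = 60 + 8 * y_std,
                           age = age, gender = gender)
  list(genotypes = geno, morphometry = morph, phenotypes = pheno,
       truth = list(path_spec = ps,
                    implied_c = if (!is.null(ps))
                      ps$c_prime[1] + sum(ps$a * ps$b) else NA_real_,
                    seed = spec$seed))
}

# Var(c'X + sum b_i M_i + gy*A + gy*G) with M_i = a_i X + gm A + gm G + e_i,
# X, A, G independent standardized, e_i independent
.signal_variance <- function(a, b, c_prime, gm, gy) {
  # coefficient on X: c' + sum b_i a_i ; on A and G: gy + gm * sum b_i
  cx <- c_prime + sum(b * a)
  ca <- gy + gm * sum(b)
  # e_i variance: 1 - a_i^2 - 2 gm^2, contributes b_i^2 * var(e_i)
  ve <- 1 - a^2 - 2 * gm^2
  cx^2 + 2 * ca^2 + sum(b^2 * ve)
}

#' Write a simulated cohort in the pipeline's file dialects
#'
#' Emits the genotype CSV, one stats table per hemisphere and feature, the
#' globals TSV and the phenotype CSV into a directory.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(genotypes = file.path(dir, "genotypes.csv"),
                phenotypes = file.path(dir, "phenotypes.csv"),
                globals = file.path(dir, "globals.tsv"))
  write_genotype_csv(cohort$genotypes, paths$genotypes)
  utils::write.csv(as.data.frame(cohort$phenotypes), paths$phenotypes,
                   row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$morphometry$globals, paths$globals,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (hemi in unique(cohort$morphometry$values$hemi))
    for (f in unique(cohort$morphometry$values$feature)) {
      sel <- cohort$morphometry$values$hemi == hemi &
        cohort$morphometry$values$feature == f
      p <- file.path(dir, paste0(hemi, ".", f, ".tsv"))
      write_stats_table(cohort$morphometry$values[sel, ], p)
      paths[[paste0(hemi, "_", f)]] <- p
    }
  invisible(paths)
}

#' Write a small versioned fixture cohort for tests and examples
#'
#' A deliberately small cohort (default 20 subjects, 4 regions) in the
#' exact file dialects the readers consume.
#'
#' @param dir output directory.
#' @param seed integer seed (default 20260928).
#' @return Named list of file paths, invisibly.
#' @export
make_fixtures <- function(dir, seed = 20260928L) {
  spec <- cohort_spec(n_subjects = 20L,
                      regions = c("isthmuscingulate", "inferiorparietal",
                                  "precuneus", "insula"),
                      seed = seed)
  write_cohort(simulate_cohort(spec), dir)
}
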