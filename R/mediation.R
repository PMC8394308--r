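#' Z-score standardization
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (n-1
#' denominator). Binary variables are standardized like any other; the
#' transform is affine, so t-statistics and p-values of regressions on the
#' standardized variable are unchanged and coefficients are reported on
#' the standardized scale.
#'
#' @param values numeric vector with at least 2 distinct finite values.
#' @return Standardized numeric vector (names preserved).
#' @export
zscore <- function(values) {
  v <- as.numeric(values)
  if (length(unique(v[is.finite(v)])) < 2L)
    stop("cannot z-score a constant input")
  out <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  names(out) <- names(values)
  out
}

# Assemble complete-case, standardized mediation data with design matrices.
# x, m, y are named per-subject vectors; covariates a phenotype_table-like
# data.frame (subject, age, gender). Returns list with z-scored x/m/y,
# covariate columns and the two design matrices used by every path fit.
.mediation_data <- function(x, m, y, covariates) {
  subj <- Reduce(intersect, list(names(x), names(m), names(y),
                                 covariates$subject))
  ci <- match(subj, covariates$subject)
  d <- data.frame(subject = subj,
                  x = as.numeric(x[subj]), m = as.numeric(m[subj]),
                  y = as.numeric(y[subj]),
                  age = covariates$age[ci],
                  gender = as.numeric(factor(covariates$gender[ci])) - 1)
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 10L)
    stop("need at least 10 complete cases for mediation, got ", nrow(d))
  if (abs(stats::cor(d$x, d$m)) > 0.999)
    stop("mediator is collinear with the causal variable (|r| > 0.999)")
  d$x <- zscore(d$x); d$m <- zscore(d$m); d$y <- zscore(d$y)
  list(d = d, n = nrow(d),
       Zm = cbind(1, d$gender, d$age, d$x),
       Zy = cbind(1, d$gender, d$age, d$x, d$m))
}

#' Estimate mediation path coefficients by OLS
#'
#' Standardizes X, M and Y, then fits the three covariate-adjusted
#' regressions of the single-mediator model: `M ~ X + age + gender`
#' (path a), `Y ~ X + age + gender` (total effect c) and
#' `Y ~ X + M + age + gender` (direct effect c' and path b); the indirect
#' effect is `ab = a * b`. With the same covariates in all three
#' regressions the OLS identity `c = c' + a*b` holds exactly.
#'
#' @param x,m,y named per-subject numeric vectors (causal variable,
#'   mediator, outcome).
#' @param covariates data.frame with columns subject, age, gender.
#' @return A list with `a`, `b`, `c`, `c_prime`, `ab` and `n`.
#' @export
fit_paths <- function(x, m, y, covariates) {
  md <- .mediation_data(x, m, y, covariates)
  d <- md$d
  fa <- stats::lm(m ~ gender + age + x, data = d)
  fc <- stats::lm(y ~ gender + age + x, data = d)
  fy <- stats::lm(y ~ gender + age + x + m, data = d)
  a <- unname(stats::coef(fa)["x"])
  b <- unname(stats::coef(fy)["m"])
  c_prime <- unname(stats::coef(fy)["x"])
  ctot <- unname(stats::coef(fc)["x"])
  list(a = a, b = b, c = ctot, c_prime = c_prime, ab = a * b, n = md$n)
}

# fast path refit on (possibly resampled) rows: returns c(a, b, c_prime)
.paths_fast <- function(Zm, mvec, Zy, yvec) {
  ca <- .lm.fit(Zm, mvec)$coefficients
  cy <- .lm.fit(Zy, yvec)$coefficients
  c(a = ca[4L], b = cy[5L], c_prime = cy[4L])
}

#' Case-resampling bootstrap of the mediation paths
#'
#' Draws subjects with replacement (whole rows: X, M, Y and covariates),
#' refits all paths per resample and returns the resample distributions.
#' Standardization is performed once on the observed data; resamples
#' re-use the standardized rows. Resamples in which the causal variable is
#' constant cannot be fit and are redrawn; their count is reported, and
#' more than 10% redraws is an error suggesting a larger sample.
#' The total effect per resample uses the exact OLS identity
#' `c = c' + a*b`.
#'
#' @inheritParams fit_paths
#' @param n_resamples number of bootstrap resamples (default 5000).
#' @param seed integer seed (mandatory, for reproducibility).
#' @return A list with `draws` (`n_resamples x 5` matrix, columns a, b,
#'   c, c_prime, ab) and `n_redraws`.
#' @export
bootstrap_paths <- function(x, m, y, covariates, n_resamples = 5000L, seed) {
  if (missing(seed)) stop("seed is required for bootstrap_paths()")
  md <- .mediation_data(x, m, y, covariates)
  .bootstrap_core(md, n_resamples, seed)
}

.bootstrap_core <- function(md, n_resamples, seed) {
  set.seed(seed)
  n <- md$n
  Zm <- md$Zm; Zy <- md$Zy
  mvec <- md$d$m; yvec <- md$d$y; xvec <- md$d$x
  draws <- matrix(NA_real_, n_resamples, 5L,
                  dimnames = list(NULL, c("a", "b", "c", "c_prime", "ab")))
  n_redraws <- 0L
  max_redraws <- ceiling(0.1 * n_resamples)
  for (r in seq_len(n_resamples)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      xs <- xvec[idx]
      if (xs[1L] != xs[2L] || length(unique(xs)) > 1L) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > max_redraws)
        stop("more than 10% of resamples had a constant causal variable; ",
             "the sample is too small or too unbalanced for the bootstrap")
    }
    p <- .paths_fast(Zm[idx, , drop = FALSE], mvec[idx],
                     Zy[idx, , drop = FALSE], yvec[idx])
    ab <- p[["a"]] * p[["b"]]
    draws[r, ] <- c(p[["a"]], p[["b"]], p[["c_prime"]] + ab,
                    p[["c_prime"]], ab)
  }
  list(draws = draws, n_redraws = n_redraws)
}

# leave-one-out path estimates, n x 5 matrix (a, b, c, c_prime, ab)
.jackknife_paths <- function(md) {
  n <- md$n
  out <- matrix(NA_real_, n, 5L,
                dimnames = list(NULL, c("a", "b", "c", "c_prime", "ab")))
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    p <- .paths_fast(md$Zm[idx, , drop = FALSE], md$d$m[idx],
                     md$Zy[idx, , drop = FALSE], md$d$y[idx])
    ab <- p[["a"]] * p[["b"]]
    out[i, ] <- c(p[["a"]], p[["b"]], p[["c_prime"]] + ab,
                  p[["c_prime"]], ab)
  }
  out
}

#' Bias-corrected and accelerated (BCa) bootstrap interval and p-value
#'
#' The bias-correction term is `z0 = qnorm(f)` with `f` the fraction of
#' resamples below the point estimate; the acceleration is the jackknife
#' skewness `sum(d^3) / (6 * sum(d^2)^1.5)` with `d` the deviations of the
#' leave-one-out estimates from their mean. Endpoints are type-6
#' (Hazen-interpolated) quantiles of the resample distribution at the
#' corrected levels. The p-value is the smallest two-sided level at which
#' the BCa interval excludes zero, found by bisection (tolerance 1e-4);
#' when even the widest resolvable interval excludes zero the p-value is
#' reported as the bound `2 / n_resamples` with `p_bound = TRUE`.
#'
#' @param boot_dist numeric vector of bootstrap replicates of a statistic.
#' @param point_estimate the statistic on the observed data.
#' @param jackknife_estimates leave-one-out estimates of the statistic.
#' @param alpha two-sided level for the reported interval (default 0.05).
#' @return A list with `lower`, `upper`, `p`, `p_bound`, `z0`, `accel`.
#' @export
bca_interval <- function(boot_dist, point_estimate, jackknife_estimates,
                         alpha = 0.05) {
  B <- length(boot_dist)
  f <- mean(boot_dist < point_estimate)
  if (f == 0 || f == 1)
    stop("all bootstrap resamples fall on one side of the point estimate ",
         "(fraction below = ", f, "); the bias correction is unbounded - ",
         "the resample distribution is degenerate")
  z0 <- stats::qnorm(f)
  dvs <- mean(jackknife_estimates) - jackknife_estimates
  denom <- sum(dvs^2)
  accel <- if (denom > 0) sum(dvs^3) / (6 * denom^1.5) else 0
  ends <- function(a) {
    zlo <- stats::qnorm(a / 2); zhi <- stats::qnorm(1 - a / 2)
    p1 <- stats::pnorm(z0 + (z0 + zlo) / (1 - accel * (z0 + zlo)))
    p2 <- stats::pnorm(z0 + (z0 + zhi) / (1 - accel * (z0 + zhi)))
    stats::quantile(boot_dist, c(p1, p2), type = 6, names = FALSE)
  }
  excludes0 <- function(a) {
    e <- ends(a)
    e[1] > 0 || e[2] < 0
  }
  ci <- ends(alpha)
  lo_a <- 2 / B
  p_bound <- FALSE
  if (excludes0(lo_a)) {
    p <- lo_a
    p_bound <- TRUE
  } else if (!excludes0(1 - 1e-6)) {
    p <- 1
  } else {
    lo <- lo_a; hi <- 1 - 1e-6
    while (hi - lo > 1e-4) {
      mid <- (lo + hi) / 2
      if (excludes0(mid)) hi <- mid else lo <- mid
    }
    p <- hi
  }
  list(lower = ci[1], upper = ci[2], p = p, p_bound = p_bound,
       z0 = z0, accel = accel)
}

#' Covariate-adjusted single-mediator analysis with bootstrap BCa inference
#'
#' Runs the full mediation procedure on one (X, M, Y) triad: Z-score
#' standardization, OLS path estimation, case-resampling bootstrap with
#' BCa confidence intervals and p-values, and prerequisite gating. The
#' indirect effect `ab` and the direct effect `c'` are evaluated only when
#' X accounts for variability in Y (path c) and in M (path a) and M
#' accounts for variability in Y given X (path b), all at `alpha`;
#' otherwise they are reported as not evaluated ("n.e."). The proportion
#' mediated `100 * ab / c` is reported when evaluated and when `ab` and
#' `c` agree in sign (otherwise flagged inconsistent, since the ratio is
#' then misleading).
#'
#' @inheritParams fit_paths
#' @param n_resamples bootstrap resamples (default 5000; at least 1000
#'   for inference).
#' @param seed integer seed (required).
#' @param alpha two-sided significance and CI level (default 0.05).
#' @param permutation also compute Freedman-Lane permutation p-values for
#'   every path (default FALSE).
#' @param n_perm permutation count when `permutation = TRUE`.
#' @return An object of class `mediation_result`: `paths` data.frame
#'   (parameter, estimate, ci_lower, ci_upper, p, p_bound, evaluated),
#'   `proportion_mediated` (percent or NA), `proportion_note`,
#'   `classification`, `n`, `n_resamples`, `n_redraws`, `seed`, `alpha`,
#'   and optionally `permutation_p`.
#' @export
mediate <- function(x, m, y, covariates, n_resamples = 5000L, seed,
                    alpha = 0.05, permutation = FALSE, n_perm = 5000L) {
  if (missing(seed)) stop("seed is required for mediate()")
  if (n_resamples < 1000L)
    stop("n_resamples must be at least 1000 for inference")
  md <- .mediation_data(x, m, y, covariates)
  est <- fit_paths(x, m, y, covariates)
  boot <- .bootstrap_core(md, n_resamples, seed)
  jack <- .jackknife_paths(md)
  pars <- c("a", "b", "c", "c_prime", "ab")
  paths <- data.frame(parameter = pars,
                      estimate = unlist(est[pars], use.names = FALSE),
                      ci_lower = NA_real_, ci_upper = NA_real_,
                      p = NA_real_, p_bound = FALSE, evaluated = TRUE,
                      stringsAsFactors = FALSE)
  bca <- list()
  for (pp in pars)
    bca[[pp]] <- bca_interval(boot$draws[, pp], est[[pp]], jack[, pp],
                              alpha = alpha)
  for (i in seq_along(pars)) {
    paths$ci_lower[i] <- bca[[pars[i]]]$lower
    paths$ci_upper[i] <- bca[[pars[i]]]$upper
    paths$p[i] <- bca[[pars[i]]]$p
    paths$p_bound[i] <- bca[[pars[i]]]$p_bound
  }
  prereq_ok <- bca$a$p < alpha && bca$b$p < alpha && bca$c$p < alpha
  proportion <- NA_real_
  note <- NA_character_
  classification <- "mediation not evaluated (prerequisites unmet)"
  if (!prereq_ok) {
    ne <- paths$parameter %in% c("ab", "c_prime")
    paths$evaluated[ne] <- FALSE
    paths$ci_lower[ne] <- paths$ci_upper[ne] <- paths$p[ne] <- NA_real_
    paths$p_bound[ne] <- NA
  } else {
    if (sign(est$ab) == sign(est$c)) {
      proportion <- 100 * est$ab / est$c
    } else {
      note <- "inconsistent mediation: ab and c differ in sign"
    }
    classification <- if (bca$c_prime$p < alpha)
      "partial mediation (direct and indirect effects)"
    else
      "indirect-dominant mediation (direct effect not significant)"
  }
  out <- list(paths = paths, proportion_mediated = proportion,
              proportion_note = note, classification = classification,
              n = md$n, n_resamples = n_resamples,
              n_redraws = boot$n_redraws, seed = seed, alpha = alpha)
  if (permutation) {
    out$permutation_p <- vapply(
      pars, function(pp) permutation_p(x, m, y, covariates, path = pp,
                                       n_perm = n_perm, seed = seed),
      numeric(1))
  }
  class(out) <- "mediation_result"
  out
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Single-mediator analysis (n = ", x$n, ", ", x$n_resamples,
      " bootstrap resamples, seed ", x$seed, ")\n\n", sep = "")
  df <- x$paths
  fmt <- function(v) ifelse(is.na(v), "n.e.", sprintf("%.3f", v))
  disp <- data.frame(parameter = df$parameter,
                     value = fmt(df$estimate),
                     ci = ifelse(df$evaluated,
                                 sprintf("[%.3f %.3f]", df$ci_lower,
                                         df$ci_upper), "n.e."),
                     p = ifelse(df$evaluated,
                                ifelse(!is.na(df$p_bound) & df$p_bound,
                                       sprintf("<%.4g", df$p),
                                       sprintf("%.4g", df$p)), "n.e."))
  names(disp) <- c("parameter", "value", "95% CI", "p")
  print(disp, row.names = FALSE)
  if (!is.na(x$proportion_mediated))
    cat(sprintf("\nProportion mediated: %.2f%%\n", x$proportion_mediated))
  if (!is.na(x$proportion_note)) cat("\n", x$proportion_note, "\n", sep = "")
  cat("\n", x$classification, "\n", sep = "")
  invisible(x)
}

#' Freedman-Lane permutation p-value for a mediation path
#'
#' Tests the chosen path by permuting the residuals of the reduced model
#' (the model without the tested predictor) while preserving the
#' covariate structure, refitting, and comparing the absolute test
#' statistic with its permutation distribution. For the composite
#' indirect effect `ab`, the causal variable is residualized on the
#' covariates and its residuals permuted, breaking the X-M and X-Y links
#' simultaneously under the null of no X effect.
#'
#' @inheritParams fit_paths
#' @param path one of `"a"`, `"b"`, `"c"`, `"c_prime"`, `"ab"`.
#' @param n_perm number of permutations (at least 100).
#' @param seed integer seed (required).
#' @return Permutation p-value `(1 + #\{|stat_perm| >= |stat_obs|\}) /
#'   (1 + n_perm)`.
#' @export
permutation_p <- function(x, m, y, covariates,
                          path = c("a", "b", "c", "c_prime", "ab"),
                          n_perm = 5000L, seed) {
  path <- match.arg(path)
  if (missing(seed)) stop("seed is required for permutation_p()")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  md <- .mediation_data(x, m, y, covariates)
  set.seed(seed)
  d <- md$d
  n <- md$n
  Zc <- cbind(1, d$gender, d$age)                 # covariates only
  coef_of <- function(Z, resp, col) .lm.fit(Z, resp)$coefficients[col]
  if (path == "ab") {
    fx <- .lm.fit(Zc, d$x)
    xhat <- d$x - fx$residuals
    stat_obs <- {
      p <- .paths_fast(md$Zm, d$m, md$Zy, d$y)
      p[["a"]] * p[["b"]]
    }
    stats_perm <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      xs <- xhat + fx$residuals[sample.int(n)]
      Zm <- cbind(1, d$gender, d$age, xs)
      Zy <- cbind(1, d$gender, d$age, xs, d$m)
      p <- .paths_fast(Zm, d$m, Zy, d$y)
      stats_perm[r] <- p[["a"]] * p[["b"]]
    }
    return((1 + sum(abs(stats_perm) >= abs(stat_obs))) / (1 + n_perm))
  }
  # single-coefficient paths: full model, tested column, reduced model
  spec <- switch(path,
    a = list(Z = md$Zm, resp = d$m, col = 4L, Zred = Zc),
    c = list(Z = cbind(1, d$gender, d$age, d$x), resp = d$y, col = 4L,
             Zred = Zc),
    c_prime = list(Z = md$Zy, resp = d$y, col = 4L,
                   Zred = cbind(1, d$gender, d$age, d$m)),
    b = list(Z = md$Zy, resp = d$y, col = 5L,
             Zred = cbind(1, d$gender, d$age, d$x)))
  stat_obs <- coef_of(spec$Z, spec$resp, spec$col)
  red <- .lm.fit(spec$Zred, spec$resp)
  fitted_red <- spec$resp - red$residuals
  stats_perm <- numeric(n_perm)
  for (r in seq_len(n_perm)) {
    resp_star <- fitted_red + red$residuals[sample.int(n)]
    stats_perm[r] <- coef_of(spec$Z, resp_star, spec$col)
  }
  (1 + sum(abs(stats_perm) >= abs(stat_obs))) / (1 + n_perm)
}

#' Write a mediation result as TSV plus a JSON run record
#'
#' The TSV mirrors the usual mediation summary layout (parameter, value,
#' 95% CI bounds, p, evaluated flag, proportion mediated); the JSON record
#' carries seed, resample count and degenerate-redraw count.
#'
#' @param result a [mediate()] result.
#' @param path output TSV path; the JSON record is written alongside with
#'   extension `.json`.
#' @return `path`, invisibly.
#' @export
write_mediation_tsv <- function(result, path) {
  df <- result$paths
  df$estimate <- round(df$estimate, 4)
  df$ci_lower <- round(df$ci_lower, 4)
  df$ci_upper <- round(df$ci_upper, 4)
  df$p <- signif(df$p, 4)
  df$proportion_mediated <- c(round(result$proportion_mediated, 2),
                              rep(NA, nrow(df) - 1L))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "n.e.")
  rec <- list(seed = result$seed, n_resamples = result$n_resamples,
              n_redraws = result$n_redraws, n = result$n,
              alpha = result$alpha,
              classification = result$classification)
  jsonlite::write_json(rec, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
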