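#' Phenotype table constructor/validator
#'
#' @param subjects character identifiers (unique).
#' @param ap_score mean attention-problems T score across waves.
#' @param age age in years.
#' @param gender two-level code (factor, character or 0/1).
#' @return data.frame of class `phenotype_table` with columns subject,
#'   ap_score, age, gender; T scores far outside the plausible 20-120
#'   range trigger a warning, not an error.
#' @export
phenotype_table <- function(subjects, ap_score, age, gender) {
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects))
    stop("duplicate subjects in phenotype table")
  if (length(unique(stats::na.omit(as.character(gender)))) > 2L)
    stop("gender must be a two-level code")
  out_of_range <- !is.na(ap_score) & (ap_score < 20 | ap_score > 120)
  if (any(out_of_range))
    warning(sum(out_of_range), " ap_score value(s) outside the plausible ",
            "T-score range 20-120")
  df <- data.frame(subject = subjects, ap_score = as.numeric(ap_score),
                   age = as.numeric(age),
                   gender = as.character(gender),
                   stringsAsFactors = FALSE)
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Read a phenotype CSV (subject, ap_score, age, gender)
#'
#' @param path path to the CSV.
#' @return A [phenotype_table()].
#' @export
read_phenotype_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "ap_score", "age", "gender")
  if (!all(need %in% names(df)))
    stop("phenotype CSV must have columns: ", paste(need, collapse = ", "))
  phenotype_table(df$subject, df$ap_score, df$age, df$gender)
}

#' Fit one screening GLM
#'
#' Ordinary least squares of `y ~ 1 + gender + age + predictor` on
#' complete cases, with a double-sided t-test on the predictor
#' coefficient. The error degrees of freedom are `n_complete - 4` for
#' this four-column design.
#'
#' @param y named numeric outcome vector (names = subjects).
#' @param predictor named numeric predictor vector.
#' @param covariates data.frame with columns subject, age, gender.
#' @return A one-row data.frame: beta, t, df, p, n_complete.
#' @export
fit_glm <- function(y, predictor, covariates) {
  subj <- intersect(names(y), intersect(names(predictor), covariates$subject))
  ci <- match(subj, covariates$subject)
  d <- data.frame(y = as.numeric(y[subj]),
                  x = as.numeric(predictor[subj]),
                  age = covariates$age[ci],
                  gender = as.numeric(factor(covariates$gender[ci])) - 1)
  d <- d[stats::complete.cases(d), ]
  ncol_design <- 4L
  if (nrow(d) < ncol_design + 1L)
    stop("need at least ", ncol_design + 1L, " complete cases, got ", nrow(d))
  if (length(unique(d$x)) < 2L) stop("constant predictor")
  X <- cbind(1, d$gender, d$age, d$x)
  qr_X <- qr(X)
  if (qr_X$rank < ncol_design) {
    cols <- c("intercept", "gender", "age", "predictor")
    drop <- setdiff(seq_len(ncol_design), qr_X$pivot[seq_len(qr_X$rank)])
    stop("rank-deficient design; collinear column(s): ",
         paste(cols[drop], collapse = ", "))
  }
  fit <- stats::lm(y ~ gender + age + x, data = d)
  sm <- summary(fit)$coefficients
  data.frame(beta = sm["x", "Estimate"], t = sm["x", "t value"],
             df = fit$df.residual, p = sm["x", "Pr(>|t|)"],
             n_complete = nrow(d))
}

# subjects x (roi, feature) normalized outcome matrix helper
.screen_one <- function(outcome, coding, pheno) {
  fit_glm(outcome, coding$values, pheno)
}

#' Design #1 screen: SNP effects on regional morphometry
#'
#' Fits one GLM per (marker, ROI, feature) combination with the
#' feature-appropriate normalization (volume/ICV, area/total surface,
#' thickness raw) and age + gender covariates. Corrected significance uses
#' the Bonferroni threshold `alpha / mc_divisor`.
#'
#' @param morph a [morphometry_table()].
#' @param codings list of [carrier_code()] results (one per marker).
#' @param pheno a [phenotype_table()] supplying the covariates.
#' @param alpha raw two-sided significance level (default 0.05).
#' @param mc_divisor Bonferroni divisor for the corrected threshold
#'   (default 31).
#' @param rois optional data.frame (hemi, region) restricting the ROI set;
#'   defaults to all ROIs present in `morph`.
#' @param features features to screen (default all three).
#' @return data.frame of class `glm_screen`: one row per
#'   (marker, hemi, region, feature) in lexicographic order, with beta, t,
#'   df, p, n_complete, p_corrected_alpha, significant_raw,
#'   significant_corrected.
#' @export
screen_design1 <- function(morph, codings, pheno, alpha = 0.05,
                           mc_divisor = 31,
                           rois = NULL,
                           features = c("thickness", "area", "volume")) {
  if (is.null(rois)) {
    rois <- unique(morph$values[, c("hemi", "region")])
  }
  rois <- rois[order(rois$hemi, rois$region), , drop = FALSE]
  if (nrow(rois) == 0L) stop("empty ROI list")
  thr <- alpha / mc_divisor
  out <- vector("list", length(codings) * nrow(rois) * length(features))
  k <- 0L
  for (r in seq_len(nrow(rois))) for (f in sort(features)) {
    nf <- normalize_feature(morph, rois$hemi[r], rois$region[r], f)
    for (cd in codings) {
      res <- fit_glm(nf$values, cd$values, pheno)
      k <- k + 1L
      out[[k]] <- cbind(data.frame(marker = cd$marker, hemi = rois$hemi[r],
                                   region = rois$region[r], feature = f,
                                   stringsAsFactors = FALSE),
                        res)
    }
  }
  res <- do.call(rbind, out[seq_len(k)])
  res$p_corrected_alpha <- thr
  res$significant_raw <- res$p < alpha
  res$significant_corrected <- res$p < thr
  res <- res[order(res$marker, res$hemi, res$region, res$feature), ]
  rownames(res) <- NULL
  class(res) <- c("glm_screen", "data.frame")
  res
}

#' Design #2 screen: SNP effects on the behavioral outcome
#'
#' One GLM per marker with the attention-problems score as outcome,
#' age + gender covariates, uncorrected alpha.
#'
#' @inheritParams screen_design1
#' @return data.frame of class `glm_screen`, one row per marker.
#' @export
screen_design2 <- function(pheno, codings, alpha = 0.05) {
  y <- pheno$ap_score
  names(y) <- pheno$subject
  out <- lapply(codings, function(cd) {
    cbind(data.frame(marker = cd$marker, stringsAsFactors = FALSE),
          fit_glm(y, cd$values, pheno))
  })
  res <- do.call(rbind, out)
  res$significant_raw <- res$p < alpha
  res <- res[order(res$marker), ]
  rownames(res) <- NULL
  class(res) <- c("glm_screen", "data.frame")
  res
}

#' Design #3 screen: morphometry effects on the behavioral outcome
#'
#' One GLM per selected normalized feature (the design-#1
#' corrected-significant hits of markers passing design #2), outcome the
#' attention-problems score, age + gender covariates, uncorrected alpha.
#'
#' @param pheno a [phenotype_table()].
#' @param selected_features list of [normalize_feature()] results.
#' @param alpha raw two-sided significance level.
#' @return data.frame of class `glm_screen`, one row per feature; empty
#'   selection yields an empty data.frame, not an error.
#' @export
screen_design3 <- function(pheno, selected_features, alpha = 0.05) {
  if (length(selected_features) == 0L) {
    res <- data.frame(hemi = character(), region = character(),
                      feature = character(), beta = numeric(),
                      t = numeric(), df = integer(), p = numeric(),
                      n_complete = integer(),
                      significant_raw = logical())
    class(res) <- c("glm_screen", "data.frame")
    return(res)
  }
  y <- pheno$ap_score
  names(y) <- pheno$subject
  out <- lapply(selected_features, function(nf) {
    cbind(data.frame(hemi = nf$hemi, region = nf$region,
                     feature = nf$feature, stringsAsFactors = FALSE),
          fit_glm(y, nf$values, pheno))
  })
  res <- do.call(rbind, out)
  res$significant_raw <- res$p < alpha
  res <- res[order(res$hemi, res$region, res$feature), ]
  rownames(res) <- NULL
  class(res) <- c("glm_screen", "data.frame")
  res
}

#' Select mediation triads from the three screening designs
#'
#' Emits one (marker, ROI-feature, outcome) triad for every combination
#' where the marker passed design #2 (raw), the (marker, ROI, feature)
#' pair passed design #1 at the corrected threshold, and the ROI feature
#' passed design #3 (raw). Duplicated result rows are an input error, not
#' silently de-duplicated.
#'
#' @param r1,r2,r3 results of [screen_design1()], [screen_design2()],
#'   [screen_design3()].
#' @return data.frame (marker, hemi, region, feature, outcome) sorted by
#'   (marker, hemi, region, feature); zero rows when no triad qualifies.
#' @export
select_triads <- function(r1, r2, r3) {
  if (anyDuplicated(r1[, c("marker", "hemi", "region", "feature")]))
    stop("duplicated (marker, hemi, region, feature) rows in design #1 results")
  if (anyDuplicated(r2$marker))
    stop("duplicated marker rows in design #2 results")
  if (nrow(r3) > 0 && anyDuplicated(r3[, c("hemi", "region", "feature")]))
    stop("duplicated ROI rows in design #3 results")
  mk2 <- r2$marker[r2$significant_raw]
  hits1 <- r1[r1$significant_corrected & r1$marker %in% mk2, ]
  if (nrow(hits1) == 0L || nrow(r3) == 0L)
    return(data.frame(marker = character(), hemi = character(),
                      region = character(), feature = character(),
                      outcome = character()))
  ok3 <- r3[r3$significant_raw, ]
  key1 <- paste(hits1$hemi, hits1$region, hits1$feature)
  key3 <- paste(ok3$hemi, ok3$region, ok3$feature)
  sel <- hits1[key1 %in% key3, c("marker", "hemi", "region", "feature")]
  sel$outcome <- "ap_score"
  sel <- sel[order(sel$marker, sel$hemi, sel$region, sel$feature), ]
  rownames(sel) <- NULL
  sel
}

#' Write a screening result table as TSV
#'
#' @param res a `glm_screen` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(res, path) {
  df <- as.data.frame(res)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 6))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
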