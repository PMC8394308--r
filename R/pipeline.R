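#' Read and validate a pipeline run configuration
#'
#' The configuration is a single YAML file with keys: `inputs` (genotypes,
#' phenotypes, globals, and per-hemisphere/feature stats tables), `alpha`,
#' `mc_divisor`, `n_resamples`, `seed`, `output_dir`, `inference`
#' (`bootstrap`, `permutation` or `both`) and optional `regions`.
#'
#' @param path path to the YAML file.
#' @return A validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(alpha = 0.05, mc_divisor = 31, n_resamples = 5000L,
                   inference = "bootstrap", regions = NULL)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$seed)) stop("config must set a seed")
  if (is.null(cfg$output_dir)) stop("config must set output_dir")
  if (is.null(cfg$inputs)) stop("config must set inputs")
  if (!cfg$inference %in% c("bootstrap", "permutation", "both"))
    stop("inference must be bootstrap, permutation or both")
  for (p in unlist(cfg$inputs))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  class(cfg) <- "run_config"
  cfg
}

# load the three tables from an inputs list (paths as in write_cohort())
.load_inputs <- function(inputs) {
  geno <- read_genotype_csv(inputs$genotypes)
  pheno <- read_phenotype_csv(inputs$phenotypes)
  globals <- read_globals(inputs$globals)
  frags <- list()
  for (nm in names(inputs)) {
    m <- regmatches(nm, regexec("^(lh|rh)_(thickness|area|volume)$", nm))[[1]]
    if (length(m) == 0L) next
    frags[[length(frags) + 1L]] <- read_stats_table(inputs[[nm]], m[3L])
  }
  if (!length(frags)) stop("no stats tables among inputs")
  morph <- morphometry_table(do.call(rbind, frags), globals)
  list(genotypes = geno, morphometry = morph, phenotypes = pheno)
}

#' Validate pipeline inputs: subject alignment, missingness, inventory
#'
#' Cross-checks the three tables: every subject must appear in all of
#' them; orphans are listed and block the run. Reports a missingness
#' census and the marker/ROI inventory.
#'
#' @param inputs named list of input paths (as in [read_run_config()]'s
#'   `inputs` key) or a list of already-loaded tables.
#' @return A list with `ok`, `errors`, `orphans`, `census`.
#' @export
validate_inputs <- function(inputs) {
  tabs <- if (!is.null(inputs$genotypes) &&
              inherits(inputs$genotypes, "genotype_table"))
    inputs else .load_inputs(inputs)
  sg <- tabs$genotypes$subjects
  sm <- unique(tabs$morphometry$values$subject)
  sp <- tabs$phenotypes$subject
  all_subj <- sort(unique(c(sg, sm, sp)))
  orphans <- data.frame(
    subject = all_subj,
    genotypes = all_subj %in% sg,
    morphometry = all_subj %in% sm,
    phenotypes = all_subj %in% sp)
  orphans <- orphans[!(orphans$genotypes & orphans$morphometry &
                         orphans$phenotypes), ]
  errors <- character()
  if (nrow(orphans) > 0L)
    errors <- c(errors, paste0("subjects missing from some table(s): ",
                               paste(orphans$subject, collapse = ", ")))
  census <- list(
    n_subjects = length(all_subj),
    n_markers = length(tabs$genotypes$markers),
    n_rois = nrow(unique(tabs$morphometry$values[, c("hemi", "region")])),
    features = sort(unique(tabs$morphometry$values$feature)),
    missing_genotype_calls = sum(is.na(tabs$genotypes$allele1)),
    missing_morphometry = sum(is.na(tabs$morphometry$values$value)),
    missing_phenotypes = sum(!stats::complete.cases(
      as.data.frame(tabs$phenotypes)[, c("ap_score", "age", "gender")])))
  list(ok = length(errors) == 0L, errors = errors, orphans = orphans,
       census = census, tables = tabs)
}

#' Run the full pipeline: QC, screening, triad selection, mediation
#'
#' Orchestrates genotype QC, the three GLM screening designs, triad
#' selection by intersection and one mediation analysis per selected
#' triad, writing all reports and a machine-readable run manifest into
#' the output directory. Runs are deterministic given the config seed.
#'
#' @param config a [read_run_config()] result, or a list with the same
#'   fields (`inputs` may also hold already-loaded tables).
#' @return The manifest list, invisibly. Files written: marker_summary.tsv,
#'   ld.tsv, screen_design1.tsv, screen_design2.tsv, screen_design3.tsv,
#'   triads.tsv, mediation_<k>.tsv/.json, manifest.json.
#' @export
run_pipeline <- function(config) {
  val <- validate_inputs(config$inputs)
  if (!val$ok)
    stop("input validation failed: ", paste(val$errors, collapse = "; "))
  tabs <- val$tables
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(f) file.path(config$output_dir, f)
  alpha <- config$alpha %||% 0.05
  mc_divisor <- config$mc_divisor %||% 31
  n_res <- config$n_resamples %||% 5000L
  inference <- config$inference %||% "bootstrap"

  summaries <- summarize_markers(tabs$genotypes)
  write_marker_summary(summaries, outp("marker_summary.tsv"))
  ld <- ld_table(tabs$genotypes)
  write_ld_table(ld, outp("ld.tsv"))

  poly <- summaries$marker[!summaries$monomorphic]
  codings <- lapply(poly, function(mk) carrier_code(tabs$genotypes, mk))
  rois <- unique(tabs$morphometry$values[, c("hemi", "region")])
  if (!is.null(config$regions))
    rois <- rois[rois$region %in% config$regions, ]
  r1 <- screen_design1(tabs$morphometry, codings, tabs$phenotypes,
                       alpha = alpha, mc_divisor = mc_divisor, rois = rois)
  r2 <- screen_design2(tabs$phenotypes, codings, alpha = alpha)
  write_screen_tsv(r1, outp("screen_design1.tsv"))
  write_screen_tsv(r2, outp("screen_design2.tsv"))

  mk2 <- r2$marker[r2$significant_raw]
  cand <- r1[r1$significant_corrected & r1$marker %in% mk2, ]
  cand_feat <- unique(cand[, c("hemi", "region", "feature")])
  selected <- lapply(seq_len(nrow(cand_feat)), function(i)
    normalize_feature(tabs$morphometry, cand_feat$hemi[i],
                      cand_feat$region[i], cand_feat$feature[i]))
  r3 <- screen_design3(tabs$phenotypes, selected, alpha = alpha)
  write_screen_tsv(r3, outp("screen_design3.tsv"))

  triads <- select_triads(r1, r2, r3)
  utils::write.table(triads, outp("triads.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  y <- tabs$phenotypes$ap_score
  names(y) <- tabs$phenotypes$subject
  mediations <- list()
  if (nrow(triads) == 0L) {
    message("no triads selected; mediation stage skipped")
  } else {
    for (k in seq_len(nrow(triads))) {
      tri <- triads[k, ]
      cc <- codings[[match(tri$marker, poly)]]
      nf <- normalize_feature(tabs$morphometry, tri$hemi, tri$region,
                              tri$feature)
      res <- mediate(cc$values, nf$values, y, tabs$phenotypes,
                     n_resamples = n_res, seed = config$seed,
                     alpha = alpha,
                     permutation = inference %in% c("permutation", "both"))
      write_mediation_tsv(res, outp(sprintf("mediation_%d.tsv", k)))
      mediations[[k]] <- res
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("neuromediate")),
    seed = config$seed, alpha = alpha, mc_divisor = mc_divisor,
    n_resamples = n_res, inference = inference,
    census = val$census,
    n_models_design1 = nrow(r1), n_models_design2 = nrow(r2),
    n_models_design3 = nrow(r3), n_triads = nrow(triads),
    n_mediations = length(mediations),
    corrected_threshold = alpha / mc_divisor)
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, screens = list(r1 = r1, r2 = r2,
                                                     r3 = r3),
                 triads = triads, mediations = mediations))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
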