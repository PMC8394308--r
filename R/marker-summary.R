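#' Summarise a marker: allele frequencies and Hardy-Weinberg equilibrium
#'
#' Computes major/minor allele labels and frequencies over called alleles
#' and a Hardy-Weinberg p-value from the genotype counts. At a frequency
#' tie (MAF = 0.5) the lexicographically smaller label is taken as minor,
#' so the coding is deterministic.
#'
#' @param table a [genotype_table()].
#' @param marker marker name.
#' @param hwe_method `"exact"` (default) or `"chisq"`, see [hwe_test()].
#' @return A list with `marker`, `major_allele`, `minor_allele`, `maf`,
#'   `hwe_p`, `n_called`, `n_missing`, `monomorphic`.
#' @export
summarize_marker <- function(table, marker, hwe_method = c("exact", "chisq")) {
  hwe_method <- match.arg(hwe_method)
  calls <- .marker_calls(table, marker)
  ok <- !is.na(calls$a1)
  if (!any(ok)) stop("marker ", marker, " has no non-missing calls")
  a1 <- calls$a1[ok]; a2 <- calls$a2[ok]
  freq <- sort(base::table(c(a1, a2)) / (2 * sum(ok)))
  if (length(freq) == 1L) {
    return(list(marker = marker, major_allele = names(freq),
                minor_allele = NA_character_, maf = 0.0, hwe_p = 1.0,
                n_called = sum(ok), n_missing = sum(!ok),
                monomorphic = TRUE))
  }
  labs <- names(freq)
  if (freq[1] == freq[2]) labs <- sort(labs)           # tie: lexicographic
  minor <- labs[1]; major <- labs[2]
  if (freq[[minor]] > freq[[major]]) { tmp <- minor; minor <- major; major <- tmp }
  n_min_hom <- sum(a1 == minor & a2 == minor)
  n_het <- sum((a1 == minor) != (a2 == minor))
  n_maj_hom <- sum(a1 == major & a2 == major)
  list(marker = marker, major_allele = major, minor_allele = minor,
       maf = unname(freq[[minor]]),
       hwe_p = hwe_test(n_maj_hom, n_het, n_min_hom, method = hwe_method),
       n_called = sum(ok), n_missing = sum(!ok), monomorphic = FALSE)
}

#' Summarise all markers of a genotype table
#'
#' @inheritParams summarize_marker
#' @return A data.frame with one row per marker: marker, major/minor
#'   alleles, maf, hwe_p, n_called, n_missing, monomorphic.
#' @export
summarize_markers <- function(table, hwe_method = c("exact", "chisq")) {
  hwe_method <- match.arg(hwe_method)
  rows <- lapply(table$markers, function(m)
    as.data.frame(summarize_marker(table, m, hwe_method),
                  stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Minor-allele-carrier (dominant) coding
#'
#' Collapses genotypes at a marker into a two-level variable: 1 when the
#' subject carries at least one minor allele (heterozygote or minor
#' homozygote), 0 when homozygous for the major allele. Missing calls
#' propagate as `NA`.
#'
#' @param table a [genotype_table()].
#' @param marker marker name.
#' @return A list with `marker`, `minor_allele`, `values` (named 0/1/NA
#'   vector over subjects), `n_carriers`.
#' @export
carrier_code <- function(table, marker) {
  s <- summarize_marker(table, marker)
  if (s$monomorphic)
    stop("marker ", marker, " is monomorphic; carrier coding undefined")
  calls <- .marker_calls(table, marker)
  v <- ifelse(is.na(calls$a1), NA_real_,
              as.numeric(calls$a1 == s$minor_allele |
                           calls$a2 == s$minor_allele))
  names(v) <- table$subjects
  list(marker = marker, minor_allele = s$minor_allele, values = v,
       n_carriers = sum(v, na.rm = TRUE))
}

#' Pairwise LD table for all polymorphic marker pairs
#'
#' @param table a [genotype_table()].
#' @return A data.frame (markerA, markerB, r2, n) over unordered pairs.
#' @export
ld_table <- function(table) {
  mk <- table$markers
  out <- list()
  k <- 0L
  for (i in seq_along(mk)) for (j in seq_along(mk)) {
    if (j <= i) next
    res <- ld_r2(table, mk[i], mk[j])
    k <- k + 1L
    out[[k]] <- data.frame(markerA = mk[i], markerB = mk[j],
                           r2 = res$r2, n = res$n,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write the marker-summary TSV (marker, allele, frequency, HWE p)
#'
#' One row per allele, mirroring the usual allele-frequency report layout;
#' the Hardy-Weinberg p-value is printed on the major-allele row.
#'
#' @param summaries data.frame from [summarize_markers()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_marker_summary <- function(summaries, path) {
  rows <- list()
  for (i in seq_len(nrow(summaries))) {
    s <- summaries[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      marker = s$marker, allele = s$major_allele,
      frequency = round(1 - s$maf, 4), hwe_p = signif(s$hwe_p, 4),
      stringsAsFactors = FALSE)
    if (!s$monomorphic)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = s$marker, allele = s$minor_allele,
        frequency = round(s$maf, 4), hwe_p = NA_real_,
        stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the pairwise LD TSV (markerA, markerB, r2, n)
#'
#' @param ld data.frame from [ld_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_table <- function(ld, path) {
  ld$r2 <- signif(ld$r2, 6)
  utils::write.table(ld, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
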