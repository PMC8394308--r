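#' Desikan-Killiany cortical region tokens
#'
#' The 34 gyral-based regions per hemisphere of the Desikan-Killiany
#' parcellation, in FreeSurfer's lower-case token form.
#'
#' @return Character vector of 34 region tokens.
#' @export
dk_regions <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
    "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal",
    "lingual", "medialorbitofrontal", "middletemporal", "parahippocampal",
    "paracentral", "parsopercularis", "parsorbitalis", "parstriangularis",
    "pericalcarine", "postcentral", "posteriorcingulate", "precentral",
    "precuneus", "rostralanteriorcingulate", "rostralmiddlefrontal",
    "superiorfrontal", "superiorparietal", "superiortemporal",
    "supramarginal", "temporalpole", "transversetemporal", "frontalpole",
    "insula")
}

#' Default 31-region analysis list
#'
#' A 31-per-hemisphere subset of the Desikan-Killiany regions used as the
#' default screening atlas. Which three regions to drop from the full
#' 34-region parcellation is an analysis choice; the default removes the
#' banks of the superior temporal sulcus and the frontal and temporal
#' poles (the smallest and least reliably measured parcels), and callers
#' can pass any region list instead.
#'
#' @return Character vector of 31 region tokens.
#' @export
dk_regions_31 <- function() {
  setdiff(dk_regions(), c("bankssts", "frontalpole", "temporalpole"))
}

#' Translate prose region names to FreeSurfer tokens
#'
#' Maps report-style names ("isthmus cingulate", "caudal ACC", "rostral
#' middle frontal", ...) onto the canonical lower-case region tokens.
#'
#' @param x character vector of prose names.
#' @return Character vector of region tokens; unknown names yield `NA`.
#' @export
roi_name_to_token <- function(x) {
  key <- gsub("[^a-z]", "", tolower(x))
  map <- c(caudalacc = "caudalanteriorcingulate",
           rostralacc = "rostralanteriorcingulate",
           isthmusofcingulatecortex = "isthmuscingulate",
           isthmusofthecingulatecortex = "isthmuscingulate",
           lateralorbitofrontalcortex = "lateralorbitofrontal",
           transversetemporalgyrus = "transversetemporal",
           inferiorparietalgyrus = "inferiorparietal",
           rostralmiddlefrontalgyrus = "rostralmiddlefrontal",
           middletemporalcortex = "middletemporal")
  out <- ifelse(key %in% names(map), unname(map[key]),
                ifelse(key %in% dk_regions(), key, NA_character_))
  unname(out)
}

#' Morphometry table
#'
#' Long-format container for region-of-interest morphometry: one row per
#' (subject, hemisphere, region, feature) with strictly positive values
#' (or `NA` for flagged-missing measures), plus per-subject global
#' normalizers (total intracranial volume in mm^3 and total cortical
#' surface area in mm^2).
#'
#' @param values data.frame with columns subject, hemi (`"lh"`/`"rh"`),
#'   region, feature (`"thickness"`/`"area"`/`"volume"`), value.
#' @param globals data.frame with columns subject, icv, total_sa.
#' @return An object of class `morphometry_table`.
#' @export
morphometry_table <- function(values, globals) {
  need <- c("subject", "hemi", "region", "feature", "value")
  if (!all(need %in% names(values)))
    stop("values must have columns: ", paste(need, collapse = ", "))
  if (!all(c("subject", "icv", "total_sa") %in% names(globals)))
    stop("globals must have columns subject, icv, total_sa")
  if (anyDuplicated(globals$subject))
    stop("duplicate subject in globals")
  bad <- !is.na(values$value) & values$value <= 0
  if (any(bad))
    stop("non-positive morphometry values for subject(s): ",
         paste(unique(values$subject[bad]), collapse = ", "))
  if (any(globals$icv <= 0) || any(globals$total_sa <= 0))
    stop("globals must be strictly positive")
  key <- paste(values$subject, values$hemi, values$region, values$feature)
  if (anyDuplicated(key))
    stop("duplicate (subject, hemi, region, feature) rows")
  structure(list(values = values, globals = globals),
            class = "morphometry_table")
}

#' @export
print.morphometry_table <- function(x, ...) {
  cat("morphometry_table:", length(unique(x$values$subject)), "subjects,",
      length(unique(paste(x$values$hemi, x$values$region))), "ROIs,",
      length(unique(x$values$feature)), "features;",
      sum(is.na(x$values$value)), "missing values\n")
  invisible(x)
}

#' Read a FreeSurfer-style stats table
#'
#' Parses the tab-separated layout written by FreeSurfer's
#' `aparcstats2table`: first column the subject identifier, remaining
#' columns named `<lh|rh>_<region>_<feature>`. Columns that do not match a
#' known region token are reported via a warning and skipped, not fatal.
#'
#' @param path path to the TSV file.
#' @param feature expected feature (`"thickness"`, `"area"`, `"volume"`);
#'   columns carrying a different feature suffix are rejected.
#' @return A long data.frame fragment (subject, hemi, region, feature,
#'   value) suitable for [morphometry_table()].
#' @export
read_stats_table <- function(path, feature = c("thickness", "area", "volume")) {
  feature <- match.arg(feature)
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("stats table needs a subject column plus measures")
  subj <- df[[1L]]
  if (anyDuplicated(subj))
    stop("duplicate subject in ", path, ": ",
         paste(unique(subj[duplicated(subj)]), collapse = ", "))
  out <- list()
  unknown <- character()
  for (col in names(df)[-1L]) {
    m <- regmatches(col, regexec("^(lh|rh)_([a-z]+)_([a-z]+)$", col))[[1L]]
    if (length(m) == 0L || !(m[3L] %in% dk_regions()) || m[4L] != feature) {
      unknown <- c(unknown, col)
      next
    }
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(val))
    if (length(bad))
      stop("non-numeric cell in ", path, " at row ", bad[1L],
           ", column ", col, ": '", raw[bad[1L]], "'")
    val[raw == ""] <- NA_real_
    out[[length(out) + 1L]] <- data.frame(
      subject = subj, hemi = m[2L], region = m[3L], feature = feature,
      value = val, stringsAsFactors = FALSE)
  }
  if (length(unknown))
    warning("skipping unrecognised columns: ", paste(unknown, collapse = ", "))
  if (!length(out)) stop("no recognised measure columns in ", path)
  do.call(rbind, out)
}

#' Read the per-subject globals TSV (subject, icv, total_sa)
#'
#' @param path path to the TSV.
#' @return data.frame with columns subject, icv, total_sa.
#' @export
read_globals <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "numeric",
                                               "numeric"))
  if (!all(c("subject", "icv", "total_sa") %in% names(df)))
    stop("globals TSV must have columns subject, icv, total_sa")
  df
}

#' Write a morphometry fragment back to the stats-table layout
#'
#' Inverse of [read_stats_table()] for a single feature: one column per
#' (hemi, region), `%.10g`-formatted values, so read-write-read round
#' trips are exact.
#'
#' @param fragment long data.frame as returned by [read_stats_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_table <- function(fragment, path) {
  feature <- unique(fragment$feature)
  if (length(feature) != 1L) stop("fragment must hold a single feature")
  subj <- unique(fragment$subject)
  cols <- unique(fragment[, c("hemi", "region")])
  cols <- cols[order(cols$hemi, cols$region), ]
  wide <- data.frame(subject = subj, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(cols))) {
    nm <- paste(cols$hemi[k], cols$region[k], feature, sep = "_")
    sel <- fragment$hemi == cols$hemi[k] & fragment$region == cols$region[k]
    v <- fragment$value[sel][match(subj, fragment$subject[sel])]
    wide[[nm]] <- ifelse(is.na(v), "", sprintf("%.10g", v))
  }
  utils::write.table(wide, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize a regional feature by its global factor
#'
#' Gray-matter volume is divided by total intracranial volume and surface
#' area by total cortical surface area; cortical thickness passes through
#' unchanged.
#'
#' @param table a [morphometry_table()].
#' @param hemi `"lh"` or `"rh"`.
#' @param region region token.
#' @param feature `"thickness"`, `"area"` or `"volume"`.
#' @return A list with `hemi`, `region`, `feature`, `values` (named
#'   per-subject vector, normalized where applicable) and `normalizer`
#'   (`"icv"`, `"total_sa"` or `"none"`).
#' @export
normalize_feature <- function(table, hemi, region,
                              feature = c("thickness", "area", "volume")) {
  feature <- match.arg(feature)
  sel <- table$values$hemi == hemi & table$values$region == region &
    table$values$feature == feature
  if (!any(sel)) stop("no values for ", hemi, " ", region, " ", feature)
  sub <- table$values[sel, ]
  v <- sub$value
  names(v) <- sub$subject
  normalizer <- "none"
  if (feature %in% c("volume", "area")) {
    gcol <- if (feature == "volume") "icv" else "total_sa"
    normalizer <- gcol
    g <- table$globals[[gcol]][match(sub$subject, table$globals$subject)]
    if (anyNA(g[!is.na(v)]))
      stop("missing global ", gcol, " for subject(s): ",
           paste(sub$subject[is.na(g) & !is.na(v)], collapse = ", "))
    if (any(g[!is.na(v)] <= 0))
      stop("non-positive global ", gcol, " for subject(s): ",
           paste(sub$subject[!is.na(v) & g <= 0], collapse = ", "))
    v <- v / g
  }
  list(hemi = hemi, region = region, feature = feature, values = v,
       normalizer = normalizer)
}

#' Write the tidy per-measure TSV (subject, hemi, region, feature, raw,
#' normalized)
#'
#' @param table a [morphometry_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_morphometry_tidy <- function(table, path) {
  df <- table$values
  norm <- numeric(nrow(df))
  g_icv <- table$globals$icv[match(df$subject, table$globals$subject)]
  g_sa <- table$globals$total_sa[match(df$subject, table$globals$subject)]
  norm <- ifelse(df$feature == "volume", df$value / g_icv,
                 ifelse(df$feature == "area", df$value / g_sa, df$value))
  df$raw <- df$value
  df$normalized <- norm
  df$value <- NULL
  df <- df[order(df$subject, df$hemi, df$region, df$feature), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
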