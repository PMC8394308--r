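#' Genotype table
#'
#' Container for biallelic genotype calls: for each subject and marker an
#' unordered pair of allele labels, or a missing call. Allele labels are
#' opaque strings, so deletion alleles such as `"-"` are handled like any
#' other label.
#'
#' @param subjects character vector of unique subject identifiers.
#' @param markers character vector of unique marker names.
#' @param allele1,allele2 character matrices (`subjects x markers`) holding
#'   the two allele labels of each call; `NA` in both marks a missing call.
#'
#' @return An object of class `genotype_table` with elements `subjects`,
#'   `markers`, `allele1`, `allele2`.
#' @export
genotype_table <- function(subjects, markers, allele1, allele2) {
  subjects <- as.character(subjects)
  markers <- as.character(markers)
  if (anyDuplicated(subjects))
    stop("duplicate subject identifiers: ",
         paste(unique(subjects[duplicated(subjects)]), collapse = ", "))
  if (anyDuplicated(markers))
    stop("duplicate marker names: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  a1 <- as.matrix(allele1); a2 <- as.matrix(allele2)
  storage.mode(a1) <- "character"; storage.mode(a2) <- "character"
  if (!all(dim(a1) == c(length(subjects), length(markers))) ||
      !all(dim(a2) == c(length(subjects), length(markers))))
    stop("allele matrices must be subjects x markers")
  # a half-missing call is invalid, not silently completed
  half <- xor(is.na(a1), is.na(a2))
  if (any(half))
    stop("half-missing calls (one allele recorded) at ",
         sum(half), " entries")
  dimnames(a1) <- dimnames(a2) <- list(subjects, markers)
  for (j in seq_along(markers)) {
    al <- unique(stats::na.omit(c(a1[, j], a2[, j])))
    if (length(al) > 2L)
      stop("marker ", markers[j], " has more than 2 allele labels: ",
           paste(al, collapse = ", "))
  }
  structure(list(subjects = subjects, markers = markers,
                 allele1 = a1, allele2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  miss <- sum(is.na(x$allele1))
  cat("genotype_table:", length(x$subjects), "subjects x",
      length(x$markers), "markers;", miss, "missing calls\n")
  invisible(x)
}

#' Read genotypes from a long-format CSV
#'
#' Expects the header `subject,marker,allele1,allele2`; empty allele fields
#' denote a missing call. Every subject x marker pair may appear at most
#' once; pairs absent from the file are recorded as missing.
#'
#' @param path path to the CSV file.
#' @return A [genotype_table()].
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("subject", "marker", "allele1", "allele2")
  if (!all(need %in% names(df)))
    stop("genotype CSV must have columns: ", paste(need, collapse = ", "))
  df$allele1[df$allele1 == ""] <- NA_character_
  df$allele2[df$allele2 == ""] <- NA_character_
  subjects <- unique(df$subject)
  markers <- unique(df$marker)
  key <- paste(df$subject, df$marker, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject, marker) rows in ", path)
  a1 <- matrix(NA_character_, length(subjects), length(markers),
               dimnames = list(subjects, markers))
  a2 <- a1
  i <- match(df$subject, subjects)
  j <- match(df$marker, markers)
  a1[cbind(i, j)] <- df$allele1
  a2[cbind(i, j)] <- df$allele2
  genotype_table(subjects, markers, a1, a2)
}

#' Write genotypes to the long-format CSV dialect
#'
#' @param x a [genotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(x, path) {
  stopifnot(inherits(x, "genotype_table"))
  grid <- expand.grid(subject = x$subjects, marker = x$markers,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- cbind(match(grid$subject, x$subjects), match(grid$marker, x$markers))
  grid$allele1 <- x$allele1[idx]
  grid$allele2 <- x$allele2[idx]
  grid$allele1[is.na(grid$allele1)] <- ""
  grid$allele2[is.na(grid$allele2)] <- ""
  grid <- grid[order(grid$subject, grid$marker), ]
  utils::write.csv(grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file (minimal biallelic reader)
#'
#' Reads biallelic SNP/indel records from a VCF v4.2 file using the GT
#' field only; `./.` and `.` genotypes become missing calls. Requires the
#' `vcfR` package.
#'
#' @param path path to a plain-text or gzipped VCF.
#' @return A [genotype_table()] with markers named by the ID column (or
#'   `chrom:pos` when ID is `.`).
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_genotype_vcf() requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt)
  if (!any(keep)) stop("no biallelic records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  ref <- fix[keep, "REF"]
  alt <- alt[keep]
  ids <- fix[keep, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[keep, "CHROM"][noid], ":", fix[keep, "POS"][noid])
  subjects <- colnames(gt)
  nm <- length(ids)
  a1 <- matrix(NA_character_, length(subjects), nm,
               dimnames = list(subjects, ids))
  a2 <- a1
  for (r in seq_len(nm)) {
    al <- c(ref[r], alt[r])
    g <- gt[r, ]
    parts <- strsplit(g, "[/|]")
    for (s in seq_along(subjects)) {
      p <- parts[[s]]
      if (length(p) != 2L || any(p == ".") || anyNA(p)) next
      a1[s, r] <- al[as.integer(p[1]) + 1L]
      a2[s, r] <- al[as.integer(p[2]) + 1L]
    }
  }
  genotype_table(subjects, ids, a1, a2)
}

# genotype at one marker as a 3-row count plus per-subject allele pairs
.marker_calls <- function(table, marker) {
  if (!marker %in% table$markers)
    stop("unknown marker: ", marker)
  j <- match(marker, table$markers)
  data.frame(subject = table$subjects,
             a1 = table$allele1[, j], a2 = table$allele2[, j],
             stringsAsFactors = FALSE)
}
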