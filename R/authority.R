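# Authority normalization, pairwise pre-adjustments, and the blended
# dual-form (diacritics retained / diacritics folded) similarity score.

#' Default author-abbreviation table
#'
#' A small built-in dictionary of common author abbreviations and their
#' expansions, applied during authority normalization. Replace or extend it
#' with [read_abbrev_table()].
#'
#' @return Named character vector: names are abbreviations (with trailing
#'   period), values the expanded surnames.
#' @export
default_abbrev_table <- function() {
  c("L."      = "Linnaeus",
    "Linn."   = "Linnaeus",
    "DC."     = "de Candolle",
    "Lam."    = "Lamarck",
    "Benth."  = "Bentham",
    "Hook."   = "Hooker",
    "Hook.f." = "Hooker f.",
    "Baill."  = "Baillon",
    "Boiss."  = "Boissier",
    "Sm."     = "Smith",
    "R.Br."   = "Brown",
    "Ag."     = "Agardh")
}

#' Read an author-abbreviation table from a delimited file
#'
#' Expects two columns (abbreviation, expansion), TSV or CSV, with or
#' without a header line named `abbreviation`/`expansion`. Keys must be
#' unique after case-folding.
#'
#' @param path Path to the file.
#' @return Named character vector usable as `abbrevs` argument elsewhere.
#' @export
read_abbrev_table <- function(path) {
  dt <- data.table::fread(path, header = "auto", sep = "auto",
                          colClasses = "character")
  if (ncol(dt) < 2L) stop("abbreviation table needs two columns")
  ab <- as.character(dt[[1]])
  ex <- as.character(dt[[2]])
  if (anyDuplicated(tolower(ab)))
    stop("duplicate abbreviation keys after case-folding")
  stats::setNames(ex, ab)
}

expand_abbrevs <- function(s, abbrevs) {
  if (!length(abbrevs)) return(s)
  toks <- strsplit(s, " ", fixed = TRUE)[[1]]
  # whole tokens ending in "." only, so surnames are never mangled
  idx <- match(tolower(toks), tolower(names(abbrevs)))
  hit <- !is.na(idx) & endsWith(toks, ".")
  toks[hit] <- abbrevs[idx[hit]]
  paste(toks, collapse = " ")
}

#' Normalize an authority string
#'
#' Applies the authority-specific pre-processing: `" et "`/`" and "` become
#' `" & "` (the phrase `"et al."` is preserved), the `&amp;` entity becomes
#' an ampersand, whitespace between author initials is removed
#' (`"F. J. R. Taylor"` to `"F.J.R. Taylor"`), a comma is inserted before a
#' trailing 4-digit year when absent, recognised abbreviations are
#' expanded, and the string is uppercased. Two forms are returned: the
#' original (diacritics retained) and a plain form with diacritics and
#' ligatures folded to ASCII.
#'
#' @param s Authority string.
#' @param abbrevs Named character vector of abbreviation expansions.
#' @return List with elements `original_norm` and `plain_norm`.
#' @export
normalize_authority <- function(s, abbrevs = default_abbrev_table()) {
  if (!nzchar(s)) stop("normalize_authority: empty string")
  x <- gsub("&amp;", "&", s, fixed = TRUE)
  x <- gsub("\\s+", " ", trimws(x))
  # protect "et al." before the et/and -> & rule
  x <- gsub("\\bet al\\.", "\001ETAL\001", x)
  x <- gsub(" (et|and) ", " & ", x)
  x <- gsub("\001ETAL\001", "et al.", x, fixed = TRUE)
  # collapse whitespace between successive single-letter initials
  repeat {
    x2 <- gsub("(\\b[A-ZÀ-ž]\\.) (?=[A-ZÀ-ž]\\.)", "\\1", x, perl = TRUE)
    if (identical(x2, x)) break
    x <- x2
  }
  # expand abbreviations before the comma rule so "L. 1758" becomes
  # "Linnaeus, 1758" rather than leaving the abbreviation token untouched
  x <- expand_abbrevs(x, abbrevs)
  # comma before a trailing year when absent
  x <- gsub("([^,]) (\\(?[0-9]{4}\\)?)$", "\\1, \\2", x)
  x <- toupper(x)
  plain <- fold_ascii(x, warn = FALSE)
  list(original_norm = x, plain_norm = plain)
}

.year_re <- "(1[5-9][0-9]{2}|20[0-9]{2})\\)?$"

#' Pairwise pre-adjustment of two normalized authority strings
#'
#' Two independent rules that soften asymmetric formatting before the
#' n-gram comparison: (1) if exactly one string ends with a 4-digit year
#' (optionally followed by a closing bracket), the last 3 digits of that
#' year are removed, so `"LINNAEUS, 1758"` compared with `"LINNAEUS"`
#' becomes `"LINNAEUS, 1"`; (2) if exactly one string starts with an
#' opening bracket, that bracket is removed. When both or neither string
#' carry the feature, nothing changes.
#'
#' @param a,b Normalized authority strings.
#' @return Character vector of length 2 with the adjusted strings.
#' @export
pair_adjust <- function(a, b) {
  ya <- grepl(.year_re, a)
  yb <- grepl(.year_re, b)
  trim_year <- function(s) sub("([0-9])[0-9]{3}(\\)?)$", "\\1\\2", s)
  if (ya && !yb) a <- trim_year(a)
  if (yb && !ya) b <- trim_year(b)
  ba <- startsWith(a, "(")
  bb <- startsWith(b, "(")
  if (ba && !bb) a <- sub("^\\(", "", a)
  if (bb && !ba) b <- sub("^\\(", "", b)
  c(a, b)
}

#' Authority similarity score
#'
#' Normalizes both authority strings, applies the pairwise adjustments, and
#' computes the blended bigram/trigram similarity twice -- once on the
#' original (diacritics retained) forms and once on the plain ASCII forms
#' -- returning the mean of the two values (a single computation when the
#' forms coincide). A missing authority on either side yields `NA`, never
#' 0, so "no authority supplied" is distinguishable from "dissimilar".
#'
#' @param a,b Authority strings (raw).
#' @param abbrevs Abbreviation table, see [default_abbrev_table()].
#' @return Similarity in \[0, 1\], or `NA_real_` when either side is
#'   missing/empty.
#' @examples
#' authority_similarity("Linnaeus, 1758", "Linnaeus")
#' @export
authority_similarity <- function(a, b, abbrevs = default_abbrev_table()) {
  if (is.null(a) || is.null(b) || is.na(a) || is.na(b) ||
      !nzchar(a) || !nzchar(b)) {
    return(NA_real_)
  }
  na_ <- normalize_authority(a, abbrevs)
  nb_ <- normalize_authority(b, abbrevs)
  orig <- pair_adjust(na_$original_norm, nb_$original_norm)
  plain <- pair_adjust(na_$plain_norm, nb_$plain_norm)
  s_orig <- blended_similarity(orig[1], orig[2])
  if (identical(orig, plain)) return(s_orig)
  s_plain <- blended_similarity(plain[1], plain[2])
  mean(c(s_orig, s_plain))
}
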