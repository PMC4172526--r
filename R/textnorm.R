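# Step-0 pre-processing: markup stripping, name parsing, word normalization.

# Rank markers recognised between a species epithet and an infraspecific
# epithet. "sp."/"spp."/"cf."/"aff."/"?" are qualifiers, not ranks.
RANK_MARKERS <- c("subsp.", "ssp.", "var.", "subvar.", "f.", "forma", "subf.")
QUALIFIERS <- c("sp.", "spp.", "cf.", "aff.", "?")

# Explicit diacritic / ligature folding table (Latin-1 + common Latin-2
# letters). Applied after uppercasing, so only uppercase keys are needed.
.fold_map <- c(
  "À" = "A", "Á" = "A", "Â" = "A", "Ã" = "A",
  "Ä" = "A", "Å" = "A", "Ā" = "A", "Ă" = "A",
  "Ą" = "A",
  "Æ" = "AE", "Œ" = "OE", "ẞ" = "SS", "ß" = "SS",
  "Ç" = "C", "Ć" = "C", "Č" = "C",
  "Ď" = "D", "Đ" = "D", "Ð" = "D",
  "È" = "E", "É" = "E", "Ê" = "E", "Ë" = "E",
  "Ē" = "E", "Ę" = "E", "Ě" = "E",
  "Ğ" = "G",
  "Ì" = "I", "Í" = "I", "Î" = "I", "Ï" = "I",
  "Ī" = "I", "İ" = "I",
  "Ĺ" = "L", "Ł" = "L",
  "Ñ" = "N", "Ń" = "N", "Ň" = "N",
  "Ò" = "O", "Ó" = "O", "Ô" = "O", "Õ" = "O",
  "Ö" = "O", "Ø" = "O", "Ō" = "O", "Ő" = "O",
  "Ŕ" = "R", "Ř" = "R",
  "Ś" = "S", "Ş" = "S", "Š" = "S",
  "Ť" = "T",
  "Ù" = "U", "Ú" = "U", "Û" = "U", "Ü" = "U",
  "Ū" = "U", "Ů" = "U", "Ű" = "U",
  "Ý" = "Y", "Ÿ" = "Y",
  "Ź" = "Z", "Ż" = "Z", "Ž" = "Z",
  "Þ" = "TH"
)

fold_ascii <- function(x, warn = TRUE) {
  out <- vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    idx <- match(chars, names(.fold_map))
    chars[!is.na(idx)] <- .fold_map[idx[!is.na(idx)]]
    s2 <- paste(chars, collapse = "")
    bad <- grepl("[^\x01-\x7F]", s2)
    if (bad) {
      if (warn) warning("dropping unmapped non-ASCII characters in '", s, "'")
      s2 <- gsub("[^\x01-\x7F]", "", s2)
    }
    s2
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Strip stray markup from a raw name string
#'
#' Removes HTML tags such as `<i>`/`</i>`, replaces the `&amp;` entity with an
#' ampersand, and collapses runs of whitespace. Identity on clean input.
#'
#' @param raw Character vector of raw name strings.
#' @return Character vector of the same length.
#' @examples
#' strip_markup("<i>Fagus</i> sylvatica")
#' @export
strip_markup <- function(raw) {
  x <- gsub("<[^<>]*>", " ", raw)
  x <- gsub("&amp;", "&", x, fixed = TRUE)
  x <- gsub("&nbsp;", " ", x, fixed = TRUE)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Normalize a scientific-name word
#'
#' Uppercases, removes hyphens and all whitespace, and folds accented letters
#' and ligatures to plain ASCII (e.g. \enc{é}{e} to E, \enc{æ}{ae} to AE).
#' Unmapped non-ASCII letters are dropped with a warning. The result contains
#' only the letters A-Z; a word that reduces to the empty string is an error.
#'
#' Idempotent: `normalize_word(normalize_word(w)) == normalize_word(w)`.
#'
#' @param word Character vector of words (genus names, epithets).
#' @return Character vector of normalized words.
#' @examples
#' normalize_word("Lacépède")  # "LACEPEDE"
#' @export
normalize_word <- function(word) {
  if (any(!nzchar(word) | is.na(word)))
    stop("normalize_word: empty or NA input")
  x <- toupper(word)
  x <- gsub("[-­]", "", x)
  x <- gsub("\\s+", "", x)
  x <- fold_ascii(x)
  x <- gsub("[^A-Z]", "", x)
  if (any(!nzchar(x)))
    stop("normalize_word: word reduced to empty string after normalization")
  x
}

latinate_cap <- function(tok) grepl("^[A-ZÀ-ž][a-zß-ž-]+$", tok)
latinate_lower <- function(tok) grepl("^[a-zß-ž][a-zß-ž-]*$", tok)

parse_failure <- function(raw, reason) {
  structure(list(raw = raw, reason = reason), class = "taxmatch_parse_failure")
}

#' @export
print.taxmatch_parse_failure <- function(x, ...) {
  cat("<parse failure> ", x$reason, ": '", x$raw, "'\n", sep = "")
  invisible(x)
}

#' Test for a parse failure
#' @param x Object returned by [parse_name()].
#' @return Logical scalar.
#' @export
is_parse_failure <- function(x) inherits(x, "taxmatch_parse_failure")

#' Split a hybrid formula into its parent names
#'
#' A hybrid formula such as `"Oenothera biennis L. x O. villosa Thunb."`
#' designates a cross between two parents, each of which is an independently
#' parseable name. The formula is split on a hybrid sign (`×` or a
#' standalone `x`) that separates two name elements; each part is matched
#' separately by the engine. A hybrid sign prefixed to a single word (hybrid
#' genus or epithet marker) does not split.
#'
#' @param raw A single raw name string.
#' @return Character vector of one or more name strings.
#' @export
split_hybrid_formula <- function(raw) {
  x <- strip_markup(raw)
  parts <- strsplit(x, "\\s+(×|x)\\s+", perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Parse a raw scientific-name string into its components
#'
#' Positional parser for latinized names: the first capitalized latinate word
#' is the genus; a parenthesized capitalized word between genus and epithet is
#' a subgenus; the following lowercase word is the specific epithet; a
#' recognised rank marker (`subsp.`, `ssp.`, `var.`, `subvar.`, `f.`,
#' `forma`, `subf.`) plus the next word form the infraspecific pair; all
#' remaining trailing text is the authority. Hybrid signs (`×` or a
#' standalone `x` before a word) are removed and recorded as flags; qualifier
#' tokens (`sp.`, `spp.`, `cf.`, `aff.`, `?`) are removed and recorded.
#'
#' @param raw A single raw name string.
#' @return An object of class `parsed_name` (a list with fields `genus_raw`,
#'   `subgenus_raw`, `epithet_raw`, `infra_rank_marker`, `infra_epithet_raw`,
#'   `authority_raw`, `hybrid_genus`, `hybrid_epithet`, `qualifiers`,
#'   `residue`), or a `taxmatch_parse_failure` carrying the raw string when
#'   the input is empty or no genus can be identified.
#' @examples
#' parse_name("Fagus sylvatica L.")
#' @export
parse_name <- function(raw) {
  if (length(raw) != 1L || is.na(raw)) return(parse_failure(as.character(raw)[1], "not a single string"))
  x <- strip_markup(raw)
  if (!nzchar(x)) return(parse_failure(raw, "empty after markup stripping"))

  toks <- strsplit(x, " ", fixed = TRUE)[[1]]

  qualifiers <- character(0)
  keep <- rep(TRUE, length(toks))
  for (i in seq_along(toks)) {
    if (toks[i] %in% QUALIFIERS) {
      qualifiers <- c(qualifiers, toks[i])
      keep[i] <- FALSE
    }
  }
  toks <- toks[keep]
  if (!length(toks)) return(parse_failure(raw, "only qualifier tokens"))

  hybrid_genus <- FALSE
  hybrid_epithet <- FALSE

  # standalone hybrid sign marks the following word
  hyb_standalone <- toks %in% c("×", "x")
  # a leading standalone marker flags the genus; one before a lowercase word
  # flags that epithet. Mark positions, then drop the sign tokens.
  flag_next <- logical(length(toks))
  if (any(hyb_standalone)) {
    idx <- which(hyb_standalone)
    for (i in idx) if (i < length(toks)) flag_next[i + 1L] <- TRUE
    toks <- toks[!hyb_standalone]
    flag_next <- flag_next[!hyb_standalone]
  }

  # attached hybrid sign
  attached <- startsWith(toks, "×")
  toks[attached] <- sub("^×", "", toks[attached])
  flag_next <- flag_next | attached
  toks <- toks[nzchar(toks)]
  flag_next <- flag_next[seq_along(toks)]

  if (!latinate_cap(toks[1]) && !grepl("^[A-ZÀ-ž][a-zß-ž-]*$", toks[1]))
    return(parse_failure(raw, "no capitalized latinate genus word"))

  genus <- toks[1]
  if (isTRUE(flag_next[1])) hybrid_genus <- TRUE
  pos <- 2L

  subgenus <- NULL
  epithet <- NULL
  infra_rank <- NULL
  infra_epithet <- NULL

  # subgenus: "(Xxx)" directly after genus
  if (pos <= length(toks) && grepl("^\\([A-ZÀ-ž][a-zß-ž-]+\\)$", toks[pos])) {
    nxt <- if (pos + 1L <= length(toks)) toks[pos + 1L] else ""
    if (latinate_lower(nxt)) {
      subgenus <- sub("^\\((.*)\\)$", "\\1", toks[pos])
      pos <- pos + 1L
    }
  }

  if (pos <= length(toks) && latinate_lower(toks[pos])) {
    epithet <- toks[pos]
    if (isTRUE(flag_next[pos])) hybrid_epithet <- TRUE
    pos <- pos + 1L
  }

  if (!is.null(epithet) && pos < length(toks) && toks[pos] %in% RANK_MARKERS &&
      latinate_lower(toks[pos + 1L])) {
    infra_rank <- toks[pos]
    infra_epithet <- toks[pos + 1L]
    pos <- pos + 2L
  }

  authority <- if (pos <= length(toks)) paste(toks[pos:length(toks)], collapse = " ") else NULL

  structure(list(
    genus_raw = genus,
    subgenus_raw = subgenus,
    epithet_raw = epithet,
    infra_rank_marker = infra_rank,
    infra_epithet_raw = infra_epithet,
    authority_raw = authority,
    hybrid_genus = hybrid_genus,
    hybrid_epithet = hybrid_epithet,
    qualifiers = qualifiers,
    residue = ""
  ), class = "parsed_name")
}

#' @export
print.parsed_name <- function(x, ...) {
  cat("<parsed name> genus:", x$genus_raw)
  if (!is.null(x$subgenus_raw)) cat(" (", x$subgenus_raw, ")", sep = "")
  if (!is.null(x$epithet_raw)) cat(" epithet:", x$epithet_raw)
  if (!is.null(x$infra_rank_marker))
    cat(" ", x$infra_rank_marker, " ", x$infra_epithet_raw, sep = "")
  if (!is.null(x$authority_raw)) cat(" authority:", x$authority_raw)
  if (x$hybrid_genus) cat(" [hybrid genus]")
  if (x$hybrid_epithet) cat(" [hybrid epithet]")
  if (length(x$qualifiers)) cat(" qualifiers:", paste(x$qualifiers, collapse = ","))
  cat("\n")
  invisible(x)
}
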