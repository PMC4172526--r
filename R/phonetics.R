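# Custom phonetic key encoders for latinized scientific names (2001 and 2007
# variants), plus the Boolean phonetic-match test used throughout the
# matching engine. Keys are computed on normalized (uppercase A-Z) words.

# Remainder substitutions shared by both encoder versions. Applied in
# left-to-right passes, longest pattern first at each cursor position;
# within a pass the cursor skips past each replacement, and passes repeat
# until a fixpoint so that substitution products (e.g. an I produced from E
# followed by an original A, forming IA) are themselves resolved -- this is
# what makes the gender endings -us/-a/-um collapse for vowel-final stems.
.remainder_pats <- list(
  c("AE", "I"), c("OE", "I"), c("IA", "A"), c("MC", "MAC"), c("SC", "S"),
  c("E", "I"), c("U", "I"), c("Y", "I"), c("O", "A"), c("K", "C"),
  c("Z", "S"), c("H", "")
)

# Leading-pattern replacements of the 2007 variant, applied to the whole
# word before the initial character is quarantined. At most one fires.
.leading_pats <- list(
  c("AE", "E"), c("EA", "E"), c("OE", "E"),
  c("CN", "N"), c("GN", "N"), c("KN", "N"), c("MN", "N"),
  c("CT", "T"), c("PT", "T"),
  c("CZ", "C"), c("DJ", "J"), c("EU", "U"),
  c("PH", "F"), c("PS", "S"), c("TS", "S"),
  c("QU", "Q"), c("X", "Z")
)

.apply_remainder <- function(s) {
  for (pass in 1:10) {
    s2 <- .apply_remainder_pass(s)
    if (identical(s2, s)) break
    s <- s2
  }
  s
}

.apply_remainder_pass <- function(s) {
  if (!nzchar(s)) return(s)
  out <- character(0)
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    hit <- FALSE
    for (p in .remainder_pats) {
      pl <- nchar(p[1])
      if (i + pl - 1L <= n && substr(s, i, i + pl - 1L) == p[1]) {
        out <- c(out, p[2])
        i <- i + pl
        hit <- TRUE
        break
      }
    }
    if (!hit) {
      out <- c(out, substr(s, i, i))
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

.collapse_dupes <- function(s) gsub("(.)\\1+", "\\1", s)

phonetic_key_one <- function(word, version, is_epithet) {
  if (!nzchar(word)) stop("phonetic key of empty word")
  if (grepl("[^A-Z]", word)) word <- normalize_word(word)
  if (version == 2007L) {
    for (p in .leading_pats) {
      if (startsWith(word, p[1])) {
        word <- paste0(p[2], substr(word, nchar(p[1]) + 1L, nchar(word)))
        break
      }
    }
  }
  head_chr <- substr(word, 1L, 1L)
  rest <- .apply_remainder(substr(word, 2L, nchar(word)))
  key <- .collapse_dupes(paste0(head_chr, rest))
  # gender normalization: keys now ending -IS (from -is/-us/-ys/-es), -IM
  # (from -um) or -AS (from -as/-os) have the last 2 characters replaced by
  # A, provided at least one stem character survives (key length >= 3); a
  # final duplicate collapse keeps the no-adjacent-repeats invariant.
  if (version == 2007L && is_epithet && nchar(key) >= 3L) {
    tail2 <- substr(key, nchar(key) - 1L, nchar(key))
    if (tail2 %in% c("IS", "IM", "AS"))
      key <- .collapse_dupes(paste0(substr(key, 1L, nchar(key) - 2L), "A"))
  }
  key
}

#' Phonetic key of a scientific-name word
#'
#' Encodes a normalized word into a phonetic key such that soundalike
#' spellings collapse to the same string. The 2001 variant retains the
#' initial character unchanged and applies soundalike substitutions to the
#' remainder (AE/OE/E/U/Y to I, IA/O to A, K to C, SC/Z to S, MC to MAC, H
#' dropped) followed by collapsing of repeated adjacent letters. The 2007
#' variant additionally transforms selected leading patterns before the
#' initial character is quarantined (e.g. PH- to F-, KN- to N-, X- to Z-)
#' and, for species epithets, normalizes the grammatical-gender ending:
#' keys ending -IS (from -is/-us/-ys/-es), -IM (from -um) or -AS (from
#' -as/-os) have the final two characters replaced by A, so that e.g.
#' "columbianus" and "columbiana" share a key.
#'
#' @param word Character vector of words; normalized internally if needed.
#' @param version 2001 or 2007 (default).
#' @param is_epithet Apply the 2007 gender-ending normalization (only
#'   meaningful with `version = 2007`).
#' @return Character vector of keys (uppercase, no adjacent duplicates).
#' @examples
#' phonetic_key("Penaeus")                      # "PINIS"
#' phonetic_key("columbianus", is_epithet = TRUE)
#' @export
phonetic_key <- function(word, version = 2007, is_epithet = FALSE) {
  version <- as.integer(version)
  if (!version %in% c(2001L, 2007L)) stop("version must be 2001 or 2007")
  vapply(word, phonetic_key_one, character(1),
         version = version, is_epithet = is_epithet, USE.NAMES = FALSE)
}

#' Boolean phonetic-match test (2007 keys)
#'
#' Two words are a phonetic match iff their 2007 phonetic keys are equal.
#' Reflexive and symmetric.
#'
#' @param a,b Character vectors of words (recycled to common length).
#' @param is_epithet Treat the words as species epithets (gender-tolerant).
#' @return Logical vector.
#' @export
phonetic_match <- function(a, b, is_epithet = FALSE) {
  phonetic_key(a, 2007, is_epithet) == phonetic_key(b, 2007, is_epithet)
}
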