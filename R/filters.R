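# Heuristic gatekeepers around the edit-distance tests. The pre-filters
# (blocking) cut the candidate set before any dynamic-programming
# comparison; the post-filters discard implausible survivors afterwards.
# All are pure functions of their arguments, which is what makes the
# optimized engine provably equivalent to the naive brute-force engine.
# Constants are frozen to the published rule set.

#' Genus pre-filter (rules 1a-1c)
#'
#' A target genus is admitted to the edit-distance test when any one rule
#' holds: (1a) the 2007 phonetic keys of query and target genus are equal;
#' (1b) the query has an epithet whose gender-normalized 2007 key occurs
#' among the target genus's species epithet keys AND the genus lengths
#' differ by at most 3; (1c) the genus lengths differ by at most 2 AND,
#' with m the length of the shorter genus: m < 5 requires the first OR
#' last character to agree, m == 5 the first 2 OR last 3, m >= 6 the
#' first 3 OR last 3. Rule 1b is skipped for uninomial queries. Vectorized
#' over targets.
#'
#' @param q_genus Normalized query genus.
#' @param q_genus_key Its 2007 phonetic key.
#' @param q_epithet_key Gender-normalized 2007 key of the query epithet, or
#'   `NULL` for a uninomial query.
#' @param g_norm Character vector of normalized target genus names.
#' @param g_key Their 2007 phonetic keys.
#' @param g_has_epithet_key Logical vector: does the target genus have a
#'   species whose epithet key equals `q_epithet_key`?
#' @param rapid Use only rules 1a/1b ("rapid" mode).
#' @return List with logical vector `pass` and character vector `rule`
#'   ("1a", "1b", "1c" or "" when failed); rule 1a doubles as the genus
#'   phonetic-match flag carried downstream.
#' @export
genus_prefilter <- function(q_genus, q_genus_key, q_epithet_key,
                            g_norm, g_key, g_has_epithet_key,
                            rapid = FALSE) {
  qlen <- nchar(q_genus)
  glen <- nchar(g_norm)
  diff <- abs(qlen - glen)

  r1a <- g_key == q_genus_key

  r1b <- if (!is.null(q_epithet_key)) {
    g_has_epithet_key & diff <= 3L
  } else rep(FALSE, length(g_norm))

  if (rapid) {
    r1c <- rep(FALSE, length(g_norm))
  } else {
    m <- pmin(qlen, glen)
    first_eq <- function(k) substr(g_norm, 1L, k) == substr(q_genus, 1L, k)
    last_eq <- function(k) {
      substr(g_norm, glen - k + 1L, glen) == substr(q_genus, qlen - k + 1L, qlen)
    }
    sub_ok <- ifelse(m < 5L, first_eq(1L) | last_eq(1L),
              ifelse(m == 5L, first_eq(2L) | last_eq(3L),
                              first_eq(3L) | last_eq(3L)))
    r1c <- diff <= 2L & sub_ok
  }

  pass <- r1a | r1b | r1c
  rule <- character(length(pass))
  rule[r1c] <- "1c"
  rule[r1b] <- "1b"
  rule[r1a] <- "1a"
  list(pass = pass, rule = rule, phonetic = r1a)
}

#' Genus post-filter (rules 3a-3c)
#'
#' Applied after the genus edit-distance test: (3a) distance 4 or more is
#' discarded; (3b) phonetic matches are accepted outright; (3c) otherwise
#' at least 50 percent "good" characters are required -- at most ED 1 in a
#' word of up to 3 characters, ED 2 up to 5 characters, ED 3 from 6
#' characters (word length = the shorter of the two names) -- and the
#' initial characters must agree whenever the distance is 2 or more.
#' Vectorized.
#'
#' @param ed Numeric vector of genus edit distances (`Inf` allowed).
#' @param phonetic Logical vector: genus phonetic match.
#' @param q_len,g_len Genus lengths.
#' @param first_char_equal Logical vector.
#' @return Logical vector.
#' @export
genus_postfilter <- function(ed, phonetic, q_len, g_len, first_char_equal) {
  m <- pmin(q_len, g_len)
  max_ed <- ifelse(m <= 3L, 1L, ifelse(m <= 5L, 2L, 3L))
  r3c <- ed <= max_ed & (ed < 2L | first_char_equal)
  ed < 4 & (phonetic | r3c)
}

#' Species pre-filter (rules 4a-4b)
#'
#' A target species is tested only when its genus passed the genus
#' post-filter (4a) and its epithet length differs from the query epithet
#' by at most 4 characters (4b). Vectorized.
#'
#' @param q_epithet_len Query epithet length.
#' @param target_epithet_len Integer vector of target epithet lengths.
#' @param parent_passed Logical vector (rule 4a).
#' @return Logical vector.
#' @export
species_prefilter <- function(q_epithet_len, target_epithet_len, parent_passed) {
  parent_passed & abs(q_epithet_len - target_epithet_len) <= 4L
}

#' Species post-filter (rules 6a-6c)
#'
#' (6a) the combined genus + epithet edit distance must not exceed 4;
#' (6b) epithet phonetic matches are then accepted outright; (6c)
#' otherwise the epithet needs at least 50 percent good characters --
#' at most ED 1 up to 3 characters, ED 2 up to 5, ED 3 up to 7, ED 4 from
#' 8 (m = shorter epithet length) -- the initial character must agree for
#' epithet ED 2 and 3, and the initial 3 characters for epithet ED 4.
#' Vectorized.
#'
#' @param genus_ed,epithet_ed Numeric vectors of distances.
#' @param epithet_phonetic Logical vector.
#' @param m Integer vector: shorter of query and target epithet lengths.
#' @param first_char_equal,first3_equal Logical vectors on the epithets.
#' @return Logical vector.
#' @export
species_postfilter <- function(genus_ed, epithet_ed, epithet_phonetic,
                               m, first_char_equal, first3_equal) {
  combined_ok <- (genus_ed + epithet_ed) <= 4
  max_ed <- ifelse(m <= 3L, 1L, ifelse(m <= 5L, 2L, ifelse(m <= 7L, 3L, 4L)))
  r6c <- epithet_ed <= max_ed &
    (epithet_ed < 2L | (epithet_ed <= 3L & first_char_equal) |
       (epithet_ed == 4L & first3_equal))
  combined_ok & (epithet_phonetic | r6c)
}
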