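# Padded/unpadded n-gram multiset similarity, and the 2/3 bigram + 1/3
# trigram blend used for authority comparison.

ngrams_of <- function(s, n, padded) {
  if (padded) s <- paste0(strrep(" ", n - 1L), s, strrep(" ", n - 1L))
  L <- nchar(s)
  if (L < n) return(character(0))
  starts <- 1:(L - n + 1L)
  substring(s, starts, starts + n - 1L)
}

multiset_intersection_size <- function(a, b) {
  ta <- table(a)
  tb <- table(b)
  common <- intersect(names(ta), names(tb))
  if (!length(common)) return(0L)
  sum(pmin(as.integer(ta[common]), as.integer(tb[common])))
}

#' n-gram multiset similarity between two strings
#'
#' Builds the multiset of length-`n` character windows of each uppercased
#' string (spaces and punctuation retained; repeated grams count as
#' separate instances) and returns the number of shared gram instances
#' divided by the arithmetic mean of the two gram counts. With
#' `padded = TRUE`, `n - 1` space characters are appended to each end of
#' each string before windowing, so terminal characters are represented in
#' as many grams as internal ones; a padded profile of a length-L string
#' has L + n - 1 grams.
#'
#' @param a,b Strings to compare.
#' @param n Gram length (>= 2); 2 = bigrams, 3 = trigrams.
#' @param padded Pad with n - 1 spaces at each end (default TRUE).
#' @return Similarity in \[0, 1\]; 1 iff the gram multisets are equal.
#' @examples
#' ngram_similarity("Tony", "Toby", n = 2, padded = FALSE)  # 1/3
#' ngram_similarity("Tony", "Toby", n = 2, padded = TRUE)   # 0.6
#' @export
ngram_similarity <- function(a, b, n = 2, padded = TRUE) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  if (!nzchar(a) || !nzchar(b)) stop("ngram_similarity: empty string")
  ga <- ngrams_of(toupper(a), n, padded)
  gb <- ngrams_of(toupper(b), n, padded)
  denom <- mean(c(length(ga), length(gb)))
  if (denom == 0) return(0)
  multiset_intersection_size(ga, gb) / denom
}

#' Blended bigram/trigram similarity
#'
#' Weighted blend of 2/3 padded bigram similarity and 1/3 padded trigram
#' similarity. Bigrams alone are insensitive to token order (any
#' permutation of space-separated tokens scores 1); the trigram component
#' reduces, without eliminating, that insensitivity. Used for authority
#' strings.
#'
#' @param a,b Strings to compare.
#' @return Similarity in \[0, 1\].
#' @export
blended_similarity <- function(a, b) {
  (2 / 3) * ngram_similarity(a, b, 2, padded = TRUE) +
    (1 / 3) * ngram_similarity(a, b, 3, padded = TRUE)
}
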