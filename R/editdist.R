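# Edit distances: Levenshtein (LD), Damerau-Levenshtein (DLD, optimal string
# alignment) and the Modified Damerau-Levenshtein distance (MDLD) in which an
# adjacent transposed block of b characters costs b instead of up to 2b.
# block_limit = 0 gives LD, 1 gives DLD, k >= 2 admits transposed blocks of
# up to k characters (equal-length, adjacent, non-overlapping).

mdld_one <- function(a, b, block_limit = 1L, max_distance = Inf) {
  A <- utf8ToInt(a)
  B <- utf8ToInt(b)
  n <- length(A)
  m <- length(B)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0L:n
  d[1L, ] <- 0L:m
  for (i in 1:n) {
    rowmin <- Inf
    for (j in 1:m) {
      cost <- if (A[i] == B[j]) 0L else 1L
      v <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L, d[i, j] + cost)
      if (block_limit >= 1L) {
        for (bl in 1:block_limit) {
          if (i >= 2L * bl && j >= 2L * bl &&
              all(A[(i - bl + 1L):i] == B[(j - 2L * bl + 1L):(j - bl)]) &&
              all(A[(i - 2L * bl + 1L):(i - bl)] == B[(j - bl + 1L):j])) {
            v <- min(v, d[i - 2L * bl + 1L, j - 2L * bl + 1L] + bl)
          }
        }
      }
      d[i + 1L, j + 1L] <- v
      if (v < rowmin) rowmin <- v
    }
    # early abandon: once no cell in a row can recover, the final distance
    # must exceed max_distance; report the sentinel rather than a clamped
    # number so callers can distinguish "unknown but large" from a value.
    if (rowmin > max_distance) return(Inf)
  }
  d[n + 1L, m + 1L]
}

#' Edit distance with multi-character block transpositions
#'
#' Dynamic-programming edit distance over normalized words with unit costs
#' for insertion, deletion and substitution. `block_limit = 0` is the plain
#' Levenshtein distance; `block_limit = 1` additionally admits adjacent
#' single-character transpositions at cost 1 (Damerau-Levenshtein, optimal
#' string alignment); `block_limit = k >= 2` admits transposition of
#' adjacent equal-length blocks of up to k characters at a cost equal to
#' the block length, so that e.g. PANULIRUS/PALINURUS score 2 rather than
#' 4. Genus comparisons default to block limit 2, species epithets to 4.
#'
#' @param a,b Words to compare (uppercased internally; vectors recycled).
#' @param block_limit Maximum transposed block length (0 = none).
#' @param max_distance Optional early-abandon bound: when every cell of a
#'   DP row exceeds it, `Inf` is returned as an "exceeds" sentinel.
#' @return Numeric vector of distances (`Inf` when abandoned).
#' @examples
#' edit_distance("FUCUS", "FICUS", block_limit = 0)      # 1
#' edit_distance("PANULIRUS", "PALINURUS", block_limit = 2)  # 2
#' @export
edit_distance <- function(a, b, block_limit = 1, max_distance = Inf) {
  block_limit <- as.integer(block_limit)
  if (block_limit < 0L) stop("block_limit must be >= 0")
  a <- toupper(a)
  b <- toupper(b)
  k <- max(length(a), length(b))
  a <- rep_len(a, k)
  b <- rep_len(b, k)
  vapply(seq_len(k), function(i) {
    as.numeric(mdld_one(a[i], b[i], block_limit, max_distance))
  }, numeric(1))
}

#' Number of distinct single-edit operations on a word
#'
#' For a word of the given length over an alphabet of the given size there
#' are `(length + 1) * alphabet_size` insertions, `length` deletions,
#' `length * (alphabet_size - 1)` substitutions to a different letter, and
#' `length - 1` adjacent transpositions: the number of operations that can
#' produce a string at edit distance at most 1 (e.g. 237 for a 4-character
#' word, 555 for 10 characters). Counts operations, not distinct strings.
#'
#' @param length Word length (>= 1), vectorized.
#' @param alphabet_size Alphabet size (default 26).
#' @return Integer vector of operation counts.
#' @export
ed1_operation_count <- function(length, alphabet_size = 26L) {
  length <- as.integer(length)
  if (any(length < 1L)) stop("length must be >= 1")
  alphabet_size <- as.integer(alphabet_size)
  (length + 1L) * alphabet_size + length +
    length * (alphabet_size - 1L) + (length - 1L)
}

#' Exact edit-distance-1 neighborhood of a word
#'
#' Enumerates every distinct string obtainable from `word` by exactly one
#' insertion, deletion, substitution to a different letter, or adjacent
#' transposition over the given alphabet. Used as an independent oracle for
#' [edit_distance()] and for the structural single-edit recall guarantee.
#'
#' @param word A single word.
#' @param alphabet Character vector of letters (default `LETTERS`).
#' @return Character vector of distinct neighbor strings (the word itself
#'   excluded).
#' @export
ed1_neighborhood <- function(word, alphabet = LETTERS) {
  stopifnot(length(word) == 1L, nzchar(word))
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  n <- length(chars)
  out <- character(0)
  for (i in 0:n) {  # insertions after position i
    for (ch in alphabet) {
      out <- c(out, paste(append(chars, ch, after = i), collapse = ""))
    }
  }
  if (n > 1L) {
    for (i in 1:n) out <- c(out, paste(chars[-i], collapse = ""))
  } else {
    out <- c(out, "")
  }
  for (i in 1:n) {  # substitutions
    for (ch in setdiff(alphabet, chars[i])) {
      tmp <- chars
      tmp[i] <- ch
      out <- c(out, paste(tmp, collapse = ""))
    }
  }
  if (n >= 2L) {  # adjacent transpositions
    for (i in 1:(n - 1L)) {
      tmp <- chars
      tmp[c(i, i + 1L)] <- tmp[c(i + 1L, i)]
      out <- c(out, paste(tmp, collapse = ""))
    }
  }
  setdiff(unique(out), word)
}
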