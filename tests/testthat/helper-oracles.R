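# Independent oracles and shared fixtures.

# Front-anchored recursive edit-script search: transforms the suffix of `a`
# starting at i into the suffix of `b` starting at j by consuming operations
# from the left. Deliberately a different formulation from the package's
# bottom-up prefix matrix.
oracle_edit_distance <- function(a, b, block_limit = 0L) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(A)
  nb <- length(B)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    if (i > na) {
      res <- nb - j + 1L
    } else if (j > nb) {
      res <- na - i + 1L
    } else {
      res <- rec(i + 1L, j + 1L) + (A[i] != B[j])
      res <- min(res, rec(i + 1L, j) + 1L, rec(i, j + 1L) + 1L)
      if (block_limit >= 1L) {
        for (bl in seq_len(block_limit)) {
          if (i + 2L * bl - 1L <= na && j + 2L * bl - 1L <= nb &&
              all(A[i:(i + bl - 1L)] == B[(j + bl):(j + 2L * bl - 1L)]) &&
              all(A[(i + bl):(i + 2L * bl - 1L)] == B[j:(j + bl - 1L)])) {
            res <- min(res, rec(i + 2L * bl, j + 2L * bl) + bl)
          }
        }
      }
    }
    memo[[key]] <- res
    res
  }
  rec(1L, 1L)
}

all_strings_upto <- function(max_len, alphabet) {
  strs <- ""
  level <- ""
  for (l in seq_len(max_len)) {
    level <- as.vector(outer(level, alphabet, paste0))
    strs <- c(strs, level)
  }
  strs
}

random_word <- function(min_len = 3, max_len = 12) {
  paste(sample(LETTERS, sample(min_len:max_len, 1), replace = TRUE),
        collapse = "")
}

# compact fixture checklist used across engine tests
fixture_rows <- function() {
  data.frame(
    genus = c("Halymenia", "Halymenia", "Aleuron", "Asura", "Alesia",
              "Asura", "Peronella", "Fucus", "Ficus", "Homo"),
    epithet = c("dilatata", "digitata", "scriptor", "scripta", "striata",
                "striata", "lesueuri", NA, NA, NA),
    authority = c("Zanardini", "J. Agardh", NA, NA, NA, NA, NA,
                  "L.", "L.", "L."),
    stringsAsFactors = FALSE)
}
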