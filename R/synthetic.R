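# Synthetic checklist generation, misspelling generation by error type,
# error classification, and the recall/precision/F1 evaluation harness.

.CONS <- c("b", "c", "d", "f", "g", "h", "l", "m", "n", "p", "r", "s", "t", "v")
.VOWS <- c("a", "e", "i", "o", "u")

# run code under a fixed seed, restoring the caller's RNG state afterwards
local_seed <- function(seed) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE))
    get(".Random.seed", envir = env) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    } else assign(".Random.seed", old, envir = env)
  }
}

cv_word <- function(len) {
  w <- ""
  while (nchar(w) < len) {
    syl <- paste0(sample(.CONS, 1), sample(.VOWS, 1),
                  if (stats::runif(1) < 0.25) sample(.CONS, 1) else "")
    w <- paste0(w, syl)
  }
  substr(w, 1, len)
}

title_case <- function(w) paste0(toupper(substr(w, 1, 1)), substring(w, 2))

#' Generate a synthetic reference checklist
#'
#' Deterministic latinate-looking names built from a consonant-vowel
#' syllable sampler: genus names of 4-16 characters, species epithets of
#' 4-14 characters finished with a classical gender ending sampled from
#' -us/-a/-um/-is. Names are unique within the checklist and pure ASCII,
#' so they survive normalization unchanged. The same seed always produces
#' the same rows.
#'
#' @param n_genera Number of genera (>= 1).
#' @param species_per_genus Species generated under each genus.
#' @param seed Integer seed.
#' @return A data.frame of reference rows (`genus`, `epithet`,
#'   `authority`, `status`, `group`) suitable for [build_index()].
#' @export
generate_reference <- function(n_genera, species_per_genus, seed = 1L) {
  stopifnot(n_genera >= 1L, species_per_genus >= 0L)
  restore <- local_seed(seed)
  on.exit(restore())

  genera <- character(0)
  while (length(genera) < n_genera) {
    g <- title_case(cv_word(sample(4:16, 1)))
    if (!g %in% genera) genera <- c(genera, g)
  }

  rows <- vector("list", n_genera)
  endings <- c("us", "a", "um", "is")
  for (i in seq_len(n_genera)) {
    eps <- character(0)
    while (length(eps) < species_per_genus) {
      end <- sample(endings, 1)
      len <- sample(4:14, 1)
      stem <- cv_word(max(2L, len - nchar(end)))
      e <- paste0(stem, end)
      if (!e %in% eps) eps <- c(eps, e)
    }
    rows[[i]] <- data.frame(
      genus = genera[i],
      epithet = if (species_per_genus) eps else NA_character_,
      authority = NA_character_, status = NA_character_,
      group = NA_character_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- single-word edit primitives (uppercase words) -------------------------

.chars <- function(w) strsplit(w, "", fixed = TRUE)[[1]]
.join <- function(ch) paste(ch, collapse = "")
.rand_letter <- function(not = NULL) sample(setdiff(LETTERS, not), 1)

edit_1a <- function(w) {  # non-initial insertion/deletion/substitution
  ch <- .chars(w)
  n <- length(ch)
  op <- sample(c("ins", "del", "sub"), 1)
  if (op == "ins") {
    pos <- sample(1:n, 1)  # insert after position >= 1
    .join(append(ch, .rand_letter(), after = pos))
  } else if (op == "del" && n > 2) {
    .join(ch[-sample(2:n, 1)])
  } else {
    pos <- sample(2:n, 1)
    ch[pos] <- .rand_letter(not = ch[pos])
    .join(ch)
  }
}

edit_1b <- function(w) {  # non-initial adjacent transposition
  ch <- .chars(w)
  n <- length(ch)
  cand <- which(ch[-n] != ch[-1])
  cand <- cand[cand >= 2]
  if (!length(cand)) return(w)
  i <- if (length(cand) == 1) cand else sample(cand, 1)
  ch[c(i, i + 1)] <- ch[c(i + 1, i)]
  .join(ch)
}

edit_1c <- function(w) {  # edit at word start
  ch <- .chars(w)
  op <- sample(c("ins", "del", "sub", "trans"), 1)
  if (op == "ins") {
    .join(c(.rand_letter(not = ch[1]), ch))
  } else if (op == "del" && length(ch) > 2 && ch[1] != ch[2]) {
    .join(ch[-1])
  } else if (op == "trans" && ch[1] != ch[2]) {
    ch[c(1, 2)] <- ch[c(2, 1)]
    .join(ch)
  } else {
    ch[1] <- .rand_letter(not = ch[1])
    .join(ch)
  }
}

edit_2 <- function(w) {  # two-character change, first character kept
  w2 <- edit_1a(w)
  edit_1a(w2)
}

edit_3 <- function(w) {  # 2-char block transposition or 3 single edits
  ch <- .chars(w)
  n <- length(ch)
  if (stats::runif(1) < 0.5 && n >= 4) {
    i <- sample(1:(n - 3), 1)
    blk <- ch[c(i + 2, i + 3, i, i + 1)]
    ch[i:(i + 3)] <- blk
    .join(ch)
  } else {
    w2 <- edit_1a(edit_1a(edit_1a(w)))
    w2
  }
}

apply_word_edit <- function(w, label) {
  switch(label,
         "1a" = edit_1a(w), "1b" = edit_1b(w), "1c" = edit_1c(w),
         "2" = edit_2(w), "3" = edit_3(w),
         stop("unknown single-word error type: ", label))
}

is_adjacent_transposition <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  A <- .chars(a)
  B <- .chars(b)
  d <- which(A != B)
  length(d) == 2 && d[2] == d[1] + 1 &&
    A[d[1]] == B[d[2]] && A[d[2]] == B[d[1]]
}

is_block2_swap <- function(a, b) {
  if (nchar(a) != nchar(b) || nchar(a) < 4) return(FALSE)
  A <- .chars(a)
  for (i in 1:(length(A) - 3)) {
    sw <- A
    sw[i:(i + 3)] <- A[c(i + 2, i + 3, i, i + 1)]
    if (.join(sw) == b) return(TRUE)
  }
  FALSE
}

classify_word_error <- function(miss, corr) {
  d1 <- edit_distance(miss, corr, block_limit = 1)
  if (d1 == 0) stop("classify_error: words are identical")
  if (d1 == 1) {
    if (substr(miss, 1, 1) != substr(corr, 1, 1)) return("1c")
    if (is_adjacent_transposition(miss, corr)) return("1b")
    return("1a")
  }
  if (d1 == 2) {
    if (is_block2_swap(miss, corr)) return("3")
    return("2")
  }
  "3"
}

#' Classify a misspelling against its correct form
#'
#' Assigns the error-type taxonomy used for evaluation: `1a` single
#' non-initial character insertion/deletion/substitution; `1b` single
#' non-initial adjacent transposition; `1c` error at word start; `2`
#' two-character insertion/deletion/substitution; `3` two-character block
#' transposition or three or more character transformations; `4`
#' (binomials only) at least one transformation in both genus and
#' epithet. The phonetic flag is true iff every changed word is a 2007
#' phonetic match of its correct form (gender-tolerant for epithets).
#'
#' @param misspelled,correct Name strings of the same structure (both
#'   uninomial or both binomial).
#' @return List with `label` and `phonetic`.
#' @examples
#' classify_error("Peneus", "Penaeus")       # 1a, phonetic
#' classify_error("Acropaginula", "Arcopaginula")  # 1b, non-phonetic
#' @export
classify_error <- function(misspelled, correct) {
  pm <- parse_name(misspelled)
  pc <- parse_name(correct)
  if (is_parse_failure(pm) || is_parse_failure(pc))
    stop("classify_error: unparseable input")
  if (is.null(pm$epithet_raw) != is.null(pc$epithet_raw))
    stop("classify_error: names do not share a structure")

  mg <- normalize_word(pm$genus_raw)
  cg <- normalize_word(pc$genus_raw)
  words <- list(c(mg, cg, FALSE))
  if (!is.null(pm$epithet_raw)) {
    words <- c(words, list(c(normalize_word(pm$epithet_raw),
                             normalize_word(pc$epithet_raw), TRUE)))
  }
  changed <- Filter(function(w) w[1] != w[2], words)
  if (!length(changed)) stop("classify_error: names are identical")

  label <- if (length(changed) == 2) "4" else
    classify_word_error(changed[[1]][1], changed[[1]][2])
  phonetic <- all(vapply(changed, function(w)
    phonetic_match(w[1], w[2], is_epithet = as.logical(w[3])), logical(1)))
  list(label = label, phonetic = phonetic)
}

#' Generate a misspelling of a given error type
#'
#' Applies a random edit of the requested type to one word of the name
#' (both words for type 4), resampling until the result differs from the
#' input and [classify_error()] reproduces the requested label, so
#' generator and classifier stay consistent by construction. Types 1a/1b
#' produce words at Damerau-Levenshtein distance exactly 1 from the
#' original.
#'
#' @param name Correct name (uninomial or binomial string).
#' @param error_type One of `"1a"`, `"1b"`, `"1c"`, `"2"`, `"3"`, `"4"`.
#' @param seed Integer seed.
#' @return A `synthetic_case` list: `correct`, `misspelled`,
#'   `error_type` (list with `label`, `phonetic`), `seed`.
#' @export
generate_misspelling <- function(name, error_type, seed = 1L) {
  restore <- local_seed(seed)
  on.exit(restore())
  p <- parse_name(name)
  if (is_parse_failure(p)) stop("generate_misspelling: unparseable name")
  binomial <- !is.null(p$epithet_raw)
  if (error_type == "4" && !binomial)
    stop("type 4 errors apply only to binomials")

  g <- normalize_word(p$genus_raw)
  e <- if (binomial) normalize_word(p$epithet_raw) else NULL
  min_len <- if (error_type %in% c("3", "4")) 4L else 3L
  if (nchar(g) < min_len && (!binomial || error_type == "4"))
    stop("word too short for requested error type")

  for (attempt in 1:100) {
    if (error_type == "4") {
      sub_types <- sample(c("1a", "1b", "1c", "2", "3"), 2, replace = TRUE)
      g2 <- apply_word_edit(g, sub_types[1])
      e2 <- apply_word_edit(e, sub_types[2])
    } else {
      which_word <- if (binomial) sample(c("g", "e"), 1) else "g"
      g2 <- g
      e2 <- e
      if (which_word == "g") {
        if (nchar(g) < min_len) next
        g2 <- apply_word_edit(g, error_type)
      } else {
        if (nchar(e) < min_len) next
        e2 <- apply_word_edit(e, error_type)
      }
    }
    if (g2 == g && (!binomial || e2 == e)) next
    if (!nzchar(g2) || (binomial && !nzchar(e2))) next
    miss <- paste(c(title_case(tolower(g2)),
                    if (binomial) tolower(e2)), collapse = " ")
    corr <- paste(c(p$genus_raw, if (binomial) p$epithet_raw), collapse = " ")
    cls <- tryCatch(classify_error(miss, corr), error = function(err) NULL)
    if (is.null(cls) || cls$label != error_type) next
    return(structure(list(correct = corr, misspelled = miss,
                          error_type = cls, seed = seed),
                     class = "synthetic_case"))
  }
  stop("could not generate a type ", error_type, " misspelling of '",
       name, "'")
}

#' Evaluate matcher performance on synthetic cases
#'
#' Runs the matcher on each misspelled name and scores: recall = the
#' fraction of cases whose designated correct target appears anywhere in
#' the returned candidates (exact, nearest or other); precision = true
#' hits divided by all returned hits pooled over the set; F1 = their
#' harmonic mean. Recall is additionally disaggregated by error type.
#'
#' @param cases List of `synthetic_case` objects.
#' @param index A `taxmatch_index` containing every correct name.
#' @param config An [engine_config()].
#' @return List with `recall`, `precision`, `f1`, `by_error_type`
#'   (named numeric vector of per-type recall), `n_cases`.
#' @export
evaluate_cases <- function(cases, index, config = engine_config()) {
  if (!length(cases)) stop("evaluate_cases: empty case list")
  hits <- logical(length(cases))
  labels <- character(length(cases))
  total_returned <- 0L
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    rep_ <- match_name(cs$misspelled, index, config)
    returned <- c(rep_$exact$name, rep_$nearest$name, rep_$other$name)
    total_returned <- total_returned + length(returned)
    hits[i] <- cs$correct %in% returned
    labels[i] <- cs$error_type$label
  }
  recall <- mean(hits)
  precision <- if (total_returned > 0) sum(hits) / total_returned else NA_real_
  f1 <- if (!is.na(precision) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  by_type <- tapply(hits, labels, mean)
  list(recall = recall, precision = precision, f1 = f1,
       by_error_type = by_type, n_cases = length(cases))
}
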