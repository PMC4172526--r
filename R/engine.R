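# Reference index construction and the match orchestration: candidate
# generation through pre-filter -> MDLD -> post-filter at genus then
# species level, result shaping, ranking, and a naive brute-force engine
# used to verify that the indexing shortcuts never change semantics.

MASKED_STATUS <- c("misspelling", "nomen nudum", "nomen_nudum",
                   "later usage", "later_usage")

#' Engine configuration
#'
#' @param mode One of `"normal"` (result shaping on), `"no_shaping"` (all
#'   post-filtered candidates reported) or `"rapid"` (genus pre-filter
#'   restricted to the phonetic rules 1a/1b, trading a little recall for
#'   speed).
#' @param group Optional free-text group label; only reference names
#'   carrying it are matched.
#' @param genus_block_limit Maximum transposed block length for the genus
#'   distance (default 2).
#' @param species_block_limit Same for the species epithet (default 4).
#' @param abbrevs Author-abbreviation table for authority similarity.
#' @return A list of class `engine_config`.
#' @export
engine_config <- function(mode = c("normal", "no_shaping", "rapid"),
                          group = NULL,
                          genus_block_limit = 2,
                          species_block_limit = 4,
                          abbrevs = default_abbrev_table()) {
  mode <- match.arg(mode)
  structure(list(mode = mode, group = group,
                 genus_block_limit = as.integer(genus_block_limit),
                 species_block_limit = as.integer(species_block_limit),
                 abbrevs = abbrevs),
            class = "engine_config")
}

#' Build a reference index from checklist rows
#'
#' Precomputes, for every reference name, the normalized form, its length,
#' and its 2007 phonetic key (gender-normalized for epithets), and collects
#' for each genus the set of epithet keys of its unmasked species -- the
#' derived columns that make the pre-filters cheap. Rows whose status flags
#' them as misspellings, nomina nuda or later usages are masked: they stay
#' in the index but are never returned as matches. Genera with zero species
#' remain matchable at genus level. Duplicate (genus, epithet) rows are
#' collapsed with a warning; unparseable rows are reported and skipped.
#'
#' @param rows A data.frame of reference rows as returned by
#'   [read_reference()] (columns `genus`, `epithet`, `authority`, `status`,
#'   `group`; or a `scientific_name` column to be parsed).
#' @return An object of class `taxmatch_index`.
#' @export
build_index <- function(rows) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (!"genus" %in% names(rows)) {
    if (!"scientific_name" %in% names(rows))
      stop("build_index: need a 'genus' or 'scientific_name' column")
    parsed <- lapply(rows$scientific_name, parse_name)
    ok <- !vapply(parsed, is_parse_failure, logical(1))
    if (any(!ok))
      warning(sum(!ok), " unparseable reference row(s) skipped")
    rows <- rows[ok, , drop = FALSE]
    parsed <- parsed[ok]
    rows$genus <- vapply(parsed, function(p) p$genus_raw, character(1))
    rows$epithet <- vapply(parsed, function(p)
      if (is.null(p$epithet_raw)) NA_character_ else p$epithet_raw, character(1))
    if (!"authority" %in% names(rows))
      rows$authority <- vapply(parsed, function(p)
        if (is.null(p$authority_raw)) NA_character_ else p$authority_raw,
        character(1))
  }
  for (col in c("epithet", "authority", "status", "group"))
    if (!col %in% names(rows)) rows[[col]] <- NA_character_
  rows$epithet[!is.na(rows$epithet) & !nzchar(rows$epithet)] <- NA_character_

  rows$genus_norm <- normalize_word(rows$genus)
  rows$masked <- !is.na(rows$status) &
    tolower(rows$status) %in% MASKED_STATUS

  gkey <- !duplicated(rows$genus_norm)
  genera <- data.frame(
    id = seq_len(sum(gkey)),
    name_raw = rows$genus[gkey],
    name_norm = rows$genus_norm[gkey],
    stringsAsFactors = FALSE
  )
  genera$len <- nchar(genera$name_norm)
  genera$key2007 <- phonetic_key(genera$name_norm, 2007, is_epithet = FALSE)
  rows$genus_id <- genera$id[match(rows$genus_norm, genera$name_norm)]

  # a genus is masked only when flagged on its own (epithet-less) row
  gmask <- tapply(rows$masked & is.na(rows$epithet), rows$genus_id, any)
  genera$masked <- FALSE
  genera$masked[as.integer(names(gmask))] <- as.logical(gmask)
  gauth <- rows$authority[is.na(rows$epithet)]
  gauth_id <- rows$genus_id[is.na(rows$epithet)]
  genera$authority <- NA_character_
  genera$authority[gauth_id] <- gauth

  genus_groups <- lapply(seq_len(nrow(genera)), function(i) {
    g <- rows$group[rows$genus_id == i]
    unique(g[!is.na(g)])
  })

  sp <- rows[!is.na(rows$epithet), , drop = FALSE]
  species <- NULL
  if (nrow(sp)) {
    sp$epithet_norm <- normalize_word(sp$epithet)
    dup <- duplicated(paste(sp$genus_norm, sp$epithet_norm))
    if (any(dup)) {
      warning(sum(dup), " duplicate (genus, epithet) row(s) collapsed")
      sp <- sp[!dup, , drop = FALSE]
    }
    species <- data.frame(
      id = seq_len(nrow(sp)),
      genus_id = sp$genus_id,
      epithet_raw = sp$epithet,
      epithet_norm = sp$epithet_norm,
      len = nchar(sp$epithet_norm),
      key2007 = phonetic_key(sp$epithet_norm, 2007, is_epithet = TRUE),
      masked = sp$masked,
      authority = sp$authority,
      group = sp$group,
      stringsAsFactors = FALSE
    )
  } else {
    species <- data.frame(id = integer(0), genus_id = integer(0),
                          epithet_raw = character(0),
                          epithet_norm = character(0), len = integer(0),
                          key2007 = character(0), masked = logical(0),
                          authority = character(0), group = character(0),
                          stringsAsFactors = FALSE)
  }

  structure(list(genera = genera, species = species,
                 genus_groups = genus_groups),
            class = "taxmatch_index")
}

#' @export
print.taxmatch_index <- function(x, ...) {
  cat("<taxmatch index> ", nrow(x$genera), " genera, ",
      nrow(x$species), " species (",
      sum(x$genera$masked) + sum(x$species$masked), " masked)\n", sep = "")
  invisible(x)
}

empty_candidates <- function() {
  data.frame(name = character(0), genus_name = character(0),
             epithet = character(0), authority = character(0),
             genus_ed = numeric(0), epithet_ed = numeric(0),
             combined_ed = numeric(0), genus_phonetic = logical(0),
             epithet_phonetic = logical(0), phonetic = logical(0),
             authority_sim = numeric(0), stringsAsFactors = FALSE)
}

#' Result shaping (rules 7b-7d)
#'
#' Suppresses distant candidates when closer ones exist, emulating a human
#' operator who widens the search only when a narrow threshold returns
#' nothing. For species (distances are combined genus + epithet): ED up to
#' 2 and phonetic matches are always kept; ED 3 only in the absence of
#' those; ED 4 only in the absence of anything closer. For genera: ED 1
#' and phonetic always; ED 2 absent those; ED 3 absent ED up to 2 or
#' phonetic. Exact (ED 0) candidates are handled separately and must not
#' be passed in.
#'
#' @param cands Candidate data.frame (as in a match report).
#' @param level `"species"` or `"genus"`.
#' @return The shaped candidate data.frame.
#' @export
shape_results <- function(cands, level = c("species", "genus")) {
  level <- match.arg(level)
  if (!nrow(cands)) return(cands)
  ed <- cands$combined_ed
  phon <- cands$phonetic
  if (level == "species") {
    close_ <- ed <= 2 | phon
    keep <- close_ |
      (ed == 3 & !any(close_)) |
      (ed == 4 & !any(close_ | ed == 3))
  } else {
    close_ <- ed <= 1 | phon
    keep <- close_ |
      (ed == 2 & !any(close_)) |
      (ed == 3 & !any(close_ | ed == 2))
  }
  cands[keep, , drop = FALSE]
}

#' Ranking into nearest / other near matches (rules 9a-9b)
#'
#' Nearest matches are candidates at edit distance 1 (combined distance
#' for species) plus any phonetic matches; everything else is an "other
#' near match". Within each group ordering is alphabetical by full name.
#' Authority similarity is displayed but never used for ordering.
#'
#' @param cands Shaped candidate data.frame.
#' @param level `"species"` or `"genus"`.
#' @return List with data.frames `nearest` and `other`.
#' @export
rank_results <- function(cands, level = c("species", "genus")) {
  level <- match.arg(level)
  if (!nrow(cands)) return(list(nearest = cands, other = cands))
  is_nearest <- cands$combined_ed == 1 | cands$phonetic
  nearest <- cands[is_nearest, , drop = FALSE]
  other <- cands[!is_nearest, , drop = FALSE]
  nearest <- nearest[order(nearest$name), , drop = FALSE]
  other <- other[order(other$name), , drop = FALSE]
  rownames(nearest) <- NULL
  rownames(other) <- NULL
  list(nearest = nearest, other = other)
}

make_report <- function(query, mode, exact, nearest, other,
                        n_genera_prefiltered, n_epithets_tested,
                        elapsed, failure = NULL) {
  structure(list(query = query, mode = mode, exact = exact,
                 nearest = nearest, other = other,
                 n_genera_prefiltered = n_genera_prefiltered,
                 n_epithets_tested = n_epithets_tested,
                 elapsed = elapsed, failure = failure),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  q <- if (inherits(x$query, "parsed_name")) {
    paste(c(x$query$genus_raw, x$query$epithet_raw), collapse = " ")
  } else as.character(x$query)
  cat("<match report> query: ", q, " [mode: ", x$mode, "]\n", sep = "")
  if (!is.null(x$failure)) {
    cat("  parse failure: ", x$failure, "\n", sep = "")
    return(invisible(x))
  }
  fmt <- function(df) {
    if (!nrow(df)) return("  (none)\n")
    paste0("  ", df$name, "  (",
           ifelse(is.na(df$genus_ed), "", df$genus_ed),
           ifelse(is.na(df$epithet_ed), "", paste0(",", df$epithet_ed)),
           ")", ifelse(df$phonetic, " [phonetic]", ""), "\n", collapse = "")
  }
  cat("exact:\n", fmt(x$exact), sep = "")
  cat("nearest:\n", fmt(x$nearest), sep = "")
  cat("other:\n", fmt(x$other), sep = "")
  cat(sprintf("genera past pre-filter: %d; epithets tested: %d; %.3fs\n",
              x$n_genera_prefiltered, x$n_epithets_tested, x$elapsed))
  invisible(x)
}

# shared candidate-evaluation logic. The optimized path passes precomputed
# index columns; the brute-force path recomputes everything per record.
match_parsed <- function(parsed, index, config, query_authority = NULL) {
  t0 <- proc.time()[["elapsed"]]
  genera <- index$genera
  species <- index$species

  q_genus <- normalize_word(parsed$genus_raw)
  q_genus_key <- phonetic_key(q_genus, 2007, is_epithet = FALSE)
  q_epithet <- NULL
  q_epithet_key <- NULL
  if (!is.null(parsed$epithet_raw)) {
    q_epithet <- normalize_word(parsed$epithet_raw)
    q_epithet_key <- phonetic_key(q_epithet, 2007, is_epithet = TRUE)
  }
  if (is.null(query_authority)) query_authority <- parsed$authority_raw

  eligible <- !genera$masked
  if (!is.null(config$group)) {
    in_group <- vapply(index$genus_groups, function(g)
      config$group %in% g, logical(1))
    eligible <- eligible & in_group
  }

  gsub_idx <- which(eligible)
  g <- genera[gsub_idx, , drop = FALSE]

  g_has_key <- rep(FALSE, nrow(g))
  if (!is.null(q_epithet_key) && nrow(species)) {
    gid_with_key <- unique(species$genus_id[!species$masked &
                                              species$key2007 == q_epithet_key])
    g_has_key <- g$id %in% gid_with_key
  }

  pf <- genus_prefilter(q_genus, q_genus_key, q_epithet_key,
                        g$name_norm, g$key2007, g_has_key,
                        rapid = config$mode == "rapid")
  n_pref <- sum(pf$pass)
  g <- g[pf$pass, , drop = FALSE]
  g_phon <- pf$phonetic[pf$pass]

  g_ed <- edit_distance(rep(q_genus, nrow(g)), g$name_norm,
                        block_limit = config$genus_block_limit,
                        max_distance = 3)
  post <- genus_postfilter(g_ed, g_phon, nchar(q_genus), g$len,
                           substr(g$name_norm, 1, 1) == substr(q_genus, 1, 1))
  g <- g[post, , drop = FALSE]
  g_ed <- g_ed[post]
  g_phon <- g_phon[post]

  if (is.null(q_epithet)) {
    cands <- data.frame(
      name = g$name_raw, genus_name = g$name_raw,
      epithet = NA_character_, authority = g$authority,
      genus_ed = g_ed, epithet_ed = NA_real_, combined_ed = g_ed,
      genus_phonetic = g_phon, epithet_phonetic = NA,
      phonetic = g_phon, authority_sim = NA_real_,
      stringsAsFactors = FALSE)
    if (!is.null(query_authority) && nrow(cands)) {
      cands$authority_sim <- vapply(cands$authority, function(a)
        authority_similarity(query_authority, a, config$abbrevs), numeric(1))
    }
    exact <- cands[cands$combined_ed == 0, , drop = FALSE]
    near <- cands[cands$combined_ed > 0, , drop = FALSE]
    if (config$mode != "no_shaping") near <- shape_results(near, "genus")
    rk <- rank_results(near, "genus")
    rownames(exact) <- NULL
    return(make_report(parsed, config$mode, exact, rk$nearest, rk$other,
                       n_pref, 0L, proc.time()[["elapsed"]] - t0))
  }

  sp <- species[species$genus_id %in% g$id & !species$masked, , drop = FALSE]
  pre <- species_prefilter(nchar(q_epithet), sp$len, rep(TRUE, nrow(sp)))
  sp <- sp[pre, , drop = FALSE]
  n_ep <- nrow(sp)

  if (n_ep) {
    uniq_ep <- unique(sp$epithet_norm)
    uniq_ed <- edit_distance(rep(q_epithet, length(uniq_ep)), uniq_ep,
                             block_limit = config$species_block_limit,
                             max_distance = 4)
    e_ed <- uniq_ed[match(sp$epithet_norm, uniq_ep)]
    e_phon <- sp$key2007 == q_epithet_key
    gm <- match(sp$genus_id, g$id)
    sp_g_ed <- g_ed[gm]
    sp_g_phon <- g_phon[gm]
    keep <- species_postfilter(
      sp_g_ed, e_ed, e_phon,
      pmin(nchar(q_epithet), sp$len),
      substr(sp$epithet_norm, 1, 1) == substr(q_epithet, 1, 1),
      substr(sp$epithet_norm, 1, 3) == substr(q_epithet, 1, 3))
    sp <- sp[keep, , drop = FALSE]
    e_ed <- e_ed[keep]
    e_phon <- e_phon[keep]
    sp_g_ed <- sp_g_ed[keep]
    sp_g_phon <- sp_g_phon[keep]
  }

  if (n_ep && nrow(sp)) {
    gname <- g$name_raw[match(sp$genus_id, g$id)]
    cands <- data.frame(
      name = paste(gname, sp$epithet_raw),
      genus_name = gname, epithet = sp$epithet_raw,
      authority = sp$authority,
      genus_ed = sp_g_ed, epithet_ed = e_ed,
      combined_ed = sp_g_ed + e_ed,
      genus_phonetic = sp_g_phon, epithet_phonetic = e_phon,
      phonetic = sp_g_phon & e_phon, authority_sim = NA_real_,
      stringsAsFactors = FALSE)
  } else {
    cands <- empty_candidates()
  }

  if (!is.null(query_authority) && nrow(cands)) {
    cands$authority_sim <- vapply(cands$authority, function(a)
      authority_similarity(query_authority, a, config$abbrevs), numeric(1))
  }

  exact <- cands[cands$combined_ed == 0, , drop = FALSE]
  near <- cands[cands$combined_ed > 0, , drop = FALSE]
  if (config$mode != "no_shaping") near <- shape_results(near, "species")
  rk <- rank_results(near, "species")
  rownames(exact) <- NULL
  make_report(parsed, config$mode, exact, rk$nearest, rk$other,
              n_pref, n_ep, proc.time()[["elapsed"]] - t0)
}

#' Match one name against a reference index
#'
#' Runs the full pipeline: parsing and normalization, the genus pre-filter
#' over all unmasked genera (phonetic rules only in rapid mode; optional
#' restriction to a group label), the genus block-transposition edit
#' distance on survivors, the genus post-filter; then, for binomial
#' queries, the species pre-filter, epithet distance and species
#' post-filter; authority similarity where both sides carry an authority;
#' result shaping (unless disabled) and ranking. Exact (distance 0)
#' matches are reported separately from near matches.
#'
#' @param raw A raw name string, or a `parsed_name` object for
#'   pre-atomized input.
#' @param index A `taxmatch_index` from [build_index()].
#' @param config An [engine_config()].
#' @return A `match_report`: list with `query`, `mode`, `exact`,
#'   `nearest`, `other` candidate data.frames, the pre-filter selectivity
#'   counts `n_genera_prefiltered` and `n_epithets_tested`, and `elapsed`
#'   seconds. On parse failure the report has empty candidates and a
#'   `failure` reason.
#' @export
match_name <- function(raw, index, config = engine_config()) {
  stopifnot(inherits(index, "taxmatch_index"))
  parsed <- if (inherits(raw, "parsed_name")) raw else parse_name(raw)
  if (is_parse_failure(parsed)) {
    return(make_report(raw, config$mode, empty_candidates(),
                       empty_candidates(), empty_candidates(), 0L, 0L, 0,
                       failure = parsed$reason))
  }
  match_parsed(parsed, index, config)
}

#' Match a list of names
#'
#' Vectorized front end to [match_name()]. Hybrid formulae (two parent
#' names joined by a hybrid sign) are split and each parent matched
#' separately.
#'
#' @param raws Character vector of raw names.
#' @inheritParams match_name
#' @return List of `match_report` objects.
#' @export
match_names <- function(raws, index, config = engine_config()) {
  parts <- unlist(lapply(raws, split_hybrid_formula), use.names = FALSE)
  lapply(parts, match_name, index = index, config = config)
}

#' Naive brute-force matcher (verification oracle)
#'
#' Applies pre-filter, edit distance, post-filter, shaping and ranking to
#' every record of the index in a plain loop, recomputing normalization
#' and phonetic keys from the raw strings and using no precomputed
#' columns, length shortcuts or early abandoning. Intended for small
#' indexes; its output must equal [match_name()] exactly -- the index is
#' an optimization, never a semantics change.
#'
#' @inheritParams match_name
#' @return A `match_report`.
#' @export
brute_force_match <- function(raw, index, config = engine_config()) {
  stopifnot(inherits(index, "taxmatch_index"))
  parsed <- if (inherits(raw, "parsed_name")) raw else parse_name(raw)
  if (is_parse_failure(parsed)) {
    return(make_report(raw, config$mode, empty_candidates(),
                       empty_candidates(), empty_candidates(), 0L, 0L, 0,
                       failure = parsed$reason))
  }
  t0 <- proc.time()[["elapsed"]]

  q_genus <- normalize_word(parsed$genus_raw)
  q_genus_key <- phonetic_key(q_genus, 2007, is_epithet = FALSE)
  q_epithet <- NULL
  q_epithet_key <- NULL
  if (!is.null(parsed$epithet_raw)) {
    q_epithet <- normalize_word(parsed$epithet_raw)
    q_epithet_key <- phonetic_key(q_epithet, 2007, is_epithet = TRUE)
  }

  genera <- index$genera
  species <- index$species
  n_pref <- 0L
  n_ep <- 0L
  rows <- list()

  for (i in seq_len(nrow(genera))) {
    if (genera$masked[i]) next
    if (!is.null(config$group) &&
        !(config$group %in% index$genus_groups[[i]])) next
    gn <- normalize_word(genera$name_raw[i])
    gk <- phonetic_key(gn, 2007, is_epithet = FALSE)
    has_key <- FALSE
    if (!is.null(q_epithet_key)) {
      kids <- species[species$genus_id == genera$id[i] & !species$masked, ,
                      drop = FALSE]
      for (e in kids$epithet_raw) {
        if (phonetic_key(normalize_word(e), 2007, TRUE) == q_epithet_key) {
          has_key <- TRUE
          break
        }
      }
    }
    pf <- genus_prefilter(q_genus, q_genus_key, q_epithet_key,
                          gn, gk, has_key, rapid = config$mode == "rapid")
    if (!pf$pass) next
    n_pref <- n_pref + 1L
    ged <- edit_distance(q_genus, gn, block_limit = config$genus_block_limit)
    if (!genus_postfilter(ged, pf$phonetic, nchar(q_genus), nchar(gn),
                          substr(gn, 1, 1) == substr(q_genus, 1, 1))) next

    if (is.null(q_epithet)) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = genera$name_raw[i], genus_name = genera$name_raw[i],
        epithet = NA_character_, authority = genera$authority[i],
        genus_ed = ged, epithet_ed = NA_real_, combined_ed = ged,
        genus_phonetic = pf$phonetic, epithet_phonetic = NA,
        phonetic = pf$phonetic, authority_sim = NA_real_,
        stringsAsFactors = FALSE)
      next
    }

    kids <- species[species$genus_id == genera$id[i] & !species$masked, ,
                    drop = FALSE]
    for (j in seq_len(nrow(kids))) {
      en <- normalize_word(kids$epithet_raw[j])
      if (!species_prefilter(nchar(q_epithet), nchar(en), TRUE)) next
      n_ep <- n_ep + 1L
      eed <- edit_distance(q_epithet, en,
                           block_limit = config$species_block_limit)
      ephon <- phonetic_key(en, 2007, TRUE) == q_epithet_key
      if (!species_postfilter(ged, eed, ephon,
                              min(nchar(q_epithet), nchar(en)),
                              substr(en, 1, 1) == substr(q_epithet, 1, 1),
                              substr(en, 1, 3) == substr(q_epithet, 1, 3)))
        next
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste(genera$name_raw[i], kids$epithet_raw[j]),
        genus_name = genera$name_raw[i], epithet = kids$epithet_raw[j],
        authority = kids$authority[j],
        genus_ed = ged, epithet_ed = eed, combined_ed = ged + eed,
        genus_phonetic = pf$phonetic, epithet_phonetic = ephon,
        phonetic = pf$phonetic && ephon, authority_sim = NA_real_,
        stringsAsFactors = FALSE)
    }
  }

  cands <- if (length(rows)) do.call(rbind, rows) else empty_candidates()
  if (!is.null(parsed$authority_raw) && nrow(cands)) {
    cands$authority_sim <- vapply(cands$authority, function(a)
      authority_similarity(parsed$authority_raw, a, config$abbrevs),
      numeric(1))
  }
  level <- if (is.null(q_epithet)) "genus" else "species"
  exact <- cands[cands$combined_ed == 0, , drop = FALSE]
  near <- cands[cands$combined_ed > 0, , drop = FALSE]
  if (config$mode != "no_shaping") near <- shape_results(near, level)
  rk <- rank_results(near, level)
  rownames(exact) <- NULL
  make_report(parsed, config$mode, exact, rk$nearest, rk$other,
              n_pref, n_ep, proc.time()[["elapsed"]] - t0)
}
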