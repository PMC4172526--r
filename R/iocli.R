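# Delimited-file input/output and the command-line entry point.

# Darwin-Core-style column aliases accepted in reference files
.col_aliases <- list(
  scientific_name = c("scientific_name", "scientificname", "scientificName"),
  genus = c("genus"),
  epithet = c("epithet", "specific_epithet", "specificepithet",
              "specificEpithet", "species"),
  authority = c("authority", "authorship", "scientificnameauthorship",
                "scientificNameAuthorship"),
  status = c("status", "taxonomicstatus", "taxonomicStatus"),
  group = c("group", "group_label", "higherclassification",
            "higherClassification")
)

#' Read a reference checklist from a delimited file
#'
#' Reads a TSV or CSV file with a header row and maps Darwin-Core-style
#' column names (`scientificName`, `genus`, `specificEpithet`,
#' `scientificNameAuthorship`, `taxonomicStatus`) onto the canonical
#' columns `scientific_name`/`genus`/`epithet`/`authority`/`status`/
#' `group`. Either a `genus` column or a `scientific_name` column is
#' mandatory. Rows whose status flags them as misspellings, nomina nuda
#' or later usages carry a mask flag through [build_index()].
#'
#' @param path Path to the file (separator auto-detected).
#' @return A data.frame of reference rows.
#' @export
read_reference <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "auto",
                          colClasses = "character", data.table = FALSE)
  out <- data.frame(row = seq_len(nrow(dt)))
  for (canon in names(.col_aliases)) {
    hit <- which(tolower(names(dt)) %in% tolower(.col_aliases[[canon]]))
    if (length(hit)) out[[canon]] <- dt[[hit[1]]]
  }
  out$row <- NULL
  if (!any(c("genus", "scientific_name") %in% names(out)))
    stop("read_reference: no 'genus' or 'scientificName' column in ", path,
         " (found: ", paste(names(dt), collapse = ", "), ")")
  for (col in names(out)) out[[col]][out[[col]] == ""] <- NA_character_
  out
}

report_to_rows <- function(rep_) {
  q <- if (inherits(rep_$query, "parsed_name")) {
    paste(c(rep_$query$genus_raw, rep_$query$epithet_raw), collapse = " ")
  } else as.character(rep_$query)
  base <- data.frame(
    query = q,
    n_genera_prefiltered = rep_$n_genera_prefiltered,
    n_epithets_tested = rep_$n_epithets_tested,
    elapsed = round(rep_$elapsed, 4),
    stringsAsFactors = FALSE)
  groups <- list(exact = rep_$exact, nearest = rep_$nearest,
                 other = rep_$other)
  rows <- list()
  for (gname in names(groups)) {
    df <- groups[[gname]]
    for (i in seq_len(nrow(df))) {
      ed_fmt <- if (is.na(df$epithet_ed[i])) {
        as.character(df$genus_ed[i])
      } else paste0(df$genus_ed[i], ",", df$epithet_ed[i])
      rows[[length(rows) + 1L]] <- cbind(base, data.frame(
        match = df$name[i],
        authority = if (is.na(df$authority[i])) "" else df$authority[i],
        edit_distance = ed_fmt,
        phonetic = df$phonetic[i],
        authority_similarity = if (is.na(df$authority_sim[i])) "" else
          sprintf("%.4f", df$authority_sim[i]),
        rank_group = gname,
        stringsAsFactors = FALSE))
    }
  }
  if (!length(rows)) {
    return(cbind(base, data.frame(
      match = "", authority = "", edit_distance = "", phonetic = NA,
      authority_similarity = "", rank_group = "",
      stringsAsFactors = FALSE)))
  }
  do.call(rbind, rows)
}

#' Write match reports to a delimited or JSON file
#'
#' One output row per candidate: query, matched name, authority, edit
#' distance in the `"x,y"` genus,epithet format, phonetic flag, authority
#' similarity (blank when undefined), rank group (exact/nearest/other),
#' plus the per-query pre-filter selectivity counts and elapsed time. A
#' query with zero candidates yields a single row with empty match
#' fields. The JSON format mirrors the same schema.
#'
#' @param reports A `match_report` or list of them.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, the flat data.frame written.
#' @export
write_report <- function(reports, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(reports, "match_report")) reports <- list(reports)
  flat <- do.call(rbind, lapply(reports, report_to_rows))
  flat <- flat[, c("query", "match", "authority", "edit_distance",
                   "phonetic", "authority_similarity", "rank_group",
                   "n_genera_prefiltered", "n_epithets_tested", "elapsed")]
  if (format == "tsv") {
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(flat, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(flat)
}

cli_usage <- function() {
  cat("usage: taxmatch <command> [options]\n",
      "commands:\n",
      "  match     --reference FILE (--name NAME | --input-list FILE) --out FILE\n",
      "  dedupe    --reference FILE --out FILE\n",
      "  evaluate  --reference FILE --n-cases N --out FILE\n",
      "shared options: --mode {normal,no-shaping,rapid} --group LABEL\n",
      "  --genus-block-limit K --species-block-limit K --abbrev-file FILE\n",
      "  --seed N --format {tsv,json}\n", sep = "")
}

parse_cli_args <- function(args) {
  opts <- list(mode = "normal", format = "tsv", seed = 1L,
               genus_block_limit = 2L, species_block_limit = 4L)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    key <- sub("^--", "", a)
    key <- gsub("-", "_", key)
    if (startsWith(a, "--")) {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    } else {
      opts$command <- a
      i <- i + 1L
    }
  }
  opts
}

#' Command-line entry point
#'
#' Drives the matcher from the command line; see `inst/cli/taxmatch.R`
#' for the launcher script. Subcommands: `match` (single name or a list
#' file, one name per line), `dedupe` (all-against-all near matching of a
#' reference file against itself, reporting non-exact hits) and
#' `evaluate` (synthetic benchmark: per-error-type recall table).
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the primary result object of the subcommand.
#' @export
taxmatch_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  opts <- parse_cli_args(args)
  if (is.null(opts$command)) {
    cli_usage()
    return(invisible(NULL))
  }
  mode <- gsub("-", "_", opts$mode)
  abbrevs <- if (!is.null(opts$abbrev_file)) {
    read_abbrev_table(opts$abbrev_file)
  } else default_abbrev_table()
  config <- engine_config(mode = mode, group = opts$group,
                          genus_block_limit = as.integer(opts$genus_block_limit),
                          species_block_limit = as.integer(opts$species_block_limit),
                          abbrevs = abbrevs)

  if (opts$command == "match") {
    index <- build_index(read_reference(opts$reference))
    names_in <- if (!is.null(opts$name)) opts$name else
      readLines(opts$input_list, warn = FALSE)
    names_in <- names_in[nzchar(trimws(names_in))]
    reports <- match_names(names_in, index, config)
    write_report(reports, opts$out, opts$format)
    message(length(reports), " quer",
            if (length(reports) == 1) "y" else "ies", " written to ",
            opts$out)
    return(invisible(reports))
  }

  if (opts$command == "dedupe") {
    rows <- read_reference(opts$reference)
    index <- build_index(rows)
    qnames <- c(index$genera$name_raw[!index$genera$masked &
                                        !(index$genera$id %in%
                                            index$species$genus_id)],
                paste(index$genera$name_raw[match(index$species$genus_id,
                                                  index$genera$id)],
                      index$species$epithet_raw)[!index$species$masked])
    reports <- lapply(qnames, match_name, index = index, config = config)
    # self-hits are exact matches by construction; near hits flag dupes
    dup <- Filter(function(r) nrow(r$nearest) + nrow(r$other) > 0, reports)
    write_report(dup, opts$out, opts$format)
    message(length(dup), " name(s) with near-duplicate candidates of ",
            length(qnames), " tested; written to ", opts$out)
    return(invisible(dup))
  }

  if (opts$command == "evaluate") {
    seed <- as.integer(opts$seed)
    n_cases <- if (!is.null(opts$n_cases)) as.integer(opts$n_cases) else 60L
    rows <- if (!is.null(opts$reference)) read_reference(opts$reference) else
      generate_reference(50, 4, seed = seed)
    index <- build_index(rows)
    sp_rows <- rows[!is.na(rows$epithet), , drop = FALSE]
    names_all <- paste(sp_rows$genus, sp_rows$epithet)
    types <- c("1a", "1b", "1c", "2", "3", "4")
    per_type <- ceiling(n_cases / length(types))
    cases <- list()
    restore <- local_seed(seed)
    on.exit(restore())
    for (ty in types) {
      picks <- sample(names_all, per_type, replace = per_type > length(names_all))
      for (k in seq_along(picks)) {
        cases[[length(cases) + 1L]] <- generate_misspelling(
          picks[k], ty, seed = sample.int(2^31 - 1, 1))
      }
    }
    res <- evaluate_cases(cases, index, config)
    tab <- data.frame(error_type = names(res$by_error_type),
                      recall = as.numeric(res$by_error_type))
    utils::write.table(tab, opts$out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    message(sprintf(
      "recall %.3f precision %.3f F1 %.3f over %d cases; table in %s",
      res$recall, res$precision, res$f1, res$n_cases, opts$out))
    return(invisible(res))
  }

  cli_usage()
  stop("unknown command: ", opts$command)
}
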