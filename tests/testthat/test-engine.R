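test_that("build_index precomputes, dedupes and masks", {
  idx <- build_index(fixture_rows())
  expect_s3_class(idx, "taxmatch_index")
  # Asura striata appears twice -> collapsed with a warning
  expect_warning(build_index(rbind(fixture_rows(), fixture_rows())),
                 "duplicate")
  expect_equal(nrow(idx$genera), 8)
  expect_equal(nrow(idx$species), 7)
  # genus with zero species is retained and matchable at genus level
  r <- match_name("Homa", idx)
  expect_true("Homo" %in% c(r$exact$name, r$nearest$name, r$other$name))
  # masked rows are never returned
  rows <- fixture_rows()
  rows$status <- NA_character_
  rows <- rbind(rows, data.frame(genus = "Halymenia", epithet = "dilitata",
                                 authority = NA, status = "misspelling",
                                 stringsAsFactors = FALSE))
  idx2 <- build_index(rows)
  r <- match_name("Halymenia dilitata", idx2)
  expect_false("Halymenia dilitata" %in%
                 c(r$exact$name, r$nearest$name, r$other$name))
  expect_true("Halymenia dilatata" %in% r$nearest$name)
})

test_that("build_index accepts full scientific-name strings", {
  rows <- data.frame(
    scientific_name = c("Fagus sylvatica L.", "Fagus orientalis Lipsky",
                        "Homo"),
    stringsAsFactors = FALSE)
  idx <- build_index(rows)
  expect_equal(nrow(idx$genera), 2)
  expect_equal(nrow(idx$species), 2)
  expect_equal(idx$species$authority[1], "L.")
})

test_that("near matching mirrors the published search example", {
  idx <- build_index(fixture_rows())
  r <- match_name("Halymenia dilitata Zanardini", idx)
  expect_setequal(r$nearest$name,
                  c("Halymenia dilatata", "Halymenia digitata"))
  expect_equal(r$nearest$genus_ed, c(0, 0))
  expect_equal(r$nearest$epithet_ed, c(1, 1))
  # alphabetic ordering within the group
  expect_equal(r$nearest$name, sort(r$nearest$name))
  # authority similarity reported for both, higher for the true source
  expect_true(all(!is.na(r$nearest$authority_sim)))
  sim <- setNames(r$nearest$authority_sim, r$nearest$name)
  expect_gt(sim[["Halymenia dilatata"]], sim[["Halymenia digitata"]])
})

test_that("exact queries report a single exact match", {
  idx <- build_index(fixture_rows())
  r <- match_name("Peronella lesueuri", idx)
  expect_equal(r$exact$name, "Peronella lesueuri")
  expect_equal(nrow(r$nearest) + nrow(r$other), 0)
  expect_equal(r$exact$combined_ed, 0)
})

test_that("result shaping suppresses distant hits only when closer exist", {
  idx <- build_index(fixture_rows())
  # designated target at combined ED 4 masked by a false hit at ED 2
  r <- match_name("Aleura scripta", idx)
  expect_equal(c(r$nearest$name, r$other$name), "Asura scripta")
  r2 <- match_name("Aleura scripta", idx, engine_config(mode = "no_shaping"))
  expect_true("Aleuron scriptor" %in% r2$other$name)
  expect_true(all(c("Alesia striata", "Asura striata") %in% r2$other$name))
  # shaping never drops ED <= 2 or phonetic candidates
  kept <- c(r$exact$name, r$nearest$name, r$other$name)
  all2 <- rbind(r2$exact, r2$nearest, r2$other)
  must_keep <- all2$name[all2$combined_ed <= 2 | all2$phonetic]
  expect_true(all(must_keep %in% kept))
})

test_that("shape_results applies the distance ladder per level", {
  mk <- function(ed, phon = FALSE) {
    data.frame(name = if (length(ed)) paste0("N", seq_along(ed)) else
                 character(0),
               combined_ed = as.numeric(ed),
               phonetic = rep_len(phon, length(ed)),
               stringsAsFactors = FALSE)
  }
  expect_equal(shape_results(mk(c(2, 3)), "species")$combined_ed, 2)
  expect_equal(shape_results(mk(4), "species")$combined_ed, 4)
  expect_equal(shape_results(mk(c(3, 4)), "species")$combined_ed, 3)
  expect_equal(nrow(shape_results(mk(numeric(0)), "species")), 0)
  expect_equal(shape_results(mk(c(1, 2)), "genus")$combined_ed, 1)
  expect_equal(shape_results(mk(c(2, 3)), "genus")$combined_ed, 2)
  # phonetic candidates survive any shaping
  got <- shape_results(mk(c(1, 4), phon = c(FALSE, TRUE)), "species")
  expect_equal(got$combined_ed, c(1, 4))
})

test_that("ranking groups ED 1 plus phonetic as nearest, rest as other", {
  cands <- data.frame(
    name = c("B one", "A two", "C phon"),
    combined_ed = c(1, 3, 2),
    phonetic = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  rk <- rank_results(cands, "species")
  expect_equal(rk$nearest$name, c("B one", "C phon"))
  expect_equal(rk$other$name, "A two")
})

test_that("uninomial queries run the genus-level pipeline", {
  idx <- build_index(fixture_rows())
  r <- match_name("Ficus", idx)
  expect_equal(r$exact$name, "Ficus")
  expect_true("Fucus" %in% r$nearest$name)  # ED 1
  expect_equal(r$n_epithets_tested, 0)
})

test_that("parse failures yield an explicit empty report", {
  idx <- build_index(fixture_rows())
  r <- match_name("", idx)
  expect_equal(nrow(r$exact) + nrow(r$nearest) + nrow(r$other), 0)
  expect_false(is.null(r$failure))
})

test_that("optimized engine equals the brute-force engine on synthetic queries", {
  rows <- generate_reference(30, 3, seed = 101)
  idx <- build_index(rows)
  sp_names <- paste(rows$genus, rows$epithet)[!is.na(rows$epithet)]
  set.seed(102)
  queries <- character(0)
  for (ty in c("1a", "1b", "1c", "2", "3", "4")) {
    for (nm in sample(sp_names, 6)) {
      queries <- c(queries, generate_misspelling(
        nm, ty, seed = sample.int(2^31 - 1, 1))$misspelled)
    }
  }
  queries <- c(queries, sample(sp_names, 5), sample(rows$genus, 5))
  cols <- c("name", "genus_ed", "epithet_ed", "combined_ed", "phonetic")
  for (mode in c("normal", "no_shaping", "rapid")) {
    cfg <- engine_config(mode = mode)
    for (q in queries) {
      a <- match_name(q, idx, cfg)
      b <- brute_force_match(q, idx, cfg)
      for (part in c("exact", "nearest", "other")) {
        expect_equal(a[[part]][cols], b[[part]][cols],
                     info = paste(mode, q, part))
      }
      expect_equal(a$n_genera_prefiltered, b$n_genera_prefiltered,
                   info = paste(mode, q))
      expect_equal(a$n_epithets_tested, b$n_epithets_tested,
                   info = paste(mode, q))
      expect_lte(a$n_genera_prefiltered, nrow(idx$genera))
    }
  }
})

test_that("rapid-mode candidates are a subset of normal-mode candidates", {
  rows <- generate_reference(25, 3, seed = 103)
  idx <- build_index(rows)
  sp_names <- paste(rows$genus, rows$epithet)[!is.na(rows$epithet)]
  set.seed(104)
  for (nm in sample(sp_names, 12)) {
    q <- generate_misspelling(nm, sample(c("1a", "1b", "2"), 1),
                              seed = sample.int(2^31 - 1, 1))$misspelled
    rn <- match_name(q, idx, engine_config(mode = "no_shaping"))
    rr <- match_name(q, idx, engine_config(mode = "rapid"))
    normal_names <- c(rn$exact$name, rn$nearest$name, rn$other$name)
    rapid_names <- c(rr$exact$name, rr$nearest$name, rr$other$name)
    # rapid shapes too; compare its pre-shaping candidate pool via the
    # prefilter count and final names against the unshaped normal pool
    expect_true(all(rapid_names %in% normal_names), info = q)
    expect_lte(rr$n_genera_prefiltered, rn$n_genera_prefiltered)
  }
})

test_that("single-edit recall guarantee holds across an ED-1 sweep", {
  rows <- generate_reference(15, 3, seed = 105)
  idx <- build_index(rows)
  sp <- rows[!is.na(rows$epithet), ][1:6, ]
  for (i in seq_len(nrow(sp))) {
    g <- toupper(sp$genus[i])
    e <- toupper(sp$epithet[i])
    target <- paste(sp$genus[i], sp$epithet[i])
    set.seed(200 + i)
    g_vars <- sample(ed1_neighborhood(g), 6)
    e_vars <- sample(ed1_neighborhood(e), 6)
    g_vars <- g_vars[nchar(g_vars) >= 2]
    e_vars <- e_vars[nchar(e_vars) >= 2]
    qs <- c(paste(taxmatch:::title_case(tolower(g_vars)), tolower(e)),
            paste(sp$genus[i], tolower(e_vars)))
    for (q in qs) {
      r <- match_name(q, idx)
      expect_true(target %in% c(r$exact$name, r$nearest$name, r$other$name),
                  info = paste(q, "->", target))
    }
  }
})

test_that("group restriction limits matching to labelled genera", {
  rows <- fixture_rows()
  rows$group <- c(rep("Rhodophyta", 2), rep("Lepidoptera", 4), "Echinodermata",
                  "Phaeophyceae", "Magnoliophyta", "Mammalia")
  idx <- build_index(rows)
  r <- match_name("Halymenia dilitata", idx,
                  engine_config(group = "Rhodophyta"))
  expect_equal(nrow(r$nearest), 2)
  r <- match_name("Halymenia dilitata", idx,
                  engine_config(group = "Lepidoptera"))
  expect_equal(nrow(r$exact) + nrow(r$nearest) + nrow(r$other), 0)
})
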