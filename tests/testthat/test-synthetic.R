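test_that("generate_reference is deterministic with the stated shape", {
  rows <- generate_reference(10, 3, seed = 1)
  expect_equal(length(unique(rows$genus)), 10)
  expect_equal(nrow(rows), 30)
  expect_identical(generate_reference(10, 3, seed = 1), rows)
  expect_false(identical(generate_reference(10, 3, seed = 2), rows))
  # lengths and endings follow the stated word model
  expect_true(all(nchar(rows$genus) >= 4 & nchar(rows$genus) <= 16))
  expect_true(all(nchar(rows$epithet) >= 4 & nchar(rows$epithet) <= 14))
  expect_true(all(grepl("(us|a|um|is)$", rows$epithet)))
  # pure ASCII: normalization is lossless up to case
  expect_identical(normalize_word(rows$genus), toupper(rows$genus))
  expect_identical(normalize_word(rows$epithet), toupper(rows$epithet))
})

test_that("zero species per genus yields genus-only rows", {
  rows <- generate_reference(5, 0, seed = 3)
  expect_equal(nrow(rows), 5)
  expect_true(all(is.na(rows$epithet)))
})

test_that("misspellings honour their type's distance contract", {
  rows <- generate_reference(15, 2, seed = 7)
  nms <- paste(rows$genus, rows$epithet)
  set.seed(8)
  for (ty in c("1a", "1b")) {
    for (k in 1:15) {
      cs <- generate_misspelling(sample(nms, 1), ty,
                                 seed = sample.int(2^31 - 1, 1))
      pm <- parse_name(cs$misspelled)
      pc <- parse_name(cs$correct)
      dg <- edit_distance(normalize_word(pm$genus_raw),
                          normalize_word(pc$genus_raw), 1)
      de <- edit_distance(normalize_word(pm$epithet_raw),
                          normalize_word(pc$epithet_raw), 1)
      expect_equal(sort(c(dg, de)), c(0, 1), info = cs$misspelled)
      expect_false(cs$misspelled == cs$correct)
    }
  }
  # type 4 touches both words
  for (k in 1:10) {
    cs <- generate_misspelling(sample(nms, 1), "4",
                               seed = sample.int(2^31 - 1, 1))
    pm <- parse_name(cs$misspelled)
    pc <- parse_name(cs$correct)
    expect_false(normalize_word(pm$genus_raw) ==
                   normalize_word(pc$genus_raw))
    expect_false(normalize_word(pm$epithet_raw) ==
                   normalize_word(pc$epithet_raw))
  }
  # 1b never touches the first character
  for (k in 1:10) {
    cs <- generate_misspelling(sample(nms, 1), "1b",
                               seed = sample.int(2^31 - 1, 1))
    expect_equal(substr(cs$misspelled, 1, 1), substr(cs$correct, 1, 1))
  }
})

test_that("classify_error reproduces the published examples", {
  cls <- classify_error("Peneus", "Penaeus")
  expect_equal(cls$label, "1a")
  expect_true(cls$phonetic)
  cls <- classify_error("Acropaginula", "Arcopaginula")
  expect_equal(cls$label, "1b")
  expect_false(cls$phonetic)
  # gender variant: an epithet-ending change that is phonetic
  cls <- classify_error("Neocrex columbianus", "Neocrex columbiana")
  expect_true(cls$phonetic)
  expect_error(classify_error("Homo", "Homo"), "identical")
  expect_error(classify_error("Homo sapiens", "Homo"), "structure")
})

test_that("generator and classifier agree on a seeded round-trip", {
  rows <- generate_reference(20, 3, seed = 11)
  nms <- paste(rows$genus, rows$epithet)
  types <- c("1a", "1b", "1c", "2", "3", "4")
  set.seed(12)
  for (k in 1:200) {
    ty <- sample(types, 1)
    cs <- generate_misspelling(sample(nms, 1), ty,
                               seed = sample.int(2^31 - 1, 1))
    expect_equal(classify_error(cs$misspelled, cs$correct)$label, ty)
    expect_equal(cs$error_type$label, ty)
  }
})

test_that("misspelling generation is deterministic under a fixed seed", {
  a <- generate_misspelling("Peronella lesueuri", "2", seed = 99)
  b <- generate_misspelling("Peronella lesueuri", "2", seed = 99)
  expect_identical(a$misspelled, b$misspelled)
})

test_that("type 4 requires a binomial and infeasible requests error", {
  expect_error(generate_misspelling("Homo", "4"), "binomials")
  expect_error(generate_misspelling("Aba", "3"), "too short")
})

test_that("evaluation metrics: exact queries score 1 and F1 is harmonic", {
  rows <- generate_reference(12, 2, seed = 13)
  idx <- build_index(rows)
  nms <- paste(rows$genus, rows$epithet)
  cases <- lapply(nms[1:10], function(n) {
    structure(list(correct = n, misspelled = n,
                   error_type = list(label = "0", phonetic = TRUE),
                   seed = 0), class = "synthetic_case")
  })
  res <- evaluate_cases(cases, idx)
  expect_equal(res$recall, 1)
  expect_equal(res$precision, 1)
  expect_equal(res$f1, 1)
  # F1 definition on a mixed outcome
  cases2 <- c(cases[1:5], list(structure(
    list(correct = "Zzzz zzzz", misspelled = "Qqqq qqqq",
         error_type = list(label = "3", phonetic = FALSE), seed = 0),
    class = "synthetic_case")))
  res2 <- evaluate_cases(cases2, idx)
  expect_equal(res2$f1,
               2 * res2$precision * res2$recall /
                 (res2$precision + res2$recall))
  expect_lt(res2$recall, 1)
  expect_error(evaluate_cases(list(), idx), "empty")
})
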