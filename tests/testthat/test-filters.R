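gpf <- function(qg, tg, q_ep_key = NULL, has_key = FALSE, rapid = FALSE) {
  genus_prefilter(qg, phonetic_key(qg, 2007), q_ep_key,
                  tg, phonetic_key(tg, 2007), has_key, rapid = rapid)
}

test_that("genus pre-filter rules 1a-1c behave as specified", {
  r <- gpf("SIGONUS", "SIGANUS")
  expect_true(r$pass)
  expect_equal(r$rule, "1a")
  expect_true(r$phonetic)

  expect_true(gpf("PERONELLA", "PERONELLA")$pass)

  # no shared first/last char, different keys, no epithet help
  r <- gpf("HOMO", "XYZQ")
  expect_false(r$pass)

  # rule 1b: epithet key present in the genus, length gap <= 3
  r <- genus_prefilter("ABCDEFGH", phonetic_key("ABCDEFGH", 2007), "KEY",
                       "ZYXWVUTS", phonetic_key("ZYXWVUTS", 2007), TRUE)
  expect_true(r$pass)
  expect_equal(r$rule, "1b")
  r <- genus_prefilter("ABCD", phonetic_key("ABCD", 2007), "KEY",
                       "ZYXWVUTS", phonetic_key("ZYXWVUTS", 2007), TRUE)
  expect_false(r$pass)  # length gap 4 defeats 1b, and 1c needs gap <= 2

  # rule 1c length bands: m < 5 first OR last char; m == 5 first 2 OR last
  # 3; m >= 6 first 3 OR last 3
  expect_true(gpf("HOMO", "HYZO")$pass)    # last char
  expect_false(gpf("HOMO", "KYZQ")$pass)
  expect_true(gpf("HOMOS", "HOZZZ")$pass)  # first 2 of a 5-char word
  expect_false(gpf("HOMOS", "HYZZZ")$pass) # first 2 fail, last 3 fail
  expect_true(gpf("PANULIRUS", "PANZZZZUS")$pass)  # first 3
  expect_false(gpf("PAQULIRUS", "PAZZZIFUS")$pass) # first 3 fail, last 3 fail
})

test_that("rapid mode keeps only the phonetic rules", {
  expect_true(gpf("HOMO", "HYZO")$pass)
  expect_false(gpf("HOMO", "HYZO", rapid = TRUE)$pass)
  expect_true(gpf("SIGONUS", "SIGANUS", rapid = TRUE)$pass)
})

test_that("genus post-filter rules 3a-3c", {
  expect_false(genus_postfilter(4, FALSE, 9, 9, TRUE))    # 3a
  expect_true(genus_postfilter(3, TRUE, 9, 9, FALSE))     # 3b
  expect_false(genus_postfilter(4, TRUE, 9, 9, TRUE))     # 3a beats 3b
  # 3c: initial char must match at ED >= 2
  expect_false(genus_postfilter(2, FALSE, 4, 4, FALSE))
  expect_true(genus_postfilter(2, FALSE, 4, 4, TRUE))
  expect_true(genus_postfilter(1, FALSE, 4, 4, FALSE))
  # 3c length bands on the shorter word
  expect_false(genus_postfilter(2, FALSE, 3, 5, TRUE))
  expect_true(genus_postfilter(2, FALSE, 5, 5, TRUE))
  expect_false(genus_postfilter(3, FALSE, 5, 5, TRUE))
  expect_true(genus_postfilter(3, FALSE, 6, 8, TRUE))
  expect_false(genus_postfilter(Inf, FALSE, 9, 9, TRUE))
})

test_that("species pre-filter rules 4a-4b", {
  expect_true(species_prefilter(9, 9, TRUE))
  expect_false(species_prefilter(9, 14, TRUE))
  expect_false(species_prefilter(9, 9, FALSE))
  expect_true(species_prefilter(9, 13, TRUE))
})

test_that("species post-filter rules 6a-6c", {
  expect_false(species_postfilter(2, 3, FALSE, 9, TRUE, TRUE))   # 6a: 5 > 4
  expect_true(species_postfilter(0, 4, FALSE, 10, TRUE, TRUE))   # 6c ED 4
  expect_false(species_postfilter(0, 4, FALSE, 10, TRUE, FALSE)) # first 3
  expect_true(species_postfilter(2, 0, FALSE, 9, TRUE, TRUE))    # ED 0 passes
  expect_true(species_postfilter(1, 3, TRUE, 2, FALSE, FALSE))   # 6b phonetic
  # 6c bands on the shorter epithet
  expect_false(species_postfilter(0, 2, FALSE, 3, TRUE, TRUE))
  expect_true(species_postfilter(0, 2, FALSE, 4, TRUE, TRUE))
  expect_false(species_postfilter(0, 3, FALSE, 5, TRUE, TRUE))
  expect_true(species_postfilter(0, 3, FALSE, 6, TRUE, TRUE))
  expect_false(species_postfilter(0, 4, FALSE, 7, TRUE, TRUE))
  # initial char requirement at epithet ED 2-3
  expect_false(species_postfilter(0, 2, FALSE, 6, FALSE, FALSE))
})

test_that("structural single-edit guarantee at genus level", {
  # any insertion/deletion/substitution neighbor passes rule 1c (a single
  # such edit cannot disturb both substring bands at once), and the
  # post-filter never rejects ED 1; adjacent transpositions at the band
  # boundary of 5-6 character words can escape 1c but are rescued by rule
  # 1b whenever the query carries an (unchanged) epithet, which is why the
  # single-edit recall guarantee holds for binomials at every position.
  is_transposition <- function(a, b) {
    nchar(a) == nchar(b) && edit_distance(a, b, 1) == 1 &&
      edit_distance(a, b, 0) == 2
  }
  set.seed(41)
  for (k in 1:25) {
    g <- random_word(4, 12)
    for (nb in sample(ed1_neighborhood(g), 8)) {
      pre <- gpf(nb, g, q_ep_key = "ANYKEY", has_key = TRUE)
      expect_true(pre$pass, info = paste(nb, g))
      if (!is_transposition(nb, g)) {
        expect_true(gpf(nb, g)$pass, info = paste("1c:", nb, g))
      }
      ed <- edit_distance(nb, g, block_limit = 2)
      expect_true(genus_postfilter(ed, pre$phonetic, nchar(nb), nchar(g),
                                   substr(nb, 1, 1) == substr(g, 1, 1)),
                  info = paste(nb, g))
    }
  }
  # the documented 1c gap: interior transposition in a 5-char word fails
  # both bands, and rule 1b closes it
  expect_false(gpf("ACBDE", "ABCDE")$pass)
  expect_true(gpf("ACBDE", "ABCDE", q_ep_key = "K", has_key = TRUE)$pass)
})

test_that("pre/post filters never reject identical names", {
  set.seed(43)
  for (k in 1:20) {
    g <- random_word(2, 14)
    expect_true(gpf(g, g)$pass)
    expect_true(genus_postfilter(0, TRUE, nchar(g), nchar(g), TRUE))
    expect_true(species_postfilter(0, 0, TRUE, nchar(g), TRUE, TRUE))
  }
})
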