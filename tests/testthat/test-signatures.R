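test_that("the six-stem pseudoknot yields the published signature chain", {
  s <- fixture_figure3()
  st <- find_stems(s)
  ec <- find_ecrs(s, st)
  top <- ec$id[is.na(ec$parent)]
  expect_equal(full_signature(top, ec, st)$word, "abcdDCefBAFE")
  expect_equal(upper_signature(top, ec, st)$word, "abcdBADC")
  expect_equal(reduced_signature(top, ec, st)$word, "abAB")
})

test_that("the five-stem fixture reduces from ten arc ends to an H-knot", {
  s <- fixture_figure1()
  st <- find_stems(s)
  ec <- find_ecrs(s, st)
  top <- ec$id[is.na(ec$parent)]
  expect_equal(full_signature(top, ec, st)$word, "abcdCDeEAB")
  expect_equal(upper_signature(top, ec, st)$word, "abAB")
  expect_equal(reduced_signature(top, ec, st)$word, "abAB")
})

test_that("named pseudoknot fixtures reduce to their canonical words", {
  words <- list(hknot = "abAB", kissing = "abAcBC", tripleknot = "abcABC")
  classes <- list(hknot = "H_knot", kissing = "kissing_hairpins",
                  tripleknot = "triple_knot")
  fixtures <- list(hknot = fixture_hknot(), kissing = fixture_kissing(),
                   tripleknot = fixture_tripleknot())
  for (nm in names(fixtures)) {
    s <- fixtures[[nm]]
    st <- find_stems(s)
    ec <- find_ecrs(s, st)
    expect_equal(nrow(ec), 1L)
    sig <- reduced_signature(ec$id[[1]], ec, st)
    expect_equal(sig$word, words[[nm]])
    expect_equal(named_class(sig), classes[[nm]])
  }
  expect_equal(named_class("abcdBADC"), "other")
})

test_that("signatures are rejected for classical ECRs and named_class needs reduced level", {
  s <- parse_dotbracket("((..))")
  st <- find_stems(s, "arbitrary")
  ec <- find_ecrs(s, st)
  expect_error(full_signature(ec$id[[1]], ec, st), "defined for pseudoknots")
  s2 <- fixture_hknot()
  st2 <- find_stems(s2)
  ec2 <- find_ecrs(s2, st2)
  expect_error(named_class(full_signature(ec2$id[[1]], ec2, st2)),
               "reduced")
})

test_that("every signature level agrees with the naive end-sorting oracle", {
  for (seed in 1:60) {
    s <- random_structure(seed + 600, pk_prob = 0.6)
    st <- find_stems(s)
    ec <- find_ecrs(s, st)
    for (e in ec$id[ec$kind == "pseudoknotted"]) {
      iv <- c(ec$start[ec$id == e], ec$end[ec$id == e])
      expect_equal(full_signature(e, ec, st)$word,
                   oracle_signature(s, iv, st, "full"))
      expect_equal(upper_signature(e, ec, st)$word,
                   oracle_signature(s, iv, st, "upper"))
      expect_equal(reduced_signature(e, ec, st)$word,
                   oracle_signature(s, iv, st, "reduced"))
    }
  }
})

test_that("signature words pair letters and reductions are idempotent", {
  for (seed in 1:40) {
    s <- random_structure(seed + 60, pk_prob = 0.7)
    st <- find_stems(s)
    ec <- find_ecrs(s, st)
    for (e in ec$id[ec$kind == "pseudoknotted"]) {
      for (fn in list(full_signature, upper_signature, reduced_signature)) {
        sig <- fn(e, ec, st)
        chars <- strsplit(sig$word, "")[[1]]
        expect_equal(length(chars), 2L * nrow(sig$arcs))
        lows <- chars[chars %in% letters]
        ups <- chars[chars %in% LETTERS]
        expect_setequal(toupper(lows), ups)
        # lower-case end precedes its capital
        for (l in lows)
          expect_lt(match(l, chars), match(toupper(l), chars))
        # letters appear in alphabetical order of left ends
        expect_equal(sort(lows), lows[order(match(lows, chars))])
      }
      red <- reduced_signature(e, ec, st)
      again <- knotann:::collapse_parallel_arcs(red$arcs)
      expect_equal(nrow(again), nrow(red$arcs))
      # a reduced pseudoknot always retains a crossing
      expect_true(any(knotann:::arc_crossing_matrix(red$arcs)))
    }
  }
})

test_that("arc letters extend deterministically past one alphabet", {
  expect_equal(knotann:::arc_token(26L, FALSE), "z")
  expect_equal(knotann:::arc_token(27L, FALSE), "a1")
  expect_equal(knotann:::arc_token(27L, TRUE), "A1")
  arcs <- data.frame(left = seq(1, by = 2, length.out = 27),
                     right = seq(60, by = 2, length.out = 27))
  arcs$stems <- as.list(seq_len(27))
  word <- knotann:::arcs_word(arcs)
  expect_true(grepl("\\.a1\\.", paste0(".", word, ".")) ||
                grepl("(^|\\.)a1(\\.|$)", word))
})
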