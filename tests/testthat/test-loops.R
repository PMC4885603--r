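test_that("H-ECRs of the multi-junction fixture stem are the two excluded regions", {
  s <- fixture_figure1()
  st <- find_stems(s)
  he <- find_h_ecrs(s, 1, st)   # stem H, face (9,48)
  expect_equal(nrow(he), 2L)
  expect_equal(he$start, c(18L, 34L))
  expect_equal(he$end, c(31L, 43L))
  expect_equal(he$kind, c("pseudoknotted", "classical"))
  # hairpin-interior stem has none
  Q <- st$id[st$face_i == 34]
  expect_equal(nrow(find_h_ecrs(s, Q, st)), 0L)
})

test_that("a nested helix makes one classical H-ECR for the outer stem", {
  s <- parse_dotbracket("((..((..))..))")
  st <- find_stems(s, "arbitrary")
  he <- find_h_ecrs(s, st$id[st$face_i == 1], st)
  expect_equal(nrow(he), 1L)
  expect_equal(c(he$start, he$end), c(5L, 10L))
  expect_equal(he$kind, "classical")
})

test_that("the fixture multi-junction loop decomposes into its documented sides, faces and wing", {
  s <- fixture_figure1()
  st <- find_stems(s)
  l <- loop_of(s, 1, st)
  expect_equal(l$sides$start, c(11L, 32L, 44L))
  expect_equal(l$sides$end, c(17L, 33L, 46L))
  expect_equal(l$faces$x, c(18L, 34L))
  expect_equal(l$faces$y, c(31L, 43L))
  expect_equal(l$faces$tag, c("pseudoknot_face", "stem_face"))
  expect_equal(nrow(l$wings_contained), 1L)
  expect_equal(c(l$wings_contained$start, l$wings_contained$end),
               c(13L, 15L))
  expect_equal(l$size_class, "multiple_junction")
  expect_equal(l$pk_class, "pseudoknotted")
  expect_equal(l$positions, c(11:18, 31:34, 43:46))
  # the hairpin stem
  lq <- loop_of(s, st$id[st$face_i == 34], st)
  expect_equal(lq$size_class, "hairpin")
  expect_equal(lq$pk_class, "classical")
  expect_equal(lq$positions, 37:40)
})

test_that("hairpins and bulges classify from faces and zero-length sides", {
  s <- parse_dotbracket("((((....))))")
  st <- find_stems(s, "arbitrary")
  l <- loop_of(s, 1, st)
  expect_equal(l$size_class, "hairpin")
  expect_equal(l$pk_class, "classical")
  expect_equal(l$positions, 5:8)
  expect_equal(nrow(l$sides), 1L)

  s2 <- parse_dotbracket("((..((....))))")
  st2 <- find_stems(s2, "arbitrary")
  outer <- loop_of(s2, st2$id[st2$face_i == 1], st2)
  expect_equal(outer$size_class, "bulge")
  expect_equal(outer$sides$start, c(3L, 13L))
  expect_equal(outer$sides$end, c(4L, 12L))
  expect_equal(outer$sides$length, c(2L, 0L))
  expect_equal(outer$faces$tag, "stem_face")

  s3 <- parse_dotbracket("((..((....))..))")
  st3 <- find_stems(s3, "arbitrary")
  expect_equal(loop_of(s3, st3$id[st3$face_i == 1], st3)$size_class,
               "internal")
})

test_that("an internal loop with a pseudoknot face and no wings is isolated", {
  # outer stem encloses an H-knot whose two stems both exit a shared region
  s <- parse_dotbracket("((..((..[[..))..]]..))")
  st <- find_stems(s, "arbitrary")
  outer <- loop_of(s, st$id[st$face_i == 1], st)
  expect_equal(outer$size_class, "internal")
  expect_equal(outer$pk_class, "isolated")
  expect_equal(outer$faces$tag, "pseudoknot_face")
})

test_that("loop membership matches the position-wise belongs predicate", {
  for (seed in 1:60) {
    s <- random_structure(seed + 40, pk_prob = 0.4)
    st <- find_stems(s)
    for (h in st$id)
      expect_identical(loop_of(s, h, st)$positions, oracle_loop(s, h, st))
  }
})

test_that("loops are in bijection with stems and labels are total and exclusive", {
  size_levels <- c("hairpin", "internal", "bulge", "multiple_junction")
  pk_levels <- c("classical", "isolated", "pseudoknotted")
  for (seed in 1:40) {
    s <- random_structure(seed + 77, pk_prob = 0.5)
    ann <- annotate_structure(s)
    expect_equal(length(ann$loops), nrow(ann$stems))
    expect_setequal(vapply(ann$loops, `[[`, 1L, "owner"), ann$stems$id)
    for (l in ann$loops) {
      expect_true(l$size_class %in% size_levels)
      expect_true(l$pk_class %in% pk_levels)
      # axis consistency with raw counts
      nf <- nrow(l$faces)
      if (nf == 0L) expect_equal(l$size_class, "hairpin")
      if (nf >= 2L) expect_equal(l$size_class, "multiple_junction")
      if (l$pk_class == "pseudoknotted")
        expect_gt(nrow(l$wings_contained), 0L)
      if (l$pk_class == "classical") {
        expect_equal(nrow(l$wings_contained), 0L)
        expect_false(any(l$faces$tag == "pseudoknot_face"))
      }
    }
  }
})

test_that("pseudoknot-free decompositions equal the classical NNM oracle", {
  for (seed in 1:50) {
    s <- random_structure(seed + 300, pk_prob = 0)
    st <- find_stems(s)
    nnm <- oracle_nnm_loops(s, st)
    for (h in st$id) {
      l <- loop_of(s, h, st)
      o <- nnm[[as.character(h)]]
      expect_identical(l$positions, o$positions)
      expect_identical(l$sides$start, o$sides$start)
      expect_identical(l$sides$end, o$sides$end)
      expect_identical(l$size_class, o$size_class)
      expect_identical(l$pk_class, "classical")
    }
  }
})
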