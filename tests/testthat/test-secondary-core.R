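test_that("pair classification is symmetric and follows the complementarity table", {
  cases <- list(c("G", "C", "watson_crick"), c("A", "U", "watson_crick"),
                c("U", "G", "wobble"), c("A", "G", "other"),
                c("N", "U", "other"), c("A", "A", "other"))
  for (cs in cases) {
    expect_equal(classify_pair(cs[[1]], cs[[2]]), cs[[3]])
    expect_equal(classify_pair(cs[[2]], cs[[1]]), cs[[3]])
  }
})

test_that("find_stems returns the six stems of the six-stem pseudoknot fixture", {
  st <- find_stems(fixture_figure3())
  expect_equal(nrow(st), 6L)
  expect_equal(st$face_i, c(1L, 4L, 6L, 9L, 17L, 20L))
  expect_equal(st$face_j, c(26L, 23L, 16L, 13L, 31L, 28L))
  expect_true(all(st$k == 1L))
})

test_that("single stacked runs and lone pairs are handled per the k > 0 rule", {
  s <- rna_structure(6, pairs = rbind(c(1, 6), c(2, 5), c(3, 4)))
  st <- find_stems(s, "arbitrary")
  expect_equal(nrow(st), 1L)
  expect_equal(st$k, 2L)
  lone <- rna_structure(10, pairs = rbind(c(1, 10)))
  st2 <- find_stems(lone, "arbitrary")
  expect_equal(nrow(st2), 0L)
  expect_equal(nrow(attr(st2, "isolated")), 1L)
  expect_error(find_stems(lone, "arbitrary", min_pairs = 1),
               "at least 2")
  st3 <- find_stems(lone, "arbitrary", keep_isolated = TRUE)
  expect_equal(nrow(st3), 1L)
  expect_equal(st3$type, "arbitrary")
  expect_equal(st3$k, 0L)
})

test_that("standard stems need a sequence and skip non-complementary pairs", {
  s <- rna_structure(8, pairs = rbind(c(1, 8), c(2, 7)))
  expect_warning(st <- find_stems(s), "no sequence")
  expect_equal(nrow(st), 1L)
  s2 <- rna_structure(8, pairs = rbind(c(1, 8), c(2, 7)), sequence = "GACCGGAC")
  st2 <- find_stems(s2)   # (1,8) G-C ok, (2,7) A-A not complementary
  expect_equal(nrow(st2), 0L)
  iso <- attr(st2, "isolated")
  expect_equal(nrow(iso), 2L)
  expect_equal(sum(iso$eligible), 1L)
})

test_that("crossing follows the two inequality chains against the face", {
  st <- find_stems(fixture_figure1())
  H <- st[st$face_i == 9, ]
  expect_true(crosses(c(13, 55), H))    # 9 < 13 < 48 < 55
  expect_false(crosses(c(18, 26), H))   # nested
  fake <- data.frame(face_i = 10L, face_j = 30L, k = 1L)
  expect_true(crosses(c(5, 20), fake))  # 5 < 10 < 20 < 30
})

test_that("internality and stem containment use the internal pair", {
  st <- find_stems(fixture_figure1())
  H <- st[st$face_i == 9, ]; W <- st[st$face_i == 13, ]
  Q <- st[st$face_i == 34, ]
  expect_true(lies_inside(Q, H))
  expect_false(lies_inside(W, H))       # right wing 53-55 outside
  expect_false(lies_inside(H, H))
  expect_true(position_internal(34, H)) # 10 < 34 < 47
  expect_false(position_internal(10, H))
})

test_that("stems agree with a brute-force run enumeration and are maximal", {
  for (seed in 1:60) {
    s <- random_structure(seed, pk_prob = 0.4)
    st <- find_stems(s)
    ref <- brute_stems(s)
    expect_equal(st$face_i, ref$face_i)
    expect_equal(st$face_j, ref$face_j)
    expect_equal(st$k, ref$k)
    # conservation: stem pairs + isolated pairs = all pairs
    iso <- attr(st, "isolated")
    n_in_stems <- sum(st$k + 1L)
    expect_equal(n_in_stems + nrow(iso), nrow(s$pairs))
    # maximality probing
    partner <- pair_partner(s)
    for (r in seq_len(nrow(st))) {
      i <- st$face_i[[r]]; j <- st$face_j[[r]]; k <- st$k[[r]]
      if (i > 1L) expect_false(partner[i - 1L] == j + 1L && j < s$length)
      expect_false(i + k + 1L < j - k - 1L &&
                     partner[i + k + 1L] == j - k - 1L)
    }
  }
})
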