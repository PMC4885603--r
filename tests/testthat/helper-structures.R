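# Shared helpers: seeded random structures sized so the generator always
# has room, and an independent maximal-run stem finder used as oracle.

random_structure <- function(seed, pk_prob = 0.4, n_tertiary = 0L) {
  L <- 40L + (seed %% 81L)   # lengths 40..120
  generate_structure(L, n_stems = max(2L, L %/% 18L),
                     min_pairs = 2L, max_pairs = 5L,
                     pk_prob = pk_prob, n_tertiary = n_tertiary,
                     seed = seed)
}

# brute-force stem oracle: enumerate maximal diagonal runs in the pair
# matrix, independent of find_stems()'s left-end lookup
brute_stems <- function(s, min_pairs = 2L) {
  p <- s$pairs
  if (nrow(p) == 0L)
    return(data.frame(face_i = integer(0), face_j = integer(0),
                      k = integer(0)))
  has <- matrix(FALSE, s$length, s$length)
  has[p] <- TRUE
  runs <- list()
  for (r in seq_len(nrow(p))) {
    i <- p[r, 1L]; j <- p[r, 2L]
    if (i > 1L && j < s$length && has[i - 1L, j + 1L]) next
    k <- 0L
    while (i + k + 1L < j - k - 1L && has[i + k + 1L, j - k - 1L])
      k <- k + 1L
    if (k + 1L >= min_pairs) runs[[length(runs) + 1L]] <- c(i, j, k)
  }
  out <- data.frame(face_i = vapply(runs, `[[`, 1L, 1L),
                    face_j = vapply(runs, `[[`, 1L, 2L),
                    k = vapply(runs, `[[`, 1L, 3L))
  out[order(out$face_i), , drop = FALSE]
}

expect_same_ecrs <- function(ecrs, oracle) {
  expect_equal(ecrs$start, oracle$start)
  expect_equal(ecrs$end, oracle$end)
  expect_equal(ecrs$kind, oracle$kind)
}
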