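#' Deterministic worked-example structures
#'
#' Small hand-built structures exercising every annotation concept, with
#' complementary sequences so that standard-stem detection recovers the
#' intended stems.
#'
#' * `fixture_figure1()` -- 57 nt, five stems named H, W, P1, P2, Q: stem
#'   H has wings 9-10 / 47-48; its loop has sides 11-17, 32-33 and 44-46,
#'   a pseudoknot face (18, 31) and a stem face (34, 43), contains the
#'   crossing wing 13-15, and is a pseudoknotted multiple junction.
#' * `fixture_figure3()` -- 31 nt, six stems inside one pseudoknotted ECR
#'   whose signature chain is full `abcdDCefBAFE`, upper `abcdBADC`,
#'   reduced `abAB`.
#' * `fixture_hknot()`, `fixture_kissing()`, `fixture_tripleknot()` --
#'   minimal realizations of the named pseudoknot classes with reduced
#'   signatures `abAB`, `abAcBC` and `abcABC`.
#'
#' @return An [rna_structure].
#' @name fixtures
NULL

fixture_from_pairs <- function(length, pairs) {
  pairs <- normalize_pairs(pairs)
  rna_structure(length, pairs = pairs,
                sequence = complementary_sequence(length, pairs))
}

# deterministic complementary fill: pairs cycle through GC/CG/AU/UA,
# unpaired positions are A
complementary_sequence <- function(length, pairs, wobble = integer(0)) {
  seq <- rep("A", length)
  duplex <- list(c("G", "C"), c("C", "G"), c("A", "U"), c("U", "A"))
  for (r in seq_len(nrow(pairs))) {
    d <- if (r %in% wobble) c("G", "U") else duplex[[(r - 1L) %% 4L + 1L]]
    seq[pairs[r, 1L]] <- d[[1L]]
    seq[pairs[r, 2L]] <- d[[2L]]
  }
  paste(seq, collapse = "")
}

#' @rdname fixtures
#' @export
fixture_figure1 <- function() {
  fixture_from_pairs(57L, rbind(
    c(9, 48), c(10, 47),            # H
    c(13, 55), c(14, 54), c(15, 53), # W, crosses H
    c(18, 26), c(19, 25),            # P1
    c(21, 31), c(22, 30),            # P2, crosses P1
    c(34, 43), c(35, 42), c(36, 41)  # Q
  ))
}

#' @rdname fixtures
#' @export
fixture_figure3 <- function() {
  fixture_from_pairs(31L, rbind(
    c(1, 26), c(2, 25),   # a
    c(4, 23), c(5, 22),   # b
    c(6, 16), c(7, 15),   # c
    c(9, 13), c(10, 12),  # d
    c(17, 31), c(18, 30), # e
    c(20, 28), c(21, 27)  # f
  ))
}

#' @rdname fixtures
#' @export
fixture_hknot <- function() {
  fixture_from_pairs(16L, rbind(c(1, 12), c(2, 11), c(5, 16), c(6, 15)))
}

#' @rdname fixtures
#' @export
fixture_kissing <- function() {
  fixture_from_pairs(17L, rbind(c(1, 8), c(2, 7), c(4, 14), c(5, 13),
                                c(10, 17), c(11, 16)))
}

#' @rdname fixtures
#' @export
fixture_tripleknot <- function() {
  fixture_from_pairs(17L, rbind(c(1, 11), c(2, 10), c(4, 14), c(5, 13),
                                c(7, 17), c(8, 16)))
}

fixture_by_name <- function(name) {
  switch(name,
         figure1 = fixture_figure1(),
         figure3 = fixture_figure3(),
         hknot = fixture_hknot(),
         kissing = fixture_kissing(),
         tripleknot = fixture_tripleknot(),
         stop("unknown fixture '", name, "' (available: figure1, figure3, ",
              "hknot, kissing, tripleknot)", call. = FALSE))
}

#' Generate a random RNA secondary structure with planted stems
#'
#' Stems are planted one at a time as non-conflicting stacked runs with at
#' least one unpaired spacer against every existing stem diagonal, so
#' maximal-stem detection recovers exactly the planted stems.  With
#' probability `pk_prob` a new stem is required to cross at least one
#' existing stem (a pseudoknot); with `pk_prob = 0` the output is
#' guaranteed pseudoknot-free.  A complementary sequence is emitted
#' (Watson-Crick pairs with occasional GU wobble), so `stem_type =
#' "standard"` detection sees every planted pair.  The generator is fully
#' reproducible: the same `seed` yields the same structure.
#'
#' @param length Chain length.
#' @param n_stems Target number of stems.
#' @param min_pairs,max_pairs Range of pairs per stem.
#' @param pk_prob Probability that each stem after the first must cross an
#'   existing stem.
#' @param n_tertiary Number of random non-canonical tertiary pairs to
#'   attach (annotations only; they may reuse paired positions).
#' @param seed Optional integer seed; when given, the caller's RNG state
#'   is left untouched.
#' @param max_tries Placement attempts per stem before giving up.
#' @return An [rna_structure] with a `"planted"` attribute: a data frame
#'   of the planted stems (`face_i`, `face_j`, `k`, `crossing`).
#' @examples
#' s <- generate_structure(60, n_stems = 4, pk_prob = 0, seed = 1)
#' nrow(find_stems(s))
#' @export
generate_structure <- function(length = 100L, n_stems = 6L,
                               min_pairs = 2L, max_pairs = 6L,
                               pk_prob = 0.3, n_tertiary = 0L,
                               seed = NULL, max_tries = 400L) {
  stopifnot(length >= 1L, n_stems >= 0L, min_pairs >= 2L,
            max_pairs >= min_pairs, pk_prob >= 0, pk_prob <= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (is.null(old))
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }

  # placement can paint itself into a corner (a required crossing with no
  # room left); restart the whole layout a bounded number of times before
  # declaring the configuration infeasible
  for (attempt in 1:25) {
    occupied <- rep(FALSE, length)
    lp <- integer(length)   # left-end lookup of placed pairs
    placed <- data.frame(face_i = integer(0), face_j = integer(0),
                         k = integer(0), crossing = logical(0))
    pairs <- matrix(integer(0), ncol = 2L)
    wobble_rows <- integer(0)
    all_done <- TRUE

    for (st in seq_len(n_stems)) {
    want_pk <- nrow(placed) > 0L && stats::runif(1) < pk_prob
    done <- FALSE
    for (try in seq_len(max_tries)) {
      np <- min_pairs + sample.int(max_pairs - min_pairs + 1L, 1L) - 1L
      k <- np - 1L
      # left wing [a, a+k], right wing [b-k, b], hairpin gap >= 3
      if (length < 2L * np + 3L) break
      if (want_pk) {
        # place the wings on opposite sides of an existing face so the
        # new stem crosses it by construction
        tg <- placed[sample.int(nrow(placed), 1L), ]
        if (stats::runif(1) < 0.5) {
          # a < face_i < b < face_j
          a_hi <- min(tg$face_i - 1L, length - 2L * np - 2L)
          if (a_hi < 1L) next
          a <- sample.int(a_hi, 1L)
          b_lo <- max(tg$face_i + 1L, a + 2L * np + 2L)
          b_hi <- tg$face_j - 1L
        } else {
          # face_i < a < face_j < b
          a_lo <- tg$face_i + 1L
          a_hi <- min(tg$face_j - 1L, length - 2L * np - 2L)
          if (a_hi < a_lo) next
          a <- a_lo + sample.int(a_hi - a_lo + 1L, 1L) - 1L
          b_lo <- max(tg$face_j + 1L, a + 2L * np + 2L)
          b_hi <- length
        }
        if (b_hi < b_lo) next
        b <- b_lo + sample.int(b_hi - b_lo + 1L, 1L) - 1L
      } else {
        a <- sample.int(length - 2L * np - 2L, 1L)
        b_min <- a + 2L * np + 2L
        b <- b_min + sample.int(length - b_min + 1L, 1L) - 1L
      }
      prop <- cbind(a + 0:k, b - 0:k)
      if (any(occupied[as.vector(prop)])) next
      # no accidental diagonal continuation of an existing stem
      ext <- FALSE
      for (r in seq_len(np)) {
        x <- prop[r, 1L]; y <- prop[r, 2L]
        if ((x > 1L && y < length && lp[x - 1L] == y + 1L) ||
            (x < length && y > 1L && lp[x + 1L] == y - 1L)) { ext <- TRUE; break }
      }
      if (ext) next
      if (nrow(placed) > 0L) {
        cr <- (a < placed$face_i & placed$face_i < b & b < placed$face_j) |
          (placed$face_i < a & a < placed$face_j & placed$face_j < b)
        if (want_pk && !any(cr)) next
        if (!want_pk && any(cr)) next
      }
      occupied[as.vector(prop)] <- TRUE
      lp[prop[, 1L]] <- prop[, 2L]
      base_row <- nrow(pairs)
      pairs <- rbind(pairs, prop)
      wob <- which(stats::runif(np) < 0.1)
      wobble_rows <- c(wobble_rows, base_row + wob)
      placed <- rbind(placed, data.frame(face_i = a, face_j = b, k = k,
                                         crossing = want_pk))
      done <- TRUE
      break
    }
      if (!done) { all_done <- FALSE; break }
    }
    if (all_done) break
    if (attempt == 25L)
      stop("infeasible generator configuration: could not place ", n_stems,
           " stems in length ", length, " (", max_tries,
           " tries per stem, 25 restarts)", call. = FALSE)
  }

  seq <- complementary_sequence(length, pairs, wobble = wobble_rows)
  # randomize unpaired residues
  free <- which(!occupied)
  sch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  sch[free] <- sample(c("A", "C", "G", "U"), length(free), replace = TRUE)

  tertiary <- NULL
  if (n_tertiary > 0L && length >= 2L) {
    lw <- c("cWW", "tWW", "cWH", "tHS", "cSS", "tSH")
    ti <- t(replicate(n_tertiary, sort(sample.int(length, 2L))))
    tertiary <- data.frame(i = ti[, 1L], j = ti[, 2L],
                           lw_class = sample(lw, n_tertiary, replace = TRUE),
                           canonical = FALSE)
  }

  s <- rna_structure(length, pairs = pairs,
                     sequence = paste(sch, collapse = ""),
                     tertiary = tertiary)
  attr(s, "planted") <- placed[order(placed$face_i), , drop = FALSE]
  s
}
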