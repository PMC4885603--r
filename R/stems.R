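#' Classify a base pair as Watson-Crick, wobble or other
#'
#' Watson-Crick means the base set is {A,U} or {C,G}; wobble means {G,U};
#' anything else, including any pair involving N, is "other".  Symmetric in
#' its arguments.  Watson-Crick and wobble pairs together are the
#' complementary pairs that standard stems are built from.
#'
#' @param base_a,base_b Single characters in `A,C,G,U,N`.
#' @return One of `"watson_crick"`, `"wobble"`, `"other"`.
#' @export
classify_pair <- function(base_a, base_b) {
  a <- toupper(base_a); b <- toupper(base_b)
  stopifnot(a %in% c("A", "C", "G", "U", "N"),
            b %in% c("A", "C", "G", "U", "N"))
  key <- paste(sort(c(a, b)), collapse = "")
  if (key %in% c("AU", "CG")) "watson_crick"
  else if (key == "GU") "wobble"
  else "other"
}

#' Find all maximal stems of a structure
#'
#' A stem is a run of stacked pairs (i, j), (i+1, j-1), ..., (i+k, j-k)
#' with k >= 1, i.e. at least two pairs.  The first pair is the face, the
#' last the internal pair; the chain fragments \[i, i+k\] and \[j-k, j\]
#' are the left and right wings.  Stems are maximal: they cannot be
#' extended inward or outward by another eligible pair.  With
#' `stem_type = "standard"` only complementary (Watson-Crick or wobble)
#' pairs are eligible; this is the default and drives all downstream
#' annotation.  Pairs not in any returned stem are reported as isolated
#' pairs in the `"isolated"` attribute and take no part in ECR or loop
#' computations unless `keep_isolated = TRUE`, which turns isolated
#' eligible pairs into nonstandard one-pair stems of type `"arbitrary"`
#' for exploratory use.
#'
#' @param s An [rna_structure].
#' @param stem_type `"standard"` (complementary pairs only; requires a
#'   sequence, otherwise falls back to `"arbitrary"` with a warning) or
#'   `"arbitrary"` (every pair eligible).
#' @param min_pairs Minimum number of pairs per stem; must be >= 2 (a
#'   single pair is not a stem).
#' @param keep_isolated Treat isolated eligible pairs as one-pair
#'   `"arbitrary"` stems (nonstandard; default `FALSE`).
#' @return A data frame of class `rna_stems`, one row per stem, sorted by
#'   face left end, with columns `id`, `face_i`, `face_j`, `k`
#'   (`n_pairs = k + 1`), `type`.  Attribute `"isolated"` holds a data
#'   frame of the non-stem pairs with their eligibility.
#' @examples
#' s <- parse_dotbracket("(((...)))")
#' find_stems(s, stem_type = "arbitrary")
#' @export
find_stems <- function(s, stem_type = c("standard", "arbitrary"),
                       min_pairs = 2L, keep_isolated = FALSE) {
  stopifnot(inherits(s, "rna_structure"))
  stem_type <- match.arg(stem_type)
  if (min_pairs < 2L)
    stop("'min_pairs' must be at least 2: a stem has k > 0, ",
         "i.e. two or more stacked pairs", call. = FALSE)
  if (stem_type == "standard" && is.null(s$sequence)) {
    warning("no sequence available; treating every pair as eligible ",
            "(stem_type forced to \"arbitrary\")", call. = FALSE)
    stem_type <- "arbitrary"
  }

  p <- s$pairs
  eligible <- rep(TRUE, nrow(p))
  if (stem_type == "standard" && nrow(p) > 0L) {
    base <- structure_bases(s)
    cls <- mapply(classify_pair, base[p[, 1L]], base[p[, 2L]])
    eligible <- cls %in% c("watson_crick", "wobble")
  }

  # left-end lookup over eligible pairs: lp[i] = j iff (i, j) eligible
  lp <- integer(s$length)
  ep <- p[eligible, , drop = FALSE]
  if (nrow(ep) > 0L) lp[ep[, 1L]] <- ep[, 2L]

  runs <- list()
  if (nrow(ep) > 0L) {
    for (r in seq_len(nrow(ep))) {
      i <- ep[r, 1L]; j <- ep[r, 2L]
      if (i > 1L && j < s$length && lp[i - 1L] == j + 1L) next  # not a run start
      k <- 0L
      while (i + k + 1L < j - k - 1L + 1L && lp[i + k + 1L] == j - k - 1L)
        k <- k + 1L
      runs[[length(runs) + 1L]] <- c(i, j, k)
    }
  }

  keep <- vapply(runs, function(x) x[[3L]] + 1L >= min_pairs, TRUE)
  stems <- runs[keep]
  stems <- stems[order(vapply(stems, `[[`, 1L, 1L))]
  df <- data.frame(
    id = seq_along(stems),
    face_i = vapply(stems, `[[`, 1L, 1L),
    face_j = vapply(stems, `[[`, 1L, 2L),
    k = vapply(stems, `[[`, 1L, 3L)
  )
  df$n_pairs <- df$k + 1L
  df$type <- rep(stem_type, nrow(df))

  # isolated = pairs in runs below min_pairs, plus ineligible pairs
  in_stem <- logical(nrow(p))
  for (r in seq_len(nrow(df)))
    in_stem <- in_stem |
      (eligible & p[, 1L] >= df$face_i[[r]] & p[, 1L] <= df$face_i[[r]] + df$k[[r]] &
         p[, 2L] <= df$face_j[[r]] & p[, 2L] >= df$face_j[[r]] - df$k[[r]])
  iso <- data.frame(i = p[!in_stem, 1L], j = p[!in_stem, 2L],
                    eligible = eligible[!in_stem])

  if (keep_isolated && nrow(iso) > 0L) {
    add <- iso[iso$eligible, , drop = FALSE]
    if (nrow(add) > 0L) {
      extra <- data.frame(id = NA_integer_, face_i = add$i, face_j = add$j,
                          k = 0L, n_pairs = 1L, type = "arbitrary")
      df <- rbind(df, extra)
      df <- df[order(df$face_i), , drop = FALSE]
      df$id <- seq_len(nrow(df))
      iso <- iso[!iso$eligible, , drop = FALSE]
    }
  }

  rownames(df) <- NULL
  rownames(iso) <- NULL
  attr(df, "isolated") <- iso
  class(df) <- c("rna_stems", "data.frame")
  df
}

stem_row <- function(stems, id) {
  r <- stems[stems$id == id, , drop = FALSE]
  if (nrow(r) != 1L) stop("unknown stem id ", id, call. = FALSE)
  r
}

stem_internal_pair <- function(stem) {
  c(stem$face_i + stem$k, stem$face_j - stem$k)
}

stem_wings <- function(stem) {
  list(left = c(stem$face_i, stem$face_i + stem$k),
       right = c(stem$face_j - stem$k, stem$face_j))
}

stem_wing_positions <- function(stem) {
  c(stem$face_i:(stem$face_i + stem$k), (stem$face_j - stem$k):stem$face_j)
}

stem_pairs <- function(stem) {
  cbind(i = stem$face_i + 0:stem$k, j = stem$face_j - 0:stem$k)
}

all_stem_pairs <- function(stems) {
  if (nrow(stems) == 0L) return(matrix(integer(0), ncol = 2L))
  do.call(rbind, lapply(seq_len(nrow(stems)),
                        function(r) stem_pairs(stems[r, ])))
}

stems_partner <- function(stems, length) {
  partner_of(all_stem_pairs(stems), length)
}

#' Does a base pair cross a stem?
#'
#' The pair (m, n) crosses a stem with face (i, j) when m < i < n < j or
#' i < m < j < n -- the defining relation of pseudoknots.
#'
#' @param p Length-2 integer vector (m, n) with m < n.
#' @param h One row of a [find_stems()] result (or a stem id together with
#'   `stems`).
#' @param stems Optional stems table used to look `h` up when it is an id.
#' @return Logical.
#' @export
crosses <- function(p, h, stems = NULL) {
  if (!is.null(stems)) h <- stem_row(stems, h)
  m <- min(p); n <- max(p)
  i <- h$face_i; j <- h$face_j
  (m < i && i < n && n < j) || (i < m && m < j && j < n)
}

#' Is a position internal to a stem?
#'
#' Internality is tested against the stem's internal pair (i, j): position
#' t is internal when i < t < j.
#'
#' @param t Position.
#' @inheritParams crosses
#' @return Logical.
#' @export
position_internal <- function(t, h, stems = NULL) {
  if (!is.null(stems)) h <- stem_row(stems, h)
  ip <- stem_internal_pair(h)
  ip[[1L]] < t & t < ip[[2L]]
}

#' Does one stem lie inside another?
#'
#' Stem `h1` lies inside stem `h` when every position of both its wings is
#' internal to `h` (strictly between the positions of `h`'s internal
#' pair).  A stem never lies inside itself.
#'
#' @param h1,h Rows of a [find_stems()] result (or ids with `stems`).
#' @inheritParams crosses
#' @return Logical.
#' @export
lies_inside <- function(h1, h, stems = NULL) {
  if (!is.null(stems)) {
    h1 <- stem_row(stems, h1)
    h <- stem_row(stems, h)
  }
  if (h1$face_i == h$face_i && h1$face_j == h$face_j) return(FALSE)
  all(position_internal(stem_wing_positions(h1), h))
}
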