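#' H-related elementary closed regions of a stem
#'
#' Let (r, s) be the internal pair of stem H.  An H-ECR is a segment
#' \[i, j\] with r < i < j < s such that no stem pair runs from \[i, j\]
#' into the rest of H's interior (pairs leaving H's interior altogether
#' are allowed -- this is what makes the notion pseudoknot-aware), no
#' proper prefix or suffix satisfies the same conditions, and the
#' boundary is made of stem faces exactly as for an ECR.  Only the
#' outermost such regions are returned; they are the fragments excluded
#' from H's loop, and their boundary pairs become the loop's faces.
#'
#' @param s An [rna_structure].
#' @param h Stem id or a single row of `stems`.
#' @param stems A [find_stems()] result for `s`.
#' @return Data frame with columns `start`, `end`, `kind`
#'   (`"classical"` when (i, j) is a stem face, else `"pseudoknotted"`),
#'   sorted left to right.
#' @export
find_h_ecrs <- function(s, h, stems) {
  if (!is.data.frame(h)) h <- stem_row(stems, h)
  ip <- stem_internal_pair(h)
  r <- ip[[1L]]; s2 <- ip[[2L]]
  sp <- stems_partner(stems, s$length)

  lefts <- stems$face_i[stems$face_i > r & stems$face_i < s2]
  rights <- stems$face_j[stems$face_j > r & stems$face_j < s2]
  found <- list()
  for (i in lefts) {
    for (j in rights) {
      if (j <= i) next
      if (sp[[i]] < i || sp[[i]] > j) next    # boundary face must close inward
      if (sp[[j]] < i || sp[[j]] > j) next
      v <- sp[i:j]
      inward <- v != 0L & v > r & v < s2     # only pairs inside H's interior count
      if (!all(!inward | (v >= i & v <= j))) next
      idx <- i:j
      g <- ifelse(inward, pmax(idx, v), idx)
      M <- cummax(g)
      len <- j - i + 1L
      if (any(M[-len] == idx[-len])) next
      found[[length(found) + 1L]] <- c(i, j)
    }
  }
  if (length(found) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      kind = character(0)))
  start <- vapply(found, `[[`, 1L, 1L)
  end <- vapply(found, `[[`, 1L, 2L)
  outer <- !vapply(seq_along(found), function(a)
    any(start < start[[a]] & end > end[[a]] |
          (start <= start[[a]] & end > end[[a]]) |
          (start < start[[a]] & end >= end[[a]])), TRUE)
  start <- start[outer]; end <- end[outer]
  ord <- order(start)
  data.frame(start = start[ord], end = end[ord],
             kind = ifelse(sp[start[ord]] == end[ord],
                           "classical", "pseudoknotted"))
}

#' The loop of a stem
#'
#' The loop of stem H with internal pair (r, s) is the set of positions
#' that belong to H: positions internal to H (strictly between r and s)
#' and not strictly inside the face of any stem lying inside H.
#' Equivalently it is the fragment \[r+1, s-1\] with the interiors of H's
#' H-ECRs excluded; the boundary pairs of the excluded regions are kept
#' as the loop's faces.  The loop decomposes into sides -- maximal
#' (possibly zero-length) runs of loop positions between consecutive
#' faces.  In pseudoknots a loop may also contain whole wings of stems
#' that cross H; such loops are pseudoknotted.
#'
#' Zero-length sides are represented explicitly with `end = start - 1`,
#' anchored between their two delimiters, so that bulges are detectable.
#'
#' @inheritParams find_h_ecrs
#' @param hecrs Optional precomputed [find_h_ecrs()] result for `h`.
#' @return An object of class `rna_loop`: a list with `owner` (stem id),
#'   `positions`, `sides` (data frame `start`, `end`, `length`), `faces`
#'   (data frame `x`, `y`, `tag` in `stem_face`/`pseudoknot_face`),
#'   `wings_contained` (data frame `stem`, `wing`, `start`, `end`),
#'   `size_class` and `pk_class`.
#' @examples
#' s <- parse_dotbracket("((..((....))))")
#' st <- find_stems(s, "arbitrary")
#' loop_of(s, 1, st)   # a bulge
#' @export
loop_of <- function(s, h, stems, hecrs = NULL) {
  if (!is.data.frame(h)) h <- stem_row(stems, h)
  if (is.null(hecrs)) hecrs <- find_h_ecrs(s, h, stems)
  ip <- stem_internal_pair(h)
  r <- ip[[1L]]; s2 <- ip[[2L]]

  interior <- if (r + 1L <= s2 - 1L) (r + 1L):(s2 - 1L) else integer(0)
  excluded <- rep(FALSE, s$length)
  for (e in seq_len(nrow(hecrs))) {
    a <- hecrs$start[[e]]; b <- hecrs$end[[e]]
    if (a + 1L <= b - 1L) excluded[(a + 1L):(b - 1L)] <- TRUE
  }
  positions <- interior[!excluded[interior]]

  # cross-check against the per-position "belongs" definition
  belongs <- belongs_positions(h, stems, r, s2, interior)
  if (!identical(positions, belongs))
    stop("internal error: H-ECR loop characterization disagrees with the ",
         "position-wise definition for stem ", h$id, call. = FALSE)

  faces <- data.frame(
    x = hecrs$start, y = hecrs$end,
    tag = ifelse(hecrs$kind == "classical", "stem_face", "pseudoknot_face")
  )

  delim <- c(r, as.vector(rbind(hecrs$start, hecrs$end)), s2)
  sides <- data.frame(start = integer(0), end = integer(0))
  for (k in seq_len(nrow(hecrs) + 1L)) {
    a <- delim[[2L * k - 1L]] + 1L
    b <- delim[[2L * k]] - 1L
    sides <- rbind(sides, data.frame(start = a, end = max(b, a - 1L)))
  }
  sides$length <- sides$end - sides$start + 1L

  wings <- data.frame(stem = integer(0), wing = character(0),
                      start = integer(0), end = integer(0))
  inloop <- rep(FALSE, s$length)
  inloop[positions] <- TRUE
  for (g in seq_len(nrow(stems))) {
    gs <- stems[g, ]
    if (gs$id == h$id || lies_inside(gs, h)) next
    for (w in c("left", "right")) {
      iv <- stem_wings(gs)[[w]]
      inside <- inloop[iv[[1L]]:iv[[2L]]]
      if (all(inside)) {
        wings <- rbind(wings, data.frame(stem = gs$id, wing = w,
                                         start = iv[[1L]], end = iv[[2L]]))
      } else if (any(inside)) {
        stop("pathological input: wing [", iv[[1L]], ",", iv[[2L]],
             "] of stem ", gs$id, " lies only partially in the loop of ",
             "stem ", h$id, call. = FALSE)
      }
    }
  }

  loop <- structure(
    list(owner = h$id, positions = positions, sides = sides,
         faces = faces, wings_contained = wings),
    class = "rna_loop"
  )
  cls <- classify_loop(loop)
  loop$size_class <- cls[["size_class"]]
  loop$pk_class <- cls[["pk_class"]]
  loop
}

belongs_positions <- function(h, stems, r, s2, interior) {
  if (length(interior) == 0L) return(integer(0))
  covered <- rep(FALSE, length(interior))
  for (g in seq_len(nrow(stems))) {
    gs <- stems[g, ]
    if (gs$id == h$id || !lies_inside(gs, h)) next
    covered <- covered | (interior > gs$face_i & interior < gs$face_j)
  }
  interior[!covered]
}

#' Classify a loop along both axes
#'
#' Size axis: a hairpin has no faces (one side); an internal loop has
#' exactly one face (two sides) and is a bulge when one side has zero
#' length; a multiple junction has two or more faces.  Pseudoknot axis: a
#' loop is pseudoknotted when it contains a wing of a crossing stem;
#' otherwise it is isolated, and additionally classical when it contains
#' no pseudoknot faces either (every classical loop is in particular
#' isolated; the label reports the most specific class).  A stem is
#' pseudoknotted when its loop is.
#'
#' @param l An `rna_loop` from [loop_of()].
#' @return Named character vector with `size_class` (one of `hairpin`,
#'   `internal`, `bulge`, `multiple_junction`) and `pk_class` (one of
#'   `classical`, `isolated`, `pseudoknotted`).
#' @export
classify_loop <- function(l) {
  n_faces <- nrow(l$faces)
  size_class <- if (n_faces == 0L) "hairpin"
  else if (n_faces == 1L) {
    if (any(l$sides$length == 0L)) "bulge" else "internal"
  } else "multiple_junction"
  pk_class <- if (nrow(l$wings_contained) > 0L) "pseudoknotted"
  else if (any(l$faces$tag == "pseudoknot_face")) "isolated"
  else "classical"
  c(size_class = size_class, pk_class = pk_class)
}

#' @export
print.rna_loop <- function(x, ...) {
  cat("Loop of stem ", x$owner, ": ", x$size_class, ", ", x$pk_class,
      "\n  sides: ",
      paste(sprintf("[%d,%d]", x$sides$start, x$sides$end), collapse = " "),
      "\n", sep = "")
  if (nrow(x$faces) > 0L)
    cat("  faces: ",
        paste(sprintf("(%d,%d):%s", x$faces$x, x$faces$y, x$faces$tag),
              collapse = " "), "\n", sep = "")
  if (nrow(x$wings_contained) > 0L)
    cat("  wings: ",
        paste(sprintf("[%d,%d]", x$wings_contained$start,
                      x$wings_contained$end), collapse = " "), "\n", sep = "")
  invisible(x)
}
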