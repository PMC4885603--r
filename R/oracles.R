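#' Brute-force reference implementations
#'
#' Slow, literal implementations of the defining conditions, used to
#' validate the fast annotation code on small structures (length up to a
#' few hundred).  [oracle_ecrs()] tests every interval directly against
#' the four ECR conditions; [oracle_loop()] evaluates the per-position
#' "belongs" predicate; [oracle_signature()] sorts all arc ends naively
#' and, for the reduced level, merges parallel arc pairs iteratively
#' until a fixed point; [oracle_nnm_loops()] computes the classical
#' nearest-neighbour-model loop decomposition of a pseudoknot-free
#' structure from the stem nesting tree.
#'
#' @param s An [rna_structure].
#' @param stems A [find_stems()] result for `s`.
#' @name oracles
NULL

#' @rdname oracles
#' @return `oracle_ecrs`: data frame `start`, `end`, `kind` of every
#'   interval satisfying the ECR conditions.
#' @export
oracle_ecrs <- function(s, stems) {
  L <- s$length
  sp <- stems_partner(stems, L)
  is_face_left <- rep(FALSE, L); is_face_right <- rep(FALSE, L)
  is_face_left[stems$face_i] <- TRUE
  is_face_right[stems$face_j] <- TRUE

  # closed[[i]][j - i + 1]: no pair with exactly one end in [i, j]
  closed <- vector("list", L)
  for (i in seq_len(L)) {
    idx <- i:L
    v <- sp[idx]
    out_left <- v != 0L & v < i
    g <- pmax(idx, ifelse(v == 0L, idx, v))
    closed[[i]] <- cummax(g) == idx & cumsum(out_left) == 0L
  }
  is_closed <- function(i, j) closed[[i]][[j - i + 1L]]

  res <- list()
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (j <= i || !is_closed(i, j)) next
      elementary <- TRUE
      for (t in (i + 1L):(j - 1L)) {
        if (t >= j) break
        if (is_closed(i, t) || is_closed(t, j)) { elementary <- FALSE; break }
      }
      if (!elementary) next
      # boundary condition: stem face, or two faces meeting the ends
      classical <- sp[[i]] == j && is_face_left[[i]]
      pseudo <- !classical && sp[[i]] != 0L && sp[[j]] != 0L &&
        is_face_left[[i]] && is_face_right[[j]] &&
        sp[[i]] < j && sp[[j]] > i
      if (!classical && !pseudo) next
      res[[length(res) + 1L]] <-
        data.frame(start = i, end = j,
                   kind = if (classical) "classical" else "pseudoknotted")
    }
  }
  if (length(res) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      kind = character(0)))
  out <- do.call(rbind, res)
  out[order(out$start, -out$end), , drop = FALSE]
}

#' @rdname oracles
#' @param h Stem id or row of `stems`.
#' @return `oracle_loop`: integer vector of the positions belonging to
#'   stem `h`.
#' @export
oracle_loop <- function(s, h, stems) {
  if (!is.data.frame(h)) h <- stem_row(stems, h)
  ip <- stem_internal_pair(h)
  keep <- integer(0)
  for (t in seq_len(s$length)) {
    if (!(ip[[1L]] < t && t < ip[[2L]])) next
    blocked <- FALSE
    for (g in seq_len(nrow(stems))) {
      gs <- stems[g, ]
      if (gs$id == h$id) next
      if (!lies_inside(gs, h)) next
      if (gs$face_i < t && t < gs$face_j) { blocked <- TRUE; break }
    }
    if (!blocked) keep <- c(keep, t)
  }
  keep
}

#' @rdname oracles
#' @param interval Length-2 vector, the pseudoknotted ECR to summarize.
#' @param level `"full"`, `"upper"` or `"reduced"`.
#' @return `oracle_signature`: the signature word as a string.
#' @export
oracle_signature <- function(s, interval, stems,
                             level = c("full", "upper", "reduced")) {
  level <- match.arg(level)
  members <- stems$id[stems$face_i >= interval[[1L]] &
                        stems$face_j <= interval[[2L]]]
  if (level != "full") {
    all_ecrs <- oracle_ecrs(s, stems)
    sub <- all_ecrs[all_ecrs$start > interval[[1L]] &
                      all_ecrs$end < interval[[2L]], , drop = FALSE]
    drop <- unique(unlist(lapply(seq_len(nrow(sub)), function(r)
      stems$id[stems$face_i >= sub$start[[r]] &
                 stems$face_j <= sub$end[[r]]])))
    members <- setdiff(members, drop)
  }
  sel <- stems[match(members, stems$id), , drop = FALSE]
  arcs <- data.frame(left = sel$face_i, right = sel$face_j - sel$k)

  if (level == "reduced") {
    repeat {
      n <- nrow(arcs)
      cross_set <- function(a) {
        l <- arcs$left; r <- arcs$right
        which((l[[a]] < l & l < r[[a]] & r[[a]] < r) |
                (l < l[[a]] & l[[a]] < r & r < r[[a]]))
      }
      merged <- FALSE
      for (a in seq_len(n)) {
        for (b in seq_len(n)) {
          if (a >= b) next
          nested <- (arcs$left[[a]] < arcs$left[[b]] &&
                       arcs$right[[b]] < arcs$right[[a]]) ||
            (arcs$left[[b]] < arcs$left[[a]] &&
               arcs$right[[a]] < arcs$right[[b]])
          if (!nested) next
          if (!setequal(setdiff(cross_set(a), b),
                        setdiff(cross_set(b), a))) next
          hull <- c(min(arcs$left[c(a, b)]), max(arcs$right[c(a, b)]))
          arcs <- arcs[-c(a, b), , drop = FALSE]
          arcs <- rbind(arcs, data.frame(left = hull[[1L]],
                                         right = hull[[2L]]))
          merged <- TRUE
          break
        }
        if (merged) break
      }
      if (!merged) break
    }
  }

  arcs <- arcs[order(arcs$left), , drop = FALSE]
  n <- nrow(arcs)
  ends <- data.frame(pos = c(arcs$left, arcs$right),
                     letter = c(letters[seq_len(n)], LETTERS[seq_len(n)]))
  paste(ends$letter[order(ends$pos)], collapse = "")
}

#' @rdname oracles
#' @return `oracle_nnm_loops`: list of classical loops, one per stem id,
#'   each a list with `positions`, `sides` and `size_class`.
#' @export
oracle_nnm_loops <- function(s, stems) {
  # classical decomposition from the stem nesting tree; pk-free input only
  n <- nrow(stems)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    if (crosses(c(stems$face_i[[a]], stems$face_j[[a]]), stems[b, ]))
      stop("oracle_nnm_loops requires a pseudoknot-free structure",
           call. = FALSE)
  }
  out <- list()
  for (a in seq_len(n)) {
    h <- stems[a, ]
    r <- h$face_i + h$k; s2 <- h$face_j - h$k
    inside <- which(stems$face_i > r & stems$face_j < s2)
    direct <- inside[vapply(inside, function(g) {
      !any(stems$face_i[inside] < stems$face_i[[g]] &
             stems$face_j[inside] > stems$face_j[[g]])
    }, TRUE)]
    direct <- direct[order(stems$face_i[direct])]
    interior <- if (r + 1L <= s2 - 1L) (r + 1L):(s2 - 1L) else integer(0)
    pos <- interior
    for (g in direct)
      pos <- pos[!(pos > stems$face_i[[g]] & pos < stems$face_j[[g]])]
    delim <- c(r, as.vector(rbind(stems$face_i[direct],
                                  stems$face_j[direct])), s2)
    sides <- data.frame(start = integer(0), end = integer(0))
    for (k in seq_len(length(direct) + 1L)) {
      from <- delim[[2L * k - 1L]] + 1L
      to <- delim[[2L * k]] - 1L
      sides <- rbind(sides, data.frame(start = from, end = max(to, from - 1L)))
    }
    sides$length <- sides$end - sides$start + 1L
    nf <- length(direct)
    size_class <- if (nf == 0L) "hairpin"
    else if (nf == 1L) {
      if (any(sides$length == 0L)) "bulge" else "internal"
    } else "multiple_junction"
    out[[as.character(h$id)]] <-
      list(positions = pos, sides = sides, size_class = size_class)
  }
  out
}
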