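#' Pseudoknot signatures
#'
#' A pseudoknotted ECR is summarized by a word over paired letters: every
#' stem contributes an arc; the arc's left end sits at the leftmost
#' coordinate of the stem's left wing and its right end at the leftmost
#' coordinate of the right wing.  Letters are assigned to arcs in
#' alphabetical order of their left ends; each arc writes its lower-case
#' letter at the left end and the matching capital at the right end, and
#' the word lists all ends in coordinate order.
#'
#' Three levels form a reduction chain:
#' * `full` -- one arc per member stem of the ECR, including stems inside
#'   nested ECRs;
#' * `upper` -- stems lying inside any nested sub-ECR are removed and the
#'   letters reassigned;
#' * `reduced` -- parallel families of arcs (bands: pairwise nested arcs
#'   crossing exactly the same set of other families) are each collapsed
#'   to a single arc spanning the family's outermost ends; the result is
#'   irreducible.
#'
#' @param e A pseudoknotted ECR id from `ecrs`.
#' @param ecrs A [find_ecrs()] result.
#' @param stems The matching [find_stems()] result.
#' @return An object of class `pk_signature`: list with `level`, `word`
#'   and `arcs` (data frame `letter`, `left`, `right`, list column
#'   `stems` of collapsed stem ids).
#' @examples
#' s <- fixture_hknot()
#' st <- find_stems(s)
#' ec <- find_ecrs(s, st)
#' reduced_signature(ec$id[[1]], ec, st)$word   # "abAB"
#' @name pk_signatures
NULL

signature_arcs <- function(stem_ids, stems) {
  sel <- stems[match(stem_ids, stems$id), , drop = FALSE]
  arcs <- data.frame(left = sel$face_i, right = sel$face_j - sel$k)
  arcs$stems <- as.list(sel$id)
  arcs[order(arcs$left), , drop = FALSE]
}

arc_token <- function(idx, upper) {
  if (max(idx) <= 26L) {
    ifelse(upper, LETTERS[idx], letters[idx])
  } else {
    # beyond one alphabet: indexed letters a1/A1, a2/A2, ...
    ifelse(idx <= 26L,
           ifelse(upper, LETTERS[idx], letters[idx]),
           paste0(ifelse(upper, "A", "a"), idx - 26L))
  }
}

arcs_word <- function(arcs) {
  n <- nrow(arcs)
  if (n == 0L) return("")
  arcs <- arcs[order(arcs$left), , drop = FALSE]
  ends <- data.frame(pos = c(arcs$left, arcs$right),
                     arc = rep(seq_len(n), 2L),
                     upper = rep(c(FALSE, TRUE), each = n))
  if (anyDuplicated(ends$pos))
    stop("internal error: coinciding arc ends", call. = FALSE)
  ends <- ends[order(ends$pos), ]
  tokens <- arc_token(ends$arc, ends$upper)
  sep <- if (n > 26L) "." else ""
  paste(tokens, collapse = sep)
}

new_signature <- function(level, arcs) {
  arcs <- arcs[order(arcs$left), , drop = FALSE]
  rownames(arcs) <- NULL
  arcs <- cbind(letter = arc_token(seq_len(nrow(arcs)), FALSE), arcs)
  structure(list(level = level, word = arcs_word(arcs), arcs = arcs),
            class = "pk_signature")
}

check_pk_ecr <- function(e, ecrs) {
  row <- ecrs[ecrs$id == e, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown ECR id ", e, call. = FALSE)
  if (row$kind != "pseudoknotted")
    stop("signatures are defined for pseudoknots; ECR [", row$start, ",",
         row$end, "] is classical", call. = FALSE)
  row
}

#' @rdname pk_signatures
#' @export
full_signature <- function(e, ecrs, stems) {
  row <- check_pk_ecr(e, ecrs)
  new_signature("full", signature_arcs(row$member_stems[[1L]], stems))
}

upper_arc_stems <- function(row, ecrs) {
  setdiff(row$member_stems[[1L]], ecr_descendant_stems(ecrs, row$id))
}

#' @rdname pk_signatures
#' @export
upper_signature <- function(e, ecrs, stems) {
  row <- check_pk_ecr(e, ecrs)
  new_signature("upper", signature_arcs(upper_arc_stems(row, ecrs), stems))
}

#' @rdname pk_signatures
#' @export
reduced_signature <- function(e, ecrs, stems) {
  row <- check_pk_ecr(e, ecrs)
  arcs <- signature_arcs(upper_arc_stems(row, ecrs), stems)
  red <- collapse_parallel_arcs(arcs)
  # irreducibility: one more pass must be the identity,
  # and a pseudoknot cannot reduce to a nested word
  again <- collapse_parallel_arcs(red)
  if (nrow(again) != nrow(red))
    stop("internal error: signature reduction is not idempotent",
         call. = FALSE)
  if (!any(arc_crossing_matrix(red)))
    stop("internal error: reduced pseudoknot signature has no crossing",
         call. = FALSE)
  new_signature("reduced", red)
}

arc_crossing_matrix <- function(arcs) {
  n <- nrow(arcs)
  l <- arcs$left; r <- arcs$right
  outer(seq_len(n), seq_len(n), function(a, b)
    (l[a] < l[b] & l[b] < r[a] & r[a] < r[b]) |
      (l[b] < l[a] & l[a] < r[b] & r[b] < r[a]))
}

# Collapse parallel families (bands): arcs with identical crossing sets,
# split into maximal pairwise-nested chains, each replaced by its hull.
# Arcs with the same crossing set never cross each other, but they can be
# disjoint (e.g. the two outer hairpins of kissing hairpins), hence the
# chain splitting.  One pass suffices because crossing sets are
# family-level invariants; idempotence is asserted by the caller.
collapse_parallel_arcs <- function(arcs) {
  n <- nrow(arcs)
  if (n <= 1L) return(arcs)
  cr <- arc_crossing_matrix(arcs)
  key <- vapply(seq_len(n), function(a)
    paste(which(cr[a, ]), collapse = ","), "")
  fam <- integer(n)
  next_fam <- 0L
  for (grp in split(seq_len(n), key)) {
    grp <- grp[order(arcs$left[grp], -arcs$right[grp])]
    chains <- list()   # each chain tracked by its innermost arc
    for (a in grp) {
      placed <- FALSE
      for (c in seq_along(chains)) {
        inner <- chains[[c]]$inner
        if (arcs$left[[a]] > arcs$left[[inner]] &&
            arcs$right[[a]] < arcs$right[[inner]]) {
          fam[[a]] <- chains[[c]]$fam
          chains[[c]]$inner <- a
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        next_fam <- next_fam + 1L
        fam[[a]] <- next_fam
        chains[[length(chains) + 1L]] <- list(fam = next_fam, inner = a)
      }
    }
  }
  out <- do.call(rbind, lapply(split(seq_len(n), fam), function(idx) {
    d <- data.frame(left = min(arcs$left[idx]), right = max(arcs$right[idx]))
    d$stems <- list(unlist(arcs$stems[idx]))
    d
  }))
  out[order(out$left), , drop = FALSE]
}

#' Recognize a named pseudoknot class from a reduced signature
#'
#' Matches the reduced word against the three named topologies: `abAB`
#' (H-knot), `abAcBC` (kissing hairpins) and `abcABC` (triple knot);
#' everything else is `"other"`.
#'
#' @param sig A `pk_signature` of level `"reduced"` (or a plain word
#'   string, assumed reduced).
#' @return One of `"H_knot"`, `"kissing_hairpins"`, `"triple_knot"`,
#'   `"other"`.
#' @export
named_class <- function(sig) {
  if (inherits(sig, "pk_signature")) {
    if (sig$level != "reduced")
      stop("named classes are defined on reduced signatures, got level '",
           sig$level, "'", call. = FALSE)
    word <- sig$word
  } else {
    stopifnot(is.character(sig), length(sig) == 1L)
    word <- sig
  }
  switch(word,
         abAB = "H_knot",
         abAcBC = "kissing_hairpins",
         abcABC = "triple_knot",
         "other")
}

#' @export
print.pk_signature <- function(x, ...) {
  cat(x$level, " signature: ", x$word, " (", nrow(x$arcs), " arcs)\n",
      sep = "")
  invisible(x)
}
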