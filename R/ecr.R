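#' Elementary closed region decomposition
#'
#' A closed region is an interval no stem pair of which connects its
#' inside to its outside; it is elementary (an ECR) when no proper prefix
#' or suffix is itself closed, and additionally its boundary must be made
#' of stem faces: either (i, j) is a stem face -- a classical ECR -- or
#' there are faces (i, x) and (y, j) of two stems with x, y inside --
#' a pseudoknotted ECR, i.e. a pseudoknot.  Only stem pairs participate;
#' isolated pairs are excluded.  ECRs can nest, giving a forest; unpaired
#' stretches outside every top-level ECR are reported as exterior
#' segments.
#'
#' The implementation scans only candidate intervals whose ends are face
#' endpoints (a consequence of the boundary condition) and checks closure
#' and elementarity on a partner vector; the brute-force
#' [oracle_ecrs()] instead tests every interval directly against the
#' defining conditions.
#'
#' @param s An [rna_structure].
#' @param stems A [find_stems()] result for `s`.
#' @return A data frame of class `rna_ecrs`, one row per ECR in pre-order
#'   (by start, outermost first), with columns `id`, `start`, `end`,
#'   `kind` (`"classical"`/`"pseudoknotted"`), `parent` (id or `NA`),
#'   `depth` (top level = 1) and a list column `member_stems` (ids of
#'   stems whose wings lie within the interval).  Attribute `"exterior"`
#'   is a data frame of the segments covered by no top-level ECR.
#' @examples
#' s <- parse_dotbracket("((..))")
#' find_ecrs(s, find_stems(s, "arbitrary"))
#' @export
find_ecrs <- function(s, stems) {
  sp <- stems_partner(stems, s$length)
  lefts <- stems$face_i
  rights <- stems$face_j
  found <- list()
  for (i in lefts) {
    for (j in rights) {
      if (j <= i) next
      v <- sp[i:j]
      if (!all(v == 0L | (v >= i & v <= j))) next          # closure
      idx <- i:j
      g <- pmax(idx, v)                                     # v <= j here
      M <- cummax(g)
      len <- j - i + 1L
      if (any(M[-len] == idx[-len])) next                   # elementarity
      found[[length(found) + 1L]] <- c(i, j)
    }
  }
  build_ecr_forest(found, sp, s$length, stems)
}

build_ecr_forest <- function(intervals, sp, length, stems) {
  n <- length(intervals)
  start <- vapply(intervals, `[[`, 1L, 1L)
  end <- vapply(intervals, `[[`, 1L, 2L)
  ord <- order(start, -end)
  start <- start[ord]; end <- end[ord]

  # laminarity check: closed regions never partially overlap
  if (n > 1L) {
    for (a in seq_len(n - 1L)) {
      b <- a + 1L
      while (b <= n && start[[b]] <= end[[a]]) {
        if (end[[b]] > end[[a]])
          stop("internal error: partially overlapping ECRs ",
               "[", start[[a]], ",", end[[a]], "] and ",
               "[", start[[b]], ",", end[[b]], "]", call. = FALSE)
        b <- b + 1L
      }
    }
  }

  parent <- rep(NA_integer_, n)
  depth <- integer(n)
  stack <- integer(0)
  for (r in seq_len(n)) {
    while (length(stack) > 0L && start[[r]] > end[[stack[[length(stack)]]]])
      stack <- stack[-length(stack)]
    if (length(stack) > 0L) parent[[r]] <- stack[[length(stack)]]
    depth[[r]] <- length(stack) + 1L
    stack <- c(stack, r)
  }

  kind <- ifelse(n > 0L & sp[start] == end, "classical", "pseudoknotted")
  members <- lapply(seq_len(n), function(r)
    stems$id[stems$face_i >= start[[r]] & stems$face_j <= end[[r]]])

  df <- data.frame(id = seq_len(n),
                   start = start, end = end,
                   kind = as.character(kind),
                   parent = parent, depth = depth)
  df$member_stems <- members

  covered <- rep(FALSE, length)
  top <- df[is.na(df$parent), , drop = FALSE]
  for (r in seq_len(nrow(top)))
    covered[top$start[[r]]:top$end[[r]]] <- TRUE
  ext <- runs_of(which(!covered))
  attr(df, "exterior") <- ext
  class(df) <- c("rna_ecrs", "data.frame")
  df
}

runs_of <- function(pos) {
  if (length(pos) == 0L)
    return(data.frame(segment = integer(0), start = integer(0),
                      end = integer(0)))
  brk <- c(0L, which(diff(pos) > 1L), length(pos))
  data.frame(segment = seq_len(length(brk) - 1L),
             start = pos[brk[-length(brk)] + 1L],
             end = pos[brk[-1L]])
}

#' Classify an ECR as classical or pseudoknotted
#'
#' Classical when its boundary (i, j) is a stem face; otherwise it is a
#' pseudoknot.
#'
#' @param e An ECR id (row of the `id` column) or a single row of a
#'   [find_ecrs()] result.
#' @param ecrs The [find_ecrs()] table (needed when `e` is an id).
#' @return `"classical"` or `"pseudoknotted"`.
#' @export
classify_ecr <- function(e, ecrs = NULL) {
  if (!is.null(ecrs)) e <- ecrs[ecrs$id == e, , drop = FALSE]
  stopifnot(nrow(e) == 1L)
  e$kind
}

ecr_children <- function(ecrs, id) {
  ecrs[!is.na(ecrs$parent) & ecrs$parent == id, , drop = FALSE]
}

ecr_descendant_stems <- function(ecrs, id) {
  # stems inside any proper sub-ECR of `id`
  e <- ecrs[ecrs$id == id, ]
  sub <- ecrs[ecrs$start > e$start & ecrs$end < e$end, , drop = FALSE]
  unique(unlist(sub$member_stems))
}
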