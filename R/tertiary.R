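#' Map a position to its secondary-structure element
#'
#' Priority rule: any stem-wing position is a helix position of its owner
#' stem (even when that wing sits inside another stem's loop); otherwise
#' the position is assigned to a loop containing it -- in pseudoknots a
#' position can lie in several loops, in which case the innermost owner
#' (smallest internal-pair span, ties by stem id) wins; positions in no
#' top-level ECR are exterior, indexed by segment.
#'
#' @param t Position (1-based).
#' @param ann An [annotate_structure()] result.
#' @param loop_priority Invert the helix-priority rule for sensitivity
#'   analysis: a wing position lying in some loop is then reported as a
#'   loop position.
#' @return List with `kind` (`"helix"`, `"loop"` or `"exterior"`) and
#'   `id` (stem id, loop owner-stem id, or exterior segment index).
#' @export
element_of <- function(t, ann, loop_priority = FALSE) {
  stopifnot(inherits(ann, "rna_annotation"))
  if (t < 1L || t > ann$structure$length)
    stop("position ", t, " is out of range [1, ", ann$structure$length,
         "]", call. = FALSE)
  stems <- ann$stems
  wing_owner <- NA_integer_
  for (r in seq_len(nrow(stems))) {
    if (t %in% stem_wing_positions(stems[r, ])) {
      wing_owner <- stems$id[[r]]
      break
    }
  }
  loop_owner <- NA_integer_
  span <- Inf
  for (l in ann$loops) {
    if (t %in% l$positions) {
      st <- stem_row(stems, l$owner)
      w <- st$face_j - st$face_i - 2L * st$k
      if (w < span || (w == span && l$owner < loop_owner)) {
        span <- w
        loop_owner <- l$owner
      }
    }
  }
  if (!is.na(wing_owner) && !(loop_priority && !is.na(loop_owner)))
    return(list(kind = "helix", id = wing_owner))
  if (!is.na(loop_owner))
    return(list(kind = "loop", id = loop_owner))
  ext <- attr(ann$ecrs, "exterior")
  seg <- which(ext$start <= t & t <= ext$end)
  if (length(seg) == 1L)
    return(list(kind = "exterior", id = ext$segment[[seg]]))
  # inside an ECR but on no wing and in no loop: should not occur for
  # well-formed annotations; report as exterior segment 0
  list(kind = "exterior", id = 0L)
}

innermost_ecr_kind <- function(t, ecrs) {
  hit <- ecrs[ecrs$start <= t & t <= ecrs$end, , drop = FALSE]
  if (nrow(hit) == 0L) return("classical")
  hit$kind[[which.max(hit$depth)]]
}

#' Classify a tertiary base-base interaction
#'
#' Labels a tertiary pair along three axes.  Structure type comes from
#' the secondary elements of its two endpoints: Helix-Helix (HH),
#' Helix-Loop (HL, both orders) or Loop-Loop (LL); exterior positions
#' count as loop for typing and are flagged.  Locality: an interaction is
#' local when both endpoints sit in the same element, or when one
#' endpoint is in a stem and the other in a loop adjacent to it -- the
#' stem's own loop (e.g. a hairpin loop and its closing stem), a loop
#' that has the stem's face among its faces, or a loop containing one of
#' the stem's wings; everything else is long-range.  Context is
#' pseudoknot when the innermost ECR enclosing either endpoint is
#' pseudoknotted, else classical.
#'
#' @param p Length-2 vector of positions, or one row of
#'   `ann$structure$tertiary`.
#' @param ann An [annotate_structure()] result.
#' @param lw_class Optional Leontis-Westhof label carried through.
#' @inheritParams element_of
#' @return List with `structure_type` (`"HH"`/`"HL"`/`"LL"`), `locality`
#'   (`"local"`/`"long_range"`), `context`
#'   (`"pseudoknot"`/`"classical"`), `lw_class` and `exterior_involved`.
#' @export
classify_interaction <- function(p, ann, lw_class = NA_character_,
                                 loop_priority = FALSE) {
  if (is.data.frame(p)) {
    if (!is.na(p$lw_class[[1L]])) lw_class <- p$lw_class[[1L]]
    p <- c(p$i[[1L]], p$j[[1L]])
  }
  e1 <- element_of(p[[1L]], ann, loop_priority)
  e2 <- element_of(p[[2L]], ann, loop_priority)

  kinds <- sort(c(e1$kind, e2$kind))
  eff1 <- if (e1$kind == "exterior") "loop" else e1$kind
  eff2 <- if (e2$kind == "exterior") "loop" else e2$kind
  structure_type <- if (eff1 == "helix" && eff2 == "helix") "HH"
  else if (eff1 == "loop" && eff2 == "loop") "LL"
  else "HL"

  locality <- if (e1$kind == e2$kind && e1$id == e2$id) "local"
  else if (any(c(e1$kind, e2$kind) == "helix") &&
           any(c(e1$kind, e2$kind) == "loop")) {
    st_id <- if (e1$kind == "helix") e1$id else e2$id
    lp_id <- if (e1$kind == "loop") e1$id else e2$id
    lp <- ann$loops[[match(lp_id, vapply(ann$loops, `[[`, 1L, "owner"))]]
    st <- stem_row(ann$stems, st_id)
    adjacent <- lp_id == st_id ||
      any(lp$faces$x == st$face_i & lp$faces$y == st$face_j) ||
      any(lp$wings_contained$stem == st_id)
    if (adjacent) "local" else "long_range"
  } else "long_range"

  ctx1 <- innermost_ecr_kind(p[[1L]], ann$ecrs)
  ctx2 <- innermost_ecr_kind(p[[2L]], ann$ecrs)
  context <- if (ctx1 == "pseudoknotted" || ctx2 == "pseudoknotted")
    "pseudoknot" else "classical"

  list(structure_type = structure_type, locality = locality,
       context = context, lw_class = lw_class,
       exterior_involved = "exterior" %in% kinds)
}

#' Tabulate tertiary interactions across a collection
#'
#' Counts annotated tertiary pairs over the full grid
#' {HH, HL, LL} x {local, long_range} x {pseudoknot, classical} and adds
#' the two fraction blocks: `pct_pair_types` -- the share of each
#' type/locality cell among all interactions of its context ("fractions
#' of pair types", summing to 100 within each context) -- and
#' `pct_structure_types` -- the split of each type/locality cell between
#' the pseudoknot and classical contexts ("fractions of structure
#' types", summing to 100 within each cell across contexts).
#'
#' @param anns A list of [annotate_structure()] results (structures
#'   without tertiary pairs contribute nothing).
#' @return Data frame of class `interaction_table` with columns
#'   `context`, `structure_type`, `locality`, `n`, `pct_pair_types`,
#'   `pct_structure_types`.  An empty collection yields the all-zero
#'   grid.
#' @export
tabulate_interactions <- function(anns) {
  if (inherits(anns, "rna_annotation")) anns <- list(anns)
  grid <- expand.grid(context = c("pseudoknot", "classical"),
                      structure_type = c("HH", "HL", "LL"),
                      locality = c("local", "long_range"),
                      stringsAsFactors = FALSE)
  grid$n <- 0L
  for (ann in anns) {
    for (lab in ann$interactions) {
      hit <- grid$context == lab$context &
        grid$structure_type == lab$structure_type &
        grid$locality == lab$locality
      grid$n[hit] <- grid$n[hit] + 1L
    }
  }
  ctx_tot <- tapply(grid$n, grid$context, sum)
  grid$pct_pair_types <- ifelse(ctx_tot[grid$context] > 0,
                                100 * grid$n / ctx_tot[grid$context], 0)
  cell <- paste(grid$structure_type, grid$locality)
  cell_tot <- tapply(grid$n, cell, sum)
  grid$pct_structure_types <- ifelse(cell_tot[cell] > 0,
                                     100 * grid$n / cell_tot[cell], 0)
  grid <- grid[order(grid$context, grid$structure_type, grid$locality), ]
  rownames(grid) <- NULL
  class(grid) <- c("interaction_table", "data.frame")
  grid
}
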