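#' Annotate a structure end to end
#'
#' Runs the whole pipeline: maximal stems (and isolated pairs), the ECR
#' forest with exterior segments, one loop per stem with both
#' classification axes, the three signature levels and named class for
#' every pseudoknotted ECR, and -- when tertiary pairs are present --
#' the interaction labels.
#'
#' @param s An [rna_structure].
#' @param stem_type,min_pairs,keep_isolated Passed to [find_stems()].
#' @param loop_priority Passed to [classify_interaction()].
#' @return An object of class `rna_annotation`: list with `structure`,
#'   `stems`, `ecrs`, `loops` (list of [loop_of()] results, one per
#'   stem), `signatures` (data frame `ecr_id`, `start`, `end`, `full`,
#'   `upper`, `reduced`, `named_class`) and `interactions` (list of
#'   [classify_interaction()] labels, or `NULL`).
#' @examples
#' ann <- annotate_structure(fixture_figure1())
#' ann$signatures
#' @export
annotate_structure <- function(s, stem_type = c("standard", "arbitrary"),
                               min_pairs = 2L, keep_isolated = FALSE,
                               loop_priority = FALSE) {
  stem_type <- match.arg(stem_type)
  stems <- find_stems(s, stem_type, min_pairs, keep_isolated)
  ecrs <- find_ecrs(s, stems)
  loops <- lapply(seq_len(nrow(stems)),
                  function(r) loop_of(s, stems[r, ], stems))
  names(loops) <- as.character(stems$id)

  pk <- ecrs[ecrs$kind == "pseudoknotted", , drop = FALSE]
  signatures <- data.frame(ecr_id = pk$id, start = pk$start, end = pk$end,
                           full = character(nrow(pk)),
                           upper = character(nrow(pk)),
                           reduced = character(nrow(pk)),
                           named_class = character(nrow(pk)))
  for (r in seq_len(nrow(pk))) {
    id <- pk$id[[r]]
    signatures$full[[r]] <- full_signature(id, ecrs, stems)$word
    signatures$upper[[r]] <- upper_signature(id, ecrs, stems)$word
    red <- reduced_signature(id, ecrs, stems)
    signatures$reduced[[r]] <- red$word
    signatures$named_class[[r]] <- named_class(red)
  }

  ann <- structure(
    list(structure = s, stems = stems, ecrs = ecrs, loops = loops,
         signatures = signatures, interactions = NULL),
    class = "rna_annotation"
  )
  if (!is.null(s$tertiary)) {
    ann$interactions <- lapply(seq_len(nrow(s$tertiary)), function(r)
      classify_interaction(s$tertiary[r, ], ann,
                           loop_priority = loop_priority))
  }
  ann
}

#' @export
print.rna_annotation <- function(x, ...) {
  cat("RNA annotation: ", x$structure$length, " nt, ",
      nrow(x$structure$pairs), " pairs, ", nrow(x$stems), " stems, ",
      nrow(x$ecrs), " ECRs (",
      sum(x$ecrs$kind == "pseudoknotted"), " pseudoknotted)\n", sep = "")
  sizes <- table(vapply(x$loops, `[[`, "", "size_class"))
  pks <- table(vapply(x$loops, `[[`, "", "pk_class"))
  if (length(sizes) > 0L)
    cat("loops:", paste(names(sizes), sizes, sep = "=", collapse = " "),
        "|", paste(names(pks), pks, sep = "=", collapse = " "), "\n")
  if (nrow(x$signatures) > 0L)
    cat("signatures:",
        paste(x$signatures$reduced, collapse = " "), "\n")
  invisible(x)
}

#' Serialize an annotation report to JSON
#'
#' @param ann An [annotate_structure()] result.
#' @param id Optional structure identifier stored in the report.
#' @param path Optional path; when given the JSON is written there.
#' @return JSON text (a `json` object from jsonlite), invisibly when
#'   written to a file.
#' @export
report_json <- function(ann, id = NULL, path = NULL) {
  stopifnot(inherits(ann, "rna_annotation"))
  st <- ann$stems
  stems_out <- data.frame(
    id = st$id, face_i = st$face_i, face_j = st$face_j,
    internal_i = st$face_i + st$k, internal_j = st$face_j - st$k,
    left_wing_start = st$face_i, left_wing_end = st$face_i + st$k,
    right_wing_start = st$face_j - st$k, right_wing_end = st$face_j,
    length = st$k + 1L, type = st$type
  )
  ecrs_out <- ann$ecrs
  loops_out <- lapply(ann$loops, function(l) list(
    owner_stem = l$owner,
    sides = l$sides,
    faces = l$faces,
    wings = l$wings_contained,
    size_class = l$size_class,
    pk_class = l$pk_class
  ))
  rep <- list(
    schema_version = "1.0",
    id = id,
    length = ann$structure$length,
    sequence = ann$structure$sequence,
    dotbracket = write_dotbracket(ann$structure),
    n_pairs = nrow(ann$structure$pairs),
    stems = stems_out,
    isolated_pairs = attr(ann$stems, "isolated"),
    ecrs = as.data.frame(
      ecrs_out[, c("id", "start", "end", "kind", "parent", "depth")]),
    exterior = attr(ann$ecrs, "exterior"),
    loops = unname(loops_out),
    signatures = ann$signatures,
    interactions = if (!is.null(ann$interactions))
      cbind(ann$structure$tertiary,
            do.call(rbind, lapply(ann$interactions, function(x)
              data.frame(structure_type = x$structure_type,
                         locality = x$locality, context = x$context))))
  )
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, null = "null",
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Write flat per-motif TSV tables for a set of annotations
#'
#' Emits `stems.tsv`, `ecrs.tsv`, `loops.tsv`, `signatures.tsv` and
#' `interactions.tsv` (when any structure carries tertiary pairs), each
#' with a leading `structure` column.
#'
#' @param anns Named list of [annotate_structure()] results.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report_tables <- function(anns, dir) {
  if (inherits(anns, "rna_annotation")) anns <- list(structure = anns)
  if (is.null(names(anns))) names(anns) <- seq_along(anns)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grab <- function(f) do.call(rbind, lapply(names(anns), function(nm) {
    d <- f(anns[[nm]])
    if (is.null(d) || nrow(d) == 0L) return(NULL)
    cbind(structure = nm, d)
  }))
  tables <- list(
    stems = grab(function(a)
      as.data.frame(a$stems[, c("id", "face_i", "face_j", "k", "n_pairs",
                                "type")])),
    ecrs = grab(function(a)
      as.data.frame(a$ecrs[, c("id", "start", "end", "kind", "parent",
                               "depth")])),
    loops = grab(function(a) do.call(rbind, lapply(a$loops, function(l)
      data.frame(owner_stem = l$owner,
                 n_sides = nrow(l$sides), n_faces = nrow(l$faces),
                 n_wings = nrow(l$wings_contained),
                 size_class = l$size_class, pk_class = l$pk_class)))),
    signatures = grab(function(a) a$signatures),
    interactions = grab(function(a) {
      if (is.null(a$interactions)) return(NULL)
      cbind(a$structure$tertiary,
            do.call(rbind, lapply(a$interactions, function(x)
              data.frame(structure_type = x$structure_type,
                         locality = x$locality, context = x$context))))
    })
  )
  paths <- character(0)
  for (nm in names(tables)) {
    if (is.null(tables[[nm]])) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
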