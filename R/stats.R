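#' Aggregate motif statistics over a collection
#'
#' Counts structural elements per structure and in total: chains, base
#' pairs, stems, isolated pairs, loops by size class and pseudoknot
#' class, ECRs by kind, pseudoknots by reduced signature.  Totals are the
#' sums of the per-structure counts, so statistics are additive under
#' collection concatenation.
#'
#' @param anns Named list of [annotate_structure()] results (or of
#'   [rna_structure] objects, which are annotated first).
#' @param ... Passed to [annotate_structure()] when annotation is run
#'   implicitly.
#' @return A list of class `stats_report` with `totals` (named numeric),
#'   `loop_classes` (size class x pseudoknot class contingency table),
#'   `signature_table` (data frame `signature`, `named_class`, `count`,
#'   sorted by count then word) and `per_structure` (data frame of
#'   per-structure counts).
#' @export
collection_stats <- function(anns, ...) {
  anns <- as_annotation_list(anns, ...)
  per <- do.call(rbind, lapply(names(anns), function(nm) {
    a <- anns[[nm]]
    data.frame(
      structure = nm,
      length = a$structure$length,
      n_pairs = nrow(a$structure$pairs),
      n_stems = nrow(a$stems),
      n_isolated = nrow(attr(a$stems, "isolated")),
      n_loops = length(a$loops),
      n_ecrs = nrow(a$ecrs),
      n_classical_ecrs = sum(a$ecrs$kind == "classical"),
      n_pseudoknots = sum(a$ecrs$kind == "pseudoknotted"),
      n_tertiary = if (is.null(a$structure$tertiary)) 0L
      else nrow(a$structure$tertiary)
    )
  }))
  if (is.null(per))
    per <- data.frame(structure = character(0), length = integer(0),
                      n_pairs = integer(0), n_stems = integer(0),
                      n_isolated = integer(0), n_loops = integer(0),
                      n_ecrs = integer(0), n_classical_ecrs = integer(0),
                      n_pseudoknots = integer(0), n_tertiary = integer(0))
  totals <- c(n_structures = nrow(per),
              vapply(per[, -1L, drop = FALSE], sum, 0))

  size_levels <- c("hairpin", "internal", "bulge", "multiple_junction")
  pk_levels <- c("classical", "isolated", "pseudoknotted")
  loop_classes <- table(
    factor(unlist(lapply(anns, function(a)
      vapply(a$loops, `[[`, "", "size_class"))), levels = size_levels),
    factor(unlist(lapply(anns, function(a)
      vapply(a$loops, `[[`, "", "pk_class"))), levels = pk_levels),
    dnn = c("size_class", "pk_class"))

  sigs <- unlist(lapply(anns, function(a) a$signatures$reduced))
  if (length(sigs) > 0L) {
    tab <- table(sigs)
    signature_table <- data.frame(signature = names(tab),
                                  count = as.integer(tab))
    signature_table$named_class <-
      vapply(signature_table$signature, named_class, "")
    signature_table <- signature_table[
      order(-signature_table$count, signature_table$signature), ,
      drop = FALSE]
    rownames(signature_table) <- NULL
  } else {
    signature_table <- data.frame(signature = character(0),
                                  count = integer(0),
                                  named_class = character(0))
  }

  structure(list(totals = totals, loop_classes = loop_classes,
                 signature_table = signature_table, per_structure = per),
            class = "stats_report")
}

as_annotation_list <- function(x, ...) {
  if (inherits(x, "rna_annotation") || inherits(x, "rna_structure"))
    x <- list(x)
  x <- lapply(x, function(el)
    if (inherits(el, "rna_structure")) annotate_structure(el, ...) else el)
  if (is.null(names(x)) && length(x) > 0L)
    names(x) <- paste0("structure_", seq_along(x))
  x
}

#' @export
print.stats_report <- function(x, ...) {
  cat("Collection statistics\n")
  for (nm in names(x$totals))
    cat(sprintf("  %-18s %g\n", nm, x$totals[[nm]]))
  if (sum(x$loop_classes) > 0L) {
    cat("Loops by class:\n")
    print(x$loop_classes)
  }
  if (nrow(x$signature_table) > 0L) {
    cat("Pseudoknots by reduced signature:\n")
    print(x$signature_table, row.names = FALSE)
  }
  invisible(x)
}

#' Parse a search query in disjunctive normal form
#'
#' Grammar: elementary predicates `key=value` joined by `AND` and `OR`
#' (case-insensitive), with `AND` binding tighter; parentheses are not
#' supported, so every query is a disjunction of conjunctions.  An empty
#' query matches everything.
#'
#' Supported keys: `signature` (reduced level; `signature.full` /
#' `signature.upper` / `signature.reduced` select a level), `named`
#' (H_knot / kissing_hairpins / triple_knot), `loop` (hairpin / internal
#' / bulge / multiple_junction), `loop_class` (classical / isolated /
#' pseudoknotted), `min_stems`, `max_stems`, `seq` (regular expression
#' over the sequence), `dotbracket` (regular expression over the written
#' dot-bracket string).  Ion and ligand predicates (`ion`, `mg`, `ca`,
#' `ligand`) require 3D information and are rejected with a clear
#' message.
#'
#' @param text Query string.
#' @return A list of class `rna_query`: one element per conjunction, each
#'   a list of predicates `list(key, level, value)`.
#' @examples
#' parse_query("signature=abAB AND min_stems=2 OR loop=bulge")
#' @export
parse_query <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- strsplit(trimws(text), "[[:space:]]+")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L)
    return(structure(list(), class = "rna_query"))

  known <- c("signature", "named", "loop", "loop_class", "min_stems",
             "max_stems", "seq", "dotbracket")
  rejected <- c("ion", "mg", "ca", "metal", "ligand")

  parse_pred <- function(tok, pos) {
    if (toupper(tok) %in% c("AND", "OR"))
      stop("query syntax error at token ", pos,
           ": expected a predicate, got '", tok, "'", call. = FALSE)
    eq <- regexpr("=", tok, fixed = TRUE)
    if (eq < 0L)
      stop("query syntax error at token ", pos, ": '", tok,
           "' is not of the form key=value", call. = FALSE)
    key <- substr(tok, 1L, eq - 1L)
    value <- substr(tok, eq + 1L, nchar(tok))
    level <- NULL
    if (grepl(".", key, fixed = TRUE)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
      key <- parts[[1L]]
      level <- parts[[2L]]
    }
    lkey <- tolower(key)
    if (lkey %in% rejected)
      stop("query error at token ", pos, ": predicate '", key,
           "' needs 3D/ligand information, which annotation-based search ",
           "does not cover", call. = FALSE)
    if (!lkey %in% known)
      stop("query syntax error at token ", pos, ": unknown key '", key,
           "'", call. = FALSE)
    if (lkey == "signature") {
      if (is.null(level)) level <- "reduced"
      if (!level %in% c("full", "upper", "reduced"))
        stop("query syntax error at token ", pos,
             ": unknown signature level '", level, "'", call. = FALSE)
    }
    if (!nzchar(value))
      stop("query syntax error at token ", pos, ": empty value",
           call. = FALSE)
    list(key = lkey, level = level, value = value)
  }

  disjuncts <- list()
  conj <- list(parse_pred(tokens[[1L]], 1L))
  t <- 2L
  while (t <= length(tokens)) {
    op <- toupper(tokens[[t]])
    if (!op %in% c("AND", "OR"))
      stop("query syntax error at token ", t, ": expected AND or OR, got '",
           tokens[[t]], "'", call. = FALSE)
    if (t + 1L > length(tokens))
      stop("query syntax error at token ", t + 1L,
           ": dangling '", op, "'", call. = FALSE)
    pred <- parse_pred(tokens[[t + 1L]], t + 1L)
    if (op == "AND") {
      conj[[length(conj) + 1L]] <- pred
    } else {
      disjuncts[[length(disjuncts) + 1L]] <- conj
      conj <- list(pred)
    }
    t <- t + 2L
  }
  disjuncts[[length(disjuncts) + 1L]] <- conj
  structure(disjuncts, class = "rna_query")
}

eval_predicate <- function(pred, ann) {
  switch(pred$key,
         signature = {
           col <- ann$signatures[[pred$level]]
           any(col == pred$value)
         },
         named = any(ann$signatures$named_class == pred$value),
         loop = any(vapply(ann$loops, `[[`, "", "size_class") == pred$value),
         loop_class = any(vapply(ann$loops, `[[`, "", "pk_class") ==
                            pred$value),
         min_stems = nrow(ann$stems) >= as.integer(pred$value),
         max_stems = nrow(ann$stems) <= as.integer(pred$value),
         seq = !is.null(ann$structure$sequence) &&
           grepl(pred$value, ann$structure$sequence),
         dotbracket = grepl(pred$value, write_dotbracket(ann$structure),
                            fixed = FALSE),
         stop("unhandled predicate key ", pred$key, call. = FALSE))
}

#' Does an annotation match a query?
#'
#' A structure matches when any conjunction has all its predicates true;
#' the empty query matches everything.
#'
#' @param ann An [annotate_structure()] result.
#' @param query An [parse_query()] result or a query string.
#' @return Logical.
#' @export
match_query <- function(ann, query) {
  if (is.character(query)) query <- parse_query(query)
  if (length(query) == 0L) return(TRUE)
  for (conj in query) {
    if (all(vapply(conj, eval_predicate, TRUE, ann = ann))) return(TRUE)
  }
  FALSE
}

#' Search a collection of structures
#'
#' @param anns Named list of annotations or structures (see
#'   [collection_stats()]).
#' @inheritParams match_query
#' @param ... Passed to [annotate_structure()] for implicit annotation.
#' @return Sorted character vector of the ids (names) of matching
#'   structures.
#' @examples
#' coll <- list(f1 = fixture_figure1(), kiss = fixture_kissing())
#' search_structures(coll, "signature=abAB")
#' @export
search_structures <- function(anns, query, ...) {
  anns <- as_annotation_list(anns, ...)
  if (is.character(query)) query <- parse_query(query)
  hits <- names(anns)[vapply(anns, match_query, TRUE, query = query)]
  sort(hits)
}
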