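#' Parse extended dot-bracket notation
#'
#' Bracket families are, in precedence order, `()`, `[]`, `{}`, `<>`, then
#' letter pairs `Aa`, `Bb`, ... where the capital letter opens and the
#' lower-case letter closes.  Dots are unpaired positions; whitespace is
#' ignored.  Each family is matched independently with a stack, so families
#' may cross each other (pseudoknots).
#'
#' @param text A dot-bracket string (one structure).
#' @return An [rna_structure] without sequence.
#' @examples
#' parse_dotbracket("((..))")$pairs
#' parse_dotbracket("(.[.).]")$pairs   # one crossing pair per family
#' @export
parse_dotbracket <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]", "", text)
  if (nchar(text) == 0L)
    return(rna_structure(0L))
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(chars)

  open <- c("(", "[", "{", "<", LETTERS)
  close <- c(")", "]", "}", ">", letters)
  fam_name <- paste0(open, close)

  stacks <- vector("list", length(open))
  pairs <- matrix(integer(0), ncol = 2L)
  for (t in seq_len(n)) {
    ch <- chars[[t]]
    if (ch == ".") next
    fo <- match(ch, open)
    if (!is.na(fo)) {
      stacks[[fo]] <- c(stacks[[fo]], t)
      next
    }
    fc <- match(ch, close)
    if (is.na(fc))
      stop("dot-bracket parse error: unknown character '", ch,
           "' at position ", t, call. = FALSE)
    st <- stacks[[fc]]
    if (length(st) == 0L)
      stop("dot-bracket parse error: unbalanced '", ch,
           "' of family ", fam_name[[fc]], " at position ", t,
           call. = FALSE)
    pairs <- rbind(pairs, c(st[[length(st)]], t))
    stacks[[fc]] <- st[-length(st)]
  }
  left_over <- which(vapply(stacks, length, 1L) > 0L)
  if (length(left_over) > 0L) {
    f <- left_over[[1L]]
    stop("dot-bracket parse error: unbalanced '", open[[f]],
         "' of family ", fam_name[[f]], " at position ",
         stacks[[f]][[1L]], call. = FALSE)
  }
  rna_structure(n, pairs = pairs)
}

#' Write extended dot-bracket notation
#'
#' Bracket families are assigned by greedy colouring of the pair-crossing
#' conflict graph, processing pairs by ascending left end: each pair takes
#' the first family not used by any already-coloured pair crossing it.
#' The output is deterministic and `parse_dotbracket()` round-trips it.
#'
#' @param s An [rna_structure].
#' @return A single string of length `s$length`.
#' @export
write_dotbracket <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  open <- c("(", "[", "{", "<", LETTERS)
  close <- c(")", "]", "}", ">", letters)
  out <- rep(".", s$length)
  p <- s$pairs
  if (nrow(p) > 0L) {
    fam <- integer(nrow(p))
    for (r in seq_len(nrow(p))) {
      i <- p[r, 1L]; j <- p[r, 2L]
      used <- integer(0)
      if (r > 1L) {
        m <- p[seq_len(r - 1L), 1L]; n <- p[seq_len(r - 1L), 2L]
        cross <- (m < i & i < n & n < j) | (i < m & m < j & j < n)
        used <- unique(fam[seq_len(r - 1L)][cross])
      }
      f <- setdiff(seq_along(open), used)[1L]
      if (is.na(f))
        stop("cannot write dot-bracket: more than ", length(open),
             " mutually crossing bracket families required", call. = FALSE)
      fam[[r]] <- f
      out[[i]] <- open[[f]]
      out[[j]] <- close[[f]]
    }
  }
  paste(out, collapse = "")
}

split_lines <- function(text) {
  lines <- unlist(strsplit(text, "\r?\n"))
  lines <- sub("#.*$", "", lines)
  lines[nzchar(trimws(lines))]
}

check_reciprocal <- function(pos, partner, what) {
  look <- integer(max(c(pos, partner, 0L)))
  look[pos] <- partner
  for (r in seq_along(pos)) {
    pr <- partner[[r]]
    if (pr == 0L) next
    if (pr > length(look) || look[[pr]] != pos[[r]])
      stop(what, " format error: positions ", pos[[r]], " and ", pr,
           " do not declare each other as partners", call. = FALSE)
  }
  invisible(NULL)
}

#' Parse a CT file
#'
#' Standard connectivity-table records: a header line whose first token is
#' the chain length, then one 6-column row per nucleotide
#' (index, base, previous, next, partner, natural index); partner 0 means
#' unpaired.  Reciprocal partner declarations are checked.
#'
#' @param text CT file contents as a single string.
#' @return An [rna_structure] with sequence.
#' @export
parse_ct <- function(text) {
  lines <- split_lines(text)
  if (length(lines) == 0L) return(rna_structure(0L))
  hdr <- strsplit(trimws(lines[[1L]]), "[[:space:]]+")[[1L]]
  n <- suppressWarnings(as.integer(hdr[[1L]]))
  if (is.na(n))
    stop("CT format error: header must start with the chain length",
         call. = FALSE)
  body <- lines[-1L]
  if (length(body) != n)
    stop("CT format error: header declares ", n, " residues but ",
         length(body), " rows follow", call. = FALSE)
  if (n == 0L) return(rna_structure(0L))
  fields <- strsplit(trimws(body), "[[:space:]]+")
  ncol_ok <- vapply(fields, length, 1L) >= 5L
  if (!all(ncol_ok))
    stop("CT format error: row ", which(!ncol_ok)[[1L]],
         " has fewer than 5 columns", call. = FALSE)
  idx <- as.integer(vapply(fields, `[[`, "", 1L))
  base <- vapply(fields, `[[`, "", 2L)
  partner <- as.integer(vapply(fields, `[[`, "", 5L))
  if (anyNA(idx) || anyNA(partner))
    stop("CT format error: non-numeric index or partner column",
         call. = FALSE)
  if (!identical(idx, seq_len(n)))
    stop("CT format error: residue indices must run 1..", n, call. = FALSE)
  if (any(partner < 0L | partner > n))
    stop("CT format error: partner index out of range", call. = FALSE)
  check_reciprocal(idx, partner, "CT")
  keep <- partner > idx
  rna_structure(n, pairs = cbind(idx[keep], partner[keep]),
                sequence = paste(base, collapse = ""))
}

#' Write a CT file
#'
#' @param s An [rna_structure]; positions without sequence are written as N.
#' @param title Optional header title.
#' @return CT file contents as a single string.
#' @export
write_ct <- function(s, title = "knotann") {
  stopifnot(inherits(s, "rna_structure"))
  n <- s$length
  base <- structure_bases(s)
  partner <- pair_partner(s)
  rows <- sprintf("%d %s %d %d %d %d", seq_len(n), base,
                  seq_len(n) - 1L, c(seq_len(n)[-1L], 0L)[seq_len(n)],
                  partner, seq_len(n))
  paste(c(paste(n, title), rows), collapse = "\n")
}

#' Parse a BPSEQ file
#'
#' Three columns per row: position, base, partner (0 = unpaired).
#' Positions may be sparse; the chain length is the largest position seen.
#'
#' @param text BPSEQ file contents as a single string.
#' @return An [rna_structure] with sequence (missing positions become N).
#' @export
parse_bpseq <- function(text) {
  lines <- split_lines(text)
  if (length(lines) == 0L) return(rna_structure(0L))
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  ncol_ok <- vapply(fields, length, 1L) >= 3L
  if (!all(ncol_ok))
    stop("BPSEQ format error: row ", which(!ncol_ok)[[1L]],
         " has fewer than 3 columns", call. = FALSE)
  pos <- as.integer(vapply(fields, `[[`, "", 1L))
  base <- vapply(fields, `[[`, "", 2L)
  partner <- as.integer(vapply(fields, `[[`, "", 3L))
  if (anyNA(pos) || anyNA(partner))
    stop("BPSEQ format error: non-numeric position or partner column",
         call. = FALSE)
  if (anyDuplicated(pos))
    stop("BPSEQ format error: duplicate position ",
         pos[duplicated(pos)][[1L]], call. = FALSE)
  n <- max(pos)
  if (any(partner < 0L | partner > n))
    stop("BPSEQ format error: partner index out of range", call. = FALSE)
  check_reciprocal(pos, partner, "BPSEQ")
  seq <- rep("N", n)
  seq[pos] <- base
  keep <- partner > pos
  rna_structure(n, pairs = cbind(pos[keep], partner[keep]),
                sequence = paste(seq, collapse = ""))
}

#' Write a BPSEQ file
#'
#' @inheritParams write_ct
#' @return BPSEQ file contents as a single string.
#' @export
write_bpseq <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  paste(sprintf("%d %s %d", seq_len(s$length), structure_bases(s),
                pair_partner(s)), collapse = "\n")
}

structure_bases <- function(s) {
  if (is.null(s$sequence)) rep("N", s$length)
  else strsplit(s$sequence, "", fixed = TRUE)[[1L]]
}

#' Parse a tabular base-pair file
#'
#' Tab-separated values with a header line; required columns `i`, `j`,
#' `base_i`, `base_j`, optional `lw_class` (Leontis-Westhof label) and
#' `canonical` (true/false).  Rows flagged canonical go into the
#' secondary-structure matching; non-canonical rows become tertiary pairs.
#' A canonical row whose position already has a secondary partner is a
#' multiplet: by default this is an error; with
#' `resolve_multiplets = "first"` the first-listed pair per position is
#' kept and later conflicting rows are demoted to tertiary pairs.
#'
#' @param text File contents as a single string.
#' @param length Chain length; defaults to the largest position seen.
#' @param resolve_multiplets `"error"` (default) or `"first"`.
#' @return An [rna_structure] with sequence (N where no row mentions a
#'   position) and tertiary pairs.
#' @export
parse_pairs_table <- function(text, length = NULL,
                              resolve_multiplets = c("error", "first")) {
  resolve_multiplets <- match.arg(resolve_multiplets)
  lines <- split_lines(text)
  if (length(lines) == 0L)
    return(rna_structure(if (is.null(length)) 0L else length))
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
  need <- c("i", "j", "base_i", "base_j")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("pairs table format error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"canonical" %in% names(df)) df$canonical <- TRUE
  df$canonical <- as.logical(df$canonical)
  if (!"lw_class" %in% names(df)) df$lw_class <- NA_character_
  df$i <- as.integer(df$i); df$j <- as.integer(df$j)
  n <- if (is.null(length)) max(df$i, df$j, 0L) else as.integer(length)

  partner <- integer(n)
  sec <- matrix(integer(0), ncol = 2L)
  tert <- df[0L, c("i", "j", "lw_class", "canonical")]
  for (r in seq_len(nrow(df))) {
    i <- min(df$i[[r]], df$j[[r]]); j <- max(df$i[[r]], df$j[[r]])
    if (isTRUE(df$canonical[[r]])) {
      clash <- c(i, j)[partner[c(i, j)] != 0L]
      if (length(clash) > 0L) {
        if (resolve_multiplets == "error")
          stop("multiplet error: position ", clash[[1L]],
               " takes part in more than one canonical pair",
               " (use resolve_multiplets = \"first\")", call. = FALSE)
        tert <- rbind(tert, data.frame(i = i, j = j,
                                       lw_class = df$lw_class[[r]],
                                       canonical = TRUE))
        next
      }
      partner[[i]] <- j; partner[[j]] <- i
      sec <- rbind(sec, c(i, j))
    } else {
      tert <- rbind(tert, data.frame(i = i, j = j,
                                     lw_class = df$lw_class[[r]],
                                     canonical = FALSE))
    }
  }
  seq <- rep("N", n)
  seq[df$i] <- toupper(df$base_i)
  seq[df$j] <- toupper(df$base_j)
  rna_structure(n, pairs = sec, sequence = paste(seq, collapse = ""),
                tertiary = if (nrow(tert) > 0L) tert else NULL)
}

#' Write a tabular base-pair file
#'
#' Inverse of [parse_pairs_table()]: secondary pairs are written with
#' `canonical = true`, tertiary pairs with their stored flag and
#' Leontis-Westhof label.
#'
#' @inheritParams write_ct
#' @return TSV contents as a single string (with header).
#' @export
write_pairs_table <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  base <- structure_bases(s)
  rows <- character(0)
  if (nrow(s$pairs) > 0L)
    rows <- sprintf("%d\t%d\t%s\t%s\t%s\ttrue", s$pairs[, 1L], s$pairs[, 2L],
                    base[s$pairs[, 1L]], base[s$pairs[, 2L]], "")
  if (!is.null(s$tertiary))
    rows <- c(rows, sprintf("%d\t%d\t%s\t%s\t%s\t%s",
                            s$tertiary$i, s$tertiary$j,
                            base[s$tertiary$i], base[s$tertiary$j],
                            ifelse(is.na(s$tertiary$lw_class), "",
                                   s$tertiary$lw_class),
                            ifelse(s$tertiary$canonical, "true", "false")))
  paste(c("i\tj\tbase_i\tbase_j\tlw_class\tcanonical", rows),
        collapse = "\n")
}

#' Read a structure file, dispatching on format
#'
#' @param path File path.
#' @param format One of `"auto"`, `"dotbracket"`, `"ct"`, `"bpseq"`,
#'   `"pairs"`.  `"auto"` dispatches on the file extension
#'   (`.db`/`.dbn`/`.dot` dot-bracket, `.ct`, `.bpseq`, `.tsv`/`.pairs`).
#' @param ... Passed to the format parser (e.g. `resolve_multiplets`).
#' @return An [rna_structure].
#' @export
read_structure <- function(path, format = "auto", ...) {
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext,
                     db = , dbn = , dot = , dotbracket = "dotbracket",
                     ct = "ct",
                     bpseq = "bpseq",
                     tsv = , pairs = "pairs",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format= explicitly", call. = FALSE))
  }
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  switch(format,
         dotbracket = parse_dotbracket(text),
         ct = parse_ct(text),
         bpseq = parse_bpseq(text),
         pairs = parse_pairs_table(text, ...),
         stop("unknown format '", format, "'", call. = FALSE))
}

#' Write a structure file in a chosen format
#'
#' @inheritParams write_ct
#' @param format One of `"dotbracket"`, `"ct"`, `"bpseq"`, `"pairs"`.
#' @return The file contents as a single string, invisibly if `path` given.
#' @param path Optional output path; when given the text is also written.
#' @export
format_structure <- function(s, format = c("dotbracket", "ct", "bpseq",
                                           "pairs"), path = NULL) {
  format <- match.arg(format)
  text <- switch(format,
                 dotbracket = write_dotbracket(s),
                 ct = write_ct(s),
                 bpseq = write_bpseq(s),
                 pairs = write_pairs_table(s))
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}
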