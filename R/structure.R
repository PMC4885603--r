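#' Construct an RNA secondary structure
#'
#' The central container of the package: a chain of `length` nucleotides,
#' an optional sequence, a secondary-structure pair set that must form a
#' matching (every position in at most one pair), and an optional table of
#' tertiary (typically non-canonical) base-base contacts.  All coordinates
#' are 1-based and intervals are inclusive on both ends.
#'
#' @param length Positive integer (or zero) number of nucleotides.
#' @param pairs Two-column matrix or data frame of paired positions; each
#'   row is stored as (min, max).  `NULL` or zero rows means no pairs.
#' @param sequence Optional string over `A,C,G,U,N` of exactly `length`
#'   characters (`T` is accepted and converted to `U`).
#' @param tertiary Optional data frame with columns `i`, `j` and optionally
#'   `lw_class` (Leontis-Westhof label, e.g. `"tHS"`) and `canonical`.
#'   Tertiary pairs are annotations: they may reuse positions of `pairs`
#'   and need not form a matching.
#' @return An object of class `rna_structure` with fields `length`,
#'   `sequence`, `pairs` (integer matrix, columns `i`, `j`, sorted by `i`)
#'   and `tertiary`.
#' @examples
#' s <- rna_structure(6, pairs = rbind(c(1, 6), c(2, 5)))
#' write_dotbracket(s)
#' @export
rna_structure <- function(length, pairs = NULL, sequence = NULL,
                          tertiary = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 0L)
    stop("'length' must be a non-negative integer", call. = FALSE)

  pairs <- normalize_pairs(pairs)
  if (nrow(pairs) > 0L) {
    if (any(pairs < 1L) || any(pairs > length))
      stop("pair positions must lie in [1, length]", call. = FALSE)
    pos <- as.vector(pairs)
    dup <- pos[duplicated(pos)]
    if (length(dup) > 0L)
      stop("secondary structure is not a matching: position ",
           dup[[1L]], " occurs in more than one pair", call. = FALSE)
  }

  if (!is.null(sequence)) {
    sequence <- toupper(paste(sequence, collapse = ""))
    sequence <- gsub("T", "U", sequence, fixed = TRUE)
    if (nchar(sequence) != length)
      stop("sequence length (", nchar(sequence),
           ") does not match 'length' (", length, ")", call. = FALSE)
    bad <- regmatches(sequence, regexpr("[^ACGUN]", sequence))
    if (length(bad) > 0L && nchar(bad) > 0L)
      stop("sequence contains unsupported residue '", bad,
           "' (allowed: A, C, G, U, N)", call. = FALSE)
  }

  tertiary <- normalize_tertiary(tertiary, length)

  structure(
    list(length = length, sequence = sequence, pairs = pairs,
         tertiary = tertiary),
    class = "rna_structure"
  )
}

normalize_pairs <- function(pairs) {
  if (is.null(pairs) || NROW(pairs) == 0L) {
    m <- matrix(integer(0), ncol = 2L)
    colnames(m) <- c("i", "j")
    return(m)
  }
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs[, 1:2])
  if (is.vector(pairs) && length(pairs) == 2L) pairs <- matrix(pairs, ncol = 2L)
  storage.mode(pairs) <- "integer"
  if (ncol(pairs) != 2L)
    stop("'pairs' must have two columns", call. = FALSE)
  if (any(is.na(pairs)))
    stop("'pairs' contains missing values", call. = FALSE)
  m <- cbind(i = pmin(pairs[, 1L], pairs[, 2L]),
             j = pmax(pairs[, 1L], pairs[, 2L]))
  if (any(m[, 1L] == m[, 2L]))
    stop("a position cannot pair with itself", call. = FALSE)
  m <- m[order(m[, 1L]), , drop = FALSE]
  rownames(m) <- NULL
  m
}

normalize_tertiary <- function(tertiary, length) {
  if (is.null(tertiary) || NROW(tertiary) == 0L) return(NULL)
  tertiary <- as.data.frame(tertiary)
  if (!all(c("i", "j") %in% names(tertiary)))
    stop("'tertiary' needs columns i and j", call. = FALSE)
  i <- as.integer(pmin(tertiary$i, tertiary$j))
  j <- as.integer(pmax(tertiary$i, tertiary$j))
  if (any(i < 1L) || any(j > length))
    stop("tertiary pair positions must lie in [1, length]", call. = FALSE)
  out <- data.frame(
    i = i, j = j,
    lw_class = if ("lw_class" %in% names(tertiary))
      as.character(tertiary$lw_class) else NA_character_,
    canonical = if ("canonical" %in% names(tertiary))
      as.logical(tertiary$canonical) else FALSE,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Partner vector of a structure
#'
#' @param s An [rna_structure].
#' @return Integer vector of length `s$length`; entry `t` is the secondary
#'   partner of position `t`, or 0 if unpaired.
#' @export
pair_partner <- function(s) {
  stopifnot(inherits(s, "rna_structure"))
  partner_of(s$pairs, s$length)
}

partner_of <- function(pairs, length) {
  p <- integer(length)
  if (nrow(pairs) > 0L) {
    p[pairs[, 1L]] <- pairs[, 2L]
    p[pairs[, 2L]] <- pairs[, 1L]
  }
  p
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("RNA secondary structure: ", x$length, " nt, ",
      nrow(x$pairs), " base pairs",
      if (!is.null(x$sequence)) ", with sequence" else "",
      if (!is.null(x$tertiary))
        paste0(", ", nrow(x$tertiary), " tertiary pairs") else "",
      "\n", sep = "")
  if (x$length > 0L && x$length <= 200L)
    cat(write_dotbracket(x), "\n", sep = "")
  invisible(x)
}
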