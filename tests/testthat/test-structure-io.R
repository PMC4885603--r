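test_that("dot-bracket parsing handles nesting, crossing families and edge cases", {
  expect_equal(parse_dotbracket("((..))")$pairs,
               cbind(i = c(1L, 2L), j = c(6L, 5L)))
  expect_equal(parse_dotbracket("(.[.).]")$pairs,
               cbind(i = c(1L, 3L), j = c(5L, 7L)))
  empty <- parse_dotbracket("")
  expect_equal(empty$length, 0L)
  expect_equal(nrow(empty$pairs), 0L)
  # letter families: capital opens, lower-case closes
  s <- parse_dotbracket("..((AA..))..aa..")
  expect_true(all(c(5L, 6L) %in% s$pairs[, "i"]))
  # whitespace ignored
  expect_equal(parse_dotbracket("( ( .\n. ) )")$pairs,
               parse_dotbracket("((..))")$pairs)
})

test_that("dot-bracket parse errors name family and position", {
  expect_error(parse_dotbracket("(()"), "unbalanced.*\\(\\).*position 1")
  expect_error(parse_dotbracket("(.]"), "unbalanced.*\\[\\].*position 3")
  expect_error(parse_dotbracket("(.?)"), "unknown character '\\?' at position 3")
  # a lone closing letter is an unbalanced member of its family
  expect_error(parse_dotbracket("(.x)"), "unbalanced.*Xx.*position 3")
})

test_that("dot-bracket writer uses greedy family assignment", {
  s <- rna_structure(6, pairs = rbind(c(1, 6), c(2, 5)))
  expect_equal(write_dotbracket(s), "((..))")
  expect_equal(write_dotbracket(rna_structure(4)), "....")
  # the H-knot crossing graph is one edge: exactly two families
  db <- write_dotbracket(fixture_hknot())
  fams <- unique(strsplit(gsub("[.]", "", db), "")[[1]])
  expect_setequal(fams, c("(", ")", "[", "]"))
})

test_that("CT and BPSEQ parsing follow the column conventions", {
  ct <- paste("6 test", "1 G 0 2 6 1", "2 C 1 3 5 2", "3 A 2 4 0 3",
              "4 A 3 5 0 4", "5 G 4 6 2 5", "6 C 5 0 1 6", sep = "\n")
  s <- parse_ct(ct)
  expect_equal(s$pairs, cbind(i = c(1L, 2L), j = c(6L, 5L)))
  expect_equal(s$sequence, "GCAAGC")
  expect_equal(parse_bpseq("3 G 0")$length, 3L)
  expect_equal(nrow(parse_bpseq("3 G 0")$pairs), 0L)
  bad_ct <- paste("2 t", "1 G 0 2 2 1", "2 C 1 0 0 2", sep = "\n")
  expect_error(parse_ct(bad_ct), "do not declare each other")
  expect_error(parse_bpseq("1 G 2\n2 C 3\n3 A 2"), "do not declare each other")
})

test_that("pairs tables route canonical rows to pairs and the rest to tertiary", {
  txt <- paste("i\tj\tbase_i\tbase_j\tlw_class\tcanonical",
               "1\t10\tG\tC\tcWW\ttrue",
               "2\t9\tC\tG\tcWW\ttrue",
               "5\t12\tG\tA\ttHS\tfalse", sep = "\n")
  s <- parse_pairs_table(txt)
  expect_equal(s$pairs, cbind(i = c(1L, 2L), j = c(10L, 9L)))
  expect_equal(s$tertiary$i, 5L)
  expect_equal(s$tertiary$lw_class, "tHS")
  expect_false(s$tertiary$canonical)
})

test_that("multiplets error by default and demote under resolve_multiplets=first", {
  txt <- paste("i\tj\tbase_i\tbase_j\tcanonical",
               "1\t10\tG\tC\ttrue",
               "1\t8\tG\tC\ttrue", sep = "\n")
  expect_error(parse_pairs_table(txt), "multiplet.*position 1")
  s <- parse_pairs_table(txt, resolve_multiplets = "first")
  expect_equal(s$pairs, cbind(i = 1L, j = 10L))
  expect_equal(s$tertiary$i, 1L)
  expect_equal(s$tertiary$j, 8L)
})

test_that("all format writers round-trip random structures", {
  for (seed in 1:40) {
    s <- random_structure(seed, pk_prob = 0.5)
    expect_identical(parse_dotbracket(write_dotbracket(s))$pairs, s$pairs)
    ct <- parse_ct(write_ct(s))
    expect_identical(ct$pairs, s$pairs)
    expect_identical(ct$sequence, s$sequence)
    expect_identical(parse_bpseq(write_bpseq(s))$pairs, s$pairs)
    expect_identical(parse_pairs_table(write_pairs_table(s))$pairs, s$pairs)
    expect_identical(ct$length, s$length)
  }
})

test_that("tertiary pairs survive the pairs-table round trip", {
  s <- random_structure(3, pk_prob = 0.3, n_tertiary = 4L)
  back <- parse_pairs_table(write_pairs_table(s), length = s$length)
  expect_identical(back$pairs, s$pairs)
  expect_equal(nrow(back$tertiary), 4L)
  expect_setequal(paste(back$tertiary$i, back$tertiary$j),
                  paste(s$tertiary$i, s$tertiary$j))
})

test_that("structure validation rejects non-matchings and bad coordinates", {
  expect_error(rna_structure(10, pairs = rbind(c(1, 5), c(5, 9))),
               "not a matching")
  expect_error(rna_structure(4, pairs = rbind(c(1, 6))), "\\[1, length\\]")
  expect_error(rna_structure(3, sequence = "ACGU"), "does not match")
  expect_error(rna_structure(2, sequence = "AX"), "unsupported residue")
})
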