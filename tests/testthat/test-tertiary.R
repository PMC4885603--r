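fixture1_with_contacts <- function() {
  f1 <- fixture_figure1()
  rna_structure(f1$length, pairs = f1$pairs, sequence = f1$sequence,
                tertiary = data.frame(
                  i = c(37, 35, 12), j = c(39, 38, 45),
                  lw_class = c("tHS", "cWW", "tWW"),
                  canonical = FALSE))
}

test_that("positions map to helix, loop or exterior with helix priority", {
  ann <- annotate_structure(fixture_figure1())
  q_id <- ann$stems$id[ann$stems$face_i == 34]
  e <- element_of(35, ann)
  expect_equal(e$kind, "helix")
  expect_equal(e$id, q_id)
  e2 <- element_of(33, ann)               # side 32-33 of the big loop
  expect_equal(e2$kind, "loop")
  expect_equal(e2$id, ann$stems$id[ann$stems$face_i == 9])
  e3 <- element_of(5, ann)                # before the first ECR
  expect_equal(e3$kind, "exterior")
  # a crossing wing inside a loop is helix unless loop_priority is set
  e4 <- element_of(13, ann)
  expect_equal(e4$kind, "helix")
  expect_equal(element_of(13, ann, loop_priority = TRUE)$kind, "loop")
  expect_error(element_of(99, ann), "out of range")
})

test_that("interaction labels reproduce the worked examples", {
  ann <- annotate_structure(fixture1_with_contacts())
  labs <- ann$interactions
  # (37,39): both in the hairpin loop of one stem
  expect_equal(labs[[1]]$structure_type, "LL")
  expect_equal(labs[[1]]$locality, "local")
  expect_equal(labs[[1]]$context, "classical")
  # (35,38): a stem and its own loop -- the canonical local example
  expect_equal(labs[[2]]$structure_type, "HL")
  expect_equal(labs[[2]]$locality, "local")
  # (12,45): two sides of the same pseudoknotted junction loop
  expect_equal(labs[[3]]$structure_type, "LL")
  expect_equal(labs[[3]]$locality, "local")
  expect_equal(labs[[3]]$context, "pseudoknot")
  expect_equal(labs[[3]]$lw_class, "tWW")
})

test_that("interaction labels are invariant under endpoint swap", {
  ann <- annotate_structure(fixture_figure1())
  pts <- list(c(37, 39), c(35, 38), c(12, 45), c(5, 33), c(11, 56))
  for (p in pts) {
    a <- classify_interaction(p, ann)
    b <- classify_interaction(rev(p), ann)
    expect_equal(a$structure_type, b$structure_type)
    expect_equal(a$locality, b$locality)
    expect_equal(a$context, b$context)
  }
})

test_that("same-element pairs are always local on generated structures", {
  for (seed in 1:15) {
    s <- random_structure(seed + 30, pk_prob = 0.5, n_tertiary = 6L)
    ann <- annotate_structure(s)
    for (r in seq_len(nrow(s$tertiary))) {
      p <- c(s$tertiary$i[[r]], s$tertiary$j[[r]])
      e1 <- element_of(p[[1]], ann)
      e2 <- element_of(p[[2]], ann)
      if (e1$kind == e2$kind && e1$id == e2$id)
        expect_equal(ann$interactions[[r]]$locality, "local")
    }
  }
})

test_that("the contingency table counts, fractions and additivity behave", {
  ann <- annotate_structure(fixture1_with_contacts())
  tab <- tabulate_interactions(list(ann))
  pick <- function(ctx, ty, loc)
    tab$n[tab$context == ctx & tab$structure_type == ty & tab$locality == loc]
  expect_equal(pick("pseudoknot", "LL", "local"), 1L)
  expect_equal(pick("classical", "LL", "local"), 1L)
  expect_equal(pick("classical", "HL", "local"), 1L)
  expect_equal(sum(tab$n), 3L)
  # fraction blocks sum to 100 within their groups when nonempty
  for (ctx in unique(tab$context)) {
    part <- tab[tab$context == ctx, ]
    if (sum(part$n) > 0) expect_equal(sum(part$pct_pair_types), 100)
  }
  cells <- split(tab, paste(tab$structure_type, tab$locality))
  for (cell in cells)
    if (sum(cell$n) > 0) expect_equal(sum(cell$pct_structure_types), 100)
  # duplicating the structure doubles every count
  tab2 <- tabulate_interactions(list(ann, ann))
  expect_equal(tab2$n, 2L * tab$n)
  # empty input: all-zero grid, no error
  tab0 <- tabulate_interactions(list())
  expect_equal(nrow(tab0), 12L)
  expect_true(all(tab0$n == 0L))
})
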