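test_that("overlap arithmetic reproduces the published validation tables", {
  # human-cargo comparison, totals column
  t2 <- overlap_counts(1415, 1611, 919)
  expect_identical(t2$pct_a_in_b, 64.95)
  expect_identical(t2$pct_b_in_a, 57.05)
  expect_identical(t2$n_union, 2107)
  # human-cargo comparison, virus column
  t2v <- overlap_counts(217, 204, 147)
  expect_identical(t2v$pct_a_in_b, 67.74)
  expect_identical(t2v$pct_b_in_a, 72.06)
  expect_identical(t2v$n_union, 274)
  # domestic-mammal cargo comparison, totals
  t3 <- overlap_counts(915, 1038, 614)
  expect_identical(t3$pct_a_in_b, 67.10)
  expect_identical(t3$pct_b_in_a, 59.15)
  expect_identical(t3$n_union, 1339)
  # wild-mammal interaction comparison, totals
  t4 <- overlap_counts(806, 1694, 516)
  expect_identical(t4$pct_a_in_b, 64.02)
  expect_identical(t4$pct_b_in_a, 30.46)
  expect_identical(t4$n_union, 1984)
})

test_that("overlap handles identity, emptiness and set inputs", {
  o <- overlap(letters[1:5], letters[1:5])
  expect_identical(o$pct_a_in_b, 100)
  expect_identical(o$pct_b_in_a, 100)
  expect_identical(o$n_union, 5L)
  expect_error(overlap(character(), letters), "empty")
  expect_error(overlap_counts(10, 5, 7), "exceeds")
  # duplicates are ignored
  expect_identical(overlap(c("a", "a", "b"), "b")$n_a, 2L)
})

test_that("overlap is symmetric and satisfies the union identity", {
  set.seed(23)
  for (i in 1:30) {
    a <- sample(letters, sample(3:20, 1))
    b <- sample(letters, sample(3:20, 1))
    ab <- overlap(a, b)
    ba <- overlap(b, a)
    expect_identical(ab$pct_a_in_b, ba$pct_b_in_a)
    expect_identical(ab$n_shared, ba$n_shared)
    expect_identical(ab$n_union, ab$n_a + ab$n_b - ab$n_shared)
    expect_identical(ab$n_union, length(union(a, b)))
    expect_lte(ab$n_shared, min(ab$n_a, ab$n_b))
  }
})

test_that("per-category overlaps partition the total", {
  set.seed(29)
  ids <- sprintf("sp%02d", 1:40)
  cats <- structure(rep(c("virus", "bacteria", "helminth", "protozoa"), 10),
                    names = ids)
  a <- sample(ids, 25)
  b <- sample(ids, 25)
  per <- overlap_by_category(a, b, cats)
  expect_identical(sum(vapply(per[names(per) != "Totals"],
                              function(o) o$n_shared, 1L)),
                   per$Totals$n_shared)
  expect_identical(per$Totals$n_union, length(union(a, b)))
  expect_error(overlap_by_category(c(a, "mystery"), b, cats),
               "uncategorized")
})

test_that("pathogen-level overlap projects interactions to in-scope cargoes", {
  a <- data.frame(cargo_id = c("P", "P", "Q"),
                  carrier_id = c("h1", "h9", "h2"), stringsAsFactors = FALSE)
  b <- data.frame(cargo_id = c("P", "R"), carrier_id = c("h2", "h9"),
                  stringsAsFactors = FALSE)
  o <- pathogen_level_overlap(a, b, host_scope = c("h1", "h2"))
  # P interacts with an in-scope host in both datasets: shared
  expect_identical(o$n_shared, 1L)
  expect_identical(o$n_a, 2L)   # P, Q
  expect_identical(o$n_b, 1L)   # P only; R's host is out of scope
  expect_error(pathogen_level_overlap(a, b, character()), "nonempty")
})

test_that("the shared-cargo network weights nodes and edges by cargo counts", {
  tax <- make_tiny_tax()
  ints <- data.frame(
    cargo_id = c("12", "22", "12", "22", "12"),
    carrier_id = c("32", "32", "35", "37", "37"),
    stringsAsFactors = FALSE)
  g <- shared_cargo_network(tax, ints, carrier_scope = c("32", "35", "37"))
  expect_identical(sort(igraph::V(g)$name), c("32", "35", "37"))
  nc <- structure(igraph::V(g)$n_cargo, names = igraph::V(g)$name)
  expect_identical(nc[["32"]], 2L)
  expect_identical(nc[["35"]], 1L)
  w <- igraph::E(g)$weight
  el <- igraph::as_edgelist(g)
  expect_identical(nrow(el), 3L)    # every pair shares at least one cargo
  for (k in seq_along(w))
    expect_lte(w[k], min(nc[[el[k, 1]]], nc[[el[k, 2]]]))
  # restricting cargo categories drops bacteria
  gv <- shared_cargo_network(tax, ints, c("32", "35", "37"),
                             cargo_categories = "virus")
  ncv <- structure(igraph::V(gv)$n_cargo, names = igraph::V(gv)$name)
  expect_identical(ncv[["32"]], 1L)
  # no shared cargo: edgeless graph
  g0 <- shared_cargo_network(tax, ints[c(1, 4), ], c("32", "37"))
  expect_identical(igraph::ecount(g0), 0)
})

test_that("networks export as edge lists and GraphML", {
  tax <- make_tiny_tax()
  ints <- data.frame(cargo_id = c("12", "12"), carrier_id = c("32", "35"),
                     stringsAsFactors = FALSE)
  g <- shared_cargo_network(tax, ints, c("32", "35"))
  tf <- tempfile(fileext = ".tsv")
  write_network(g, tf)
  el <- read.delim(tf, stringsAsFactors = FALSE)
  expect_identical(names(el), c("from", "to", "weight"))
  expect_identical(el$weight, 1L)
  tg <- tempfile(fileext = ".graphml")
  write_network(g, tg, format = "graphml")
  back <- igraph::read_graph(tg, format = "graphml")
  expect_identical(igraph::vcount(back), 2)
  expect_identical(igraph::E(back)$weight, 1)
})

test_that("comparison lists can pre-filter negative prevalence rows", {
  tf <- tempfile(fileext = ".tsv")
  write.table(data.frame(identifier = c("a", "b", "c"),
                         category = "helminth",
                         prevalence = c(0.4, -1, 0)),
              tf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_identical(read_comparison_list(tf)$identifier, c("a", "b", "c"))
  expect_identical(read_comparison_list(tf, nonnegative_prevalence = TRUE)$identifier,
                   c("a", "c"))
})
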