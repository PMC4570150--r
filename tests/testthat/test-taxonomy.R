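test_that("rank reclassification follows the five rules in order", {
  cases <- list(
    list("uncultured bacterium", "species", FALSE, "no_rank"),
    list("Homo sapiens", "no_rank", FALSE, "species"),
    list("Canis lupus familiaris", "species", FALSE, "subspecies"),
    list("Bacillus sp. 56", "species", FALSE, "no_rank"),
    list("Classical swine fever virus", "no_rank", TRUE, "no_rank"),
    list("unclassified Flaviviridae", "species", FALSE, "no_rank"),
    list("Vitis vinifera var. sylvestris", "species", FALSE, "no_rank"),
    list("Varanus komodoensis", "species", FALSE, "species"),
    list("Drosophila", "species", FALSE, "no_rank"))
  for (cs in cases)
    expect_identical(reclassify_rank(cs[[1]], cs[[2]], cs[[3]]), cs[[4]],
                     label = cs[[1]])
  expect_error(reclassify_rank("", "species", FALSE), "empty")
  expect_error(reclassify_rank("Homo sapiens", "genus", FALSE),
               "original_rank")
})

test_that("reclassification is idempotent and matches a brute-force oracle", {
  set.seed(11)
  words <- c("alpha", "beta", "uncultured", "var", "Varanus", "x9",
             "gamma", "unclassified", "delta", "strain")
  for (i in 1:200) {
    nm <- paste(sample(words, sample(1:4, 1), replace = TRUE),
                collapse = " ")
    virus <- i %% 5 == 0
    r1 <- reclassify_rank(nm, "species", virus)
    expect_identical(reclassify_rank(nm, r1, virus), r1, label = nm)
    expect_identical(r1, oracle_rank(nm, "species", virus), label = nm)
  }
})

test_that("rank counts on a synthetic dump equal independent rule application", {
  fx <- generate_fixture(fixture_spec(seed = 21, n_records = 50))
  tab <- fx$taxonomy$nodes
  sub <- tab[tab$original_rank %in% c("species", "subspecies", "no_rank"), ]
  expected <- unname(mapply(oracle_rank, sub$name, sub$original_rank,
                            sub$category %in% c("virus", "viroid")))
  expect_identical(sub$effective_rank, expected)
  expect_identical(as.vector(table(sub$effective_rank)),
                   as.vector(table(expected)))
  # viruses and viroids keep their dump rank
  vir <- tab[tab$category %in% c("virus", "viroid"), ]
  expect_identical(vir$effective_rank, vir$original_rank)
})

test_that("species roll-up walks to the species ancestor and discards higher ranks", {
  tax <- make_tiny_tax()
  expect_identical(resolve_to_species(tax, "32"), "32")    # species
  expect_identical(resolve_to_species(tax, "33"), "32")    # subspecies
  expect_identical(resolve_to_species(tax, "13"), "12")    # strain
  expect_identical(resolve_to_species(tax, "31"), NA_character_)  # genus
  expect_identical(resolve_to_species(tax, "1"), NA_character_)   # root
  expect_error(resolve_to_species(tax, "999"), "unknown tax_id")
  # idempotent, never returns a non-species node
  out <- resolve_to_species(tax, tax$nodes$tax_id)
  ok <- !is.na(out)
  expect_identical(resolve_to_species(tax, out[ok]), out[ok])
  expect_true(all(tax$nodes$effective_rank[tax$row[out[ok]]] == "species"))
})

test_that("supplemental organisms attach to preferred or fallback parents", {
  tax <- make_tiny_tax()
  r <- insert_supplemental(tax, list(tax_id = "500", name = "Novus cargoi",
                                     rank = "species", category = "bacteria"),
                           preferred_parent = "21")
  expect_identical(r$parent_id, "21")
  r2 <- insert_supplemental(r$taxonomy,
                            list(tax_id = "501", name = "Novus hosti",
                                 rank = "species", category = "other_mammal"))
  expect_identical(r2$parent_id, "30")   # category fallback
  expect_identical(resolve_to_species(r2$taxonomy, "501"), "501")
  expect_error(insert_supplemental(r2$taxonomy,
                                   list(tax_id = "500", name = "dup",
                                        rank = "species",
                                        category = "bacteria"), "21"),
               "already present")
  expect_error(insert_supplemental(tax, list(tax_id = "502", name = "x y",
                                             rank = "species",
                                             category = "virus")),
               "no fallback")
})

test_that("taxdump round-trips through the tab-pipe dialect", {
  fx <- generate_fixture(fixture_spec(seed = 4, n_records = 20),
                         dir = tempfile("fx"))
  nodes <- read_taxdump(file.path(dirname(fx$files[1]), "nodes.dmp"),
                        file.path(dirname(fx$files[1]), "names.dmp"))
  expect_identical(nodes$tax_id, fx$nodes$tax_id)
  expect_identical(nodes$name, fx$nodes$name)
  expect_identical(nodes$parent_id, fx$nodes$parent_id)
})

test_that("malformed trees are rejected", {
  n <- data.frame(tax_id = c("1", "2"), parent_id = c("1", "9"),
                  rank_raw = c("no rank", "species"),
                  name = c("root", "Aa bb"), stringsAsFactors = FALSE)
  expect_error(load_taxonomy(n), "parent_id not in tree")
  n2 <- data.frame(tax_id = c("1", "2", "3"), parent_id = c("1", "3", "2"),
                   rank_raw = "no rank", name = c("root", "b", "c"),
                   stringsAsFactors = FALSE)
  expect_error(load_taxonomy(n2), "cycle")
})

test_that("name sets are attached and retrievable", {
  tax <- make_tiny_tax()
  ns <- name_set(tax, "12")
  expect_setequal(ns$alt, c("CSFV", "hog cholera virus",
                            "pestivirus type 2", "swine fever virus"))
  expect_identical(ns$exclude, "african swine fever")
  expect_identical(name_set(tax, "22")$alt, character(0))
})
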