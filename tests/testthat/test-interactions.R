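one_record <- function(seq_id, tax_id, host) {
  data.frame(seq_id = seq_id, tax_id = tax_id, host = host,
             country = NA_character_, year = 2000L, stringsAsFactors = FALSE)
}

test_that("a single record with a resolvable host yields one interaction", {
  tax <- make_tiny_tax()
  ints <- build_species_interactions(tax, one_record("9", "12", "sheep"))
  expect_identical(nrow(ints), 1L)
  expect_identical(ints$cargo_id, "12")
  expect_identical(ints$carrier_id, "32")
  expect_identical(ints$origin, "sequence_backed")
  expect_identical(ints$sequence_ids[[1]], "9")
  # unresolved host contributes nothing
  none <- build_species_interactions(tax, one_record("9", "12", "martian"))
  expect_identical(nrow(none), 0L)
})

test_that("publication-only interactions require five shared papers", {
  tax <- make_tiny_tax()
  # corpus defines 12 as cargo and 32 (via sheep) as carrier, plus 22 cargo
  rec <- rbind(one_record("1", "12", "sheep"), one_record("2", "22", NA))
  pm4 <- list(`22` = 1:4, `32` = 1:4)
  pm6 <- list(`22` = 1:6, `32` = 1:6)
  got4 <- build_species_interactions(tax, rec, pm4)
  expect_false(any(got4$origin == "publication_only"))
  got6 <- build_species_interactions(tax, rec, pm6)
  pub <- got6[got6$origin == "publication_only", ]
  expect_identical(nrow(pub), 1L)
  expect_identical(pub$cargo_id, "22")
  expect_identical(pub$carrier_id, "32")
  expect_identical(pub$pmids[[1]], 1:6)
  # shared papers below threshold still attach to sequence-backed pairs
  got <- build_species_interactions(tax, rec,
                                    list(`12` = 1:3, `32` = 2:4))
  sb <- got[got$origin == "sequence_backed", ]
  expect_identical(sb$pmids[[1]], 2:3)
})

test_that("sequence evidence is conserved across assembled interactions", {
  fx <- generate_fixture(fixture_spec(seed = 17, n_records = 1200))
  cl <- classify_records(fx$taxonomy, fx$records)
  ints <- build_species_interactions(fx$taxonomy, cl, fx$organism_pmids)
  n_eligible <- sum(cl$outcome == "interaction_eligible")
  expect_identical(sum(lengths(ints$sequence_ids)), n_eligible)
  # no publication-only interaction below the threshold, ever
  pub <- ints[ints$origin == "publication_only", ]
  expect_true(all(lengths(pub$pmids) >= 5L))
  expect_true(all(lengths(pub$sequence_ids) == 0L))
  expect_true(all(lengths(
    ints$sequence_ids[ints$origin == "sequence_backed"]) >= 1L))
})

test_that("species-location assembly adds country and region evidence", {
  tax <- make_tiny_tax()
  gaz <- demo_gaz()
  rec <- data.frame(seq_id = c("1", "2", "3"), tax_id = c("12", "13", "22"),
                    host = NA_character_,
                    country = c("Italy: Milan", "France", "USSR"),
                    year = 2000L, stringsAsFactors = FALSE)
  locs <- build_species_locations(tax, gaz, rec)
  key <- paste(locs$species_id, locs$country, locs$region)
  expect_setequal(key, c("12 Italy NA", "12 Italy Regione Lombardia",
                         "12 France NA"))
  # discarded location contributes nothing; strain rolled up to species
  pm <- list(`22` = 1:7)
  locs2 <- build_species_locations(tax, gaz, rec, species_pmids = pm,
                                   country_pmids = list(France = 2:9))
  pub <- locs2[locs2$origin == "publication_only", ]
  expect_identical(pub$species_id, "22")
  expect_identical(pub$country, "France")
  expect_identical(pub$pmids[[1]], 2:7)
})

test_that("the interaction CSV schema matches the published field list", {
  tax <- make_tiny_tax()
  ints <- build_species_interactions(tax, one_record("9", "13", "sheep"))
  df <- export_interactions_csv(tax, ints)
  expect_identical(names(df),
                   c("Cargo", "Cargo classification", "Carrier",
                     "Carrier classification", "Sequences count",
                     "Publication count", "Sequences", "Publications"))
  expect_identical(df$Cargo, "Classical swine fever virus")
  expect_identical(df$`Cargo classification`, "virus")
  expect_identical(df$Carrier, "Ovis aries")
  expect_identical(df$`Sequences count`, 1L)
  expect_identical(df$Publications, "")
  # domestic override applies to carriers, never to humans
  df2 <- export_interactions_csv(tax, ints, domestic = "32")
  expect_identical(df2$`Carrier classification`, "domestic")
  ints_h <- build_species_interactions(tax, one_record("9", "13",
                                                       "Homo sapiens"))
  df3 <- export_interactions_csv(tax, ints_h, domestic = c("32", "35"))
  expect_identical(df3$`Carrier classification`, "human")
  # empty set exports a header-only table
  expect_identical(nrow(export_interactions_csv(tax, ints[0, ])), 0L)
})

test_that("evidence lists cap at 100 identifiers but counts do not", {
  tax <- make_tiny_tax()
  rec <- do.call(rbind, lapply(1:250, function(i)
    one_record(as.character(1000 + i), "12", "sheep")))
  ints <- build_species_interactions(tax, rec)
  df <- export_interactions_csv(tax, ints)
  expect_identical(df$`Sequences count`, 250L)
  listed <- strsplit(df$Sequences, ";")[[1]]
  expect_length(listed, 100L)
  expect_identical(listed, as.character(1001:1100))  # ascending numeric
})

test_that("export round-trips through CSV for lists within the cap", {
  tax <- make_tiny_tax()
  rec <- rbind(one_record("12", "13", "sheep"),
               one_record("3", "13", "sheep"),
               one_record("7", "22", "cattle"))
  ints <- build_species_interactions(tax, rec,
                                     list(`12` = 1:8, `32` = 1:8))
  tf <- tempfile(fileext = ".csv")
  export_interactions_csv(tax, ints, file = tf)
  back <- read.csv(tf, check.names = FALSE, stringsAsFactors = FALSE)
  direct <- export_interactions_csv(tax, ints)
  expect_identical(back$Sequences, direct$Sequences)
  expect_identical(back$`Sequences count`, direct$`Sequences count`)
  expect_identical(back$Publications, direct$Publications)
  expect_identical(back$Cargo, direct$Cargo)
  expect_identical(sort(strsplit(back$Sequences[back$Cargo ==
    "Classical swine fever virus"], ";")[[1]]), c("12", "3"))
})

test_that("the category cross-tab counts unique pairs and conserves totals", {
  tax <- make_tiny_tax()
  rec <- rbind(one_record("1", "13", "sheep"),
               one_record("2", "12", "sheep"),    # same pair as record 1
               one_record("3", "22", "sheep"),
               one_record("4", "22", "Homo sapiens"))
  ints <- build_species_interactions(tax, rec)
  ct <- crosstab_by_category(tax, ints)
  expect_identical(sum(ct), 3L)
  expect_identical(ct["other mammals", "virus"], 1L)
  expect_identical(ct["other mammals", "bacteria"], 1L)
  expect_identical(ct["human", "bacteria"], 1L)
  ct2 <- crosstab_by_category(tax, ints, domestic = "32")
  expect_identical(ct2["domestic", "virus"], 1L)
  expect_identical(sum(ct2), 3L)
})

test_that("location export matches the published field list", {
  tax <- make_tiny_tax()
  gaz <- demo_gaz()
  rec <- data.frame(seq_id = "1", tax_id = "12", host = NA_character_,
                    country = "Italy: Milan", year = 2000L,
                    stringsAsFactors = FALSE)
  locs <- build_species_locations(tax, gaz, rec)
  df <- export_locations_csv(tax, locs)
  expect_identical(names(df),
                   c("Species", "Species classification", "Country",
                     "Region", "Sequences count", "Publication count",
                     "Sequences", "Publications"))
  expect_setequal(df$Region, c("", "Regione Lombardia"))
})
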