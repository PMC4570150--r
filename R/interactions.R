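new_interactions <- function() {
  data.frame(cargo_id = character(), carrier_id = character(),
             origin = character(),
             sequence_ids = I(list()), pmids = I(list()),
             stringsAsFactors = FALSE)
}

sort_ids <- function(x) {
  x <- unique(as.character(x))
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) x[order(num)] else sort(x)
}

#' Assemble species-species (cargo-carrier) interactions
#'
#' Two-step evidence extraction.  Step 1, sequence evidence: every record
#' with a resolved cargo species and a resolved carrier species contributes
#' its sequence identifier to the (cargo, carrier) pair.  Step 2,
#' publication evidence: for every cargo and carrier identified in step 1
#' that both have PMID sets, the sets are intersected; shared citations are
#' attached to existing pairs, and pairs with no sequence evidence but at
#' least `threshold` (default five) shared papers become publication-only
#' interactions.
#'
#' @param tax a `cargomine_taxonomy`.
#' @param records a corpus from [read_sequence_meta()], or the output of
#'   [classify_records()].
#' @param organism_pmids named list (tax_id -> integer PMIDs), e.g. from
#'   [read_pmid_sets()].
#' @param threshold minimum shared papers for a publication-only
#'   interaction.
#' @return data.frame(cargo_id, carrier_id, origin, sequence_ids, pmids)
#'   with list columns of evidence identifiers.
#' @export
build_species_interactions <- function(tax, records,
                                       organism_pmids = list(),
                                       threshold = 5L) {
  if (is.null(records$outcome)) records <- classify_records(tax, records)
  el <- records[records$outcome == "interaction_eligible", , drop = FALSE]
  key <- paste(el$cargo_species, el$carrier_species, sep = "\r")
  seq_by_pair <- lapply(split(el$seq_id, key), sort_ids)
  pairs <- do.call(rbind, strsplit(names(seq_by_pair), "\r", fixed = TRUE))
  out <- if (length(seq_by_pair)) data.frame(
    cargo_id = pairs[, 1L], carrier_id = pairs[, 2L],
    origin = "sequence_backed",
    sequence_ids = I(unname(seq_by_pair)),
    pmids = I(rep(list(integer()), length(seq_by_pair))),
    stringsAsFactors = FALSE) else new_interactions()

  cargoes <- unique(stats::na.omit(records$cargo_species))
  carriers <- unique(stats::na.omit(records$carrier_species))
  cargoes <- intersect(cargoes, names(organism_pmids))
  carriers <- intersect(carriers, names(organism_pmids))
  have <- paste(out$cargo_id, out$carrier_id, sep = "\r")
  for (g in cargoes) {
    for (a in carriers) {
      cc <- co_citation(organism_pmids[[g]], organism_pmids[[a]],
                        threshold = threshold)
      if (!length(cc$pmids)) next
      k <- paste(g, a, sep = "\r")
      at <- match(k, have)
      if (!is.na(at)) {
        out$pmids[[at]] <- cc$pmids
      } else if (cc$passes && g != a) {
        out <- rbind(out, data.frame(
          cargo_id = g, carrier_id = a, origin = "publication_only",
          sequence_ids = I(list(character())), pmids = I(list(cc$pmids)),
          stringsAsFactors = FALSE))
        have <- c(have, k)
      }
    }
  }
  row.names(out) <- NULL
  out
}

#' Assemble species-location interactions
#'
#' Sequence route: every record with a resolved species and a
#' non-discarded location assignment adds evidence at country level and,
#' when a region was identified, at region level.  Publication route:
#' the species PMID set is intersected with each country set (and with
#' the region-within-country set PMID_RC); intersections of at least
#' `threshold` papers add or support (species, country) and
#' (species, country, region) entries.
#'
#' @param tax a `cargomine_taxonomy`.
#' @param gaz a `cargomine_gazetteer`.
#' @param records corpus data.frame.
#' @param species_pmids named list, tax_id -> PMIDs.
#' @param country_pmids named list, canonical country -> PMIDs (PMID_C).
#' @param region_pmids named list, `"country|region"` -> PMIDs (PMID_R).
#' @param threshold minimum shared papers on the publication route.
#' @param successors historical-country successor map, see
#'   [resolve_country()].
#' @return data.frame(species_id, country, region, origin, sequence_ids,
#'   pmids); `region` is `NA` for country-level entries.
#' @export
build_species_locations <- function(tax, gaz, records,
                                    species_pmids = list(),
                                    country_pmids = list(),
                                    region_pmids = list(),
                                    threshold = 5L, successors = list()) {
  if (is.null(records$cargo_species))
    records$cargo_species <- identify_cargo(tax, records)
  has_loc <- !is.na(records$country) & !is.na(records$cargo_species)
  sub <- records[has_loc, , drop = FALSE]
  uniq <- unique(sub$country)
  assign <- lapply(uniq, function(raw) geolocate(gaz, raw, successors))
  names(assign) <- uniq
  co <- vapply(assign, function(a) a$country, "")[sub$country]
  re <- vapply(assign, function(a) a$region, "")[sub$country]
  keep <- !is.na(co)
  sub <- sub[keep, , drop = FALSE]; co <- co[keep]; re <- re[keep]

  key <- c(paste(sub$cargo_species, co, "", sep = "\r"),
           paste(sub$cargo_species, co, re, sep = "\r")[!is.na(re)])
  sid <- c(sub$seq_id, sub$seq_id[!is.na(re)])
  seq_by_loc <- lapply(split(sid, key), sort_ids)
  # country-level keys have an empty third component that strsplit drops
  parts <- t(vapply(strsplit(names(seq_by_loc), "\r", fixed = TRUE),
                    function(p) { length(p) <- 3L
                                  ifelse(is.na(p), "", p) },
                    character(3L)))
  out <- if (length(seq_by_loc)) data.frame(
    species_id = parts[, 1L], country = parts[, 2L],
    region = ifelse(nzchar(parts[, 3L]), parts[, 3L], NA_character_),
    origin = "sequence_backed",
    sequence_ids = I(unname(seq_by_loc)),
    pmids = I(rep(list(integer()), length(seq_by_loc))),
    stringsAsFactors = FALSE) else
    data.frame(species_id = character(), country = character(),
               region = character(), origin = character(),
               sequence_ids = I(list()), pmids = I(list()),
               stringsAsFactors = FALSE)

  have <- paste(out$species_id, out$country,
                ifelse(is.na(out$region), "", out$region), sep = "\r")
  add <- function(out, sp, country, region, pm, have) {
    k <- paste(sp, country, ifelse(is.na(region), "", region), sep = "\r")
    at <- match(k, have)
    if (!is.na(at)) {
      out$pmids[[at]] <- pm$pmids
    } else if (pm$passes) {
      out <- rbind(out, data.frame(
        species_id = sp, country = country, region = region,
        origin = "publication_only",
        sequence_ids = I(list(character())), pmids = I(list(pm$pmids)),
        stringsAsFactors = FALSE))
    }
    out
  }
  rk <- strsplit(names(region_pmids) %||% character(), "|", fixed = TRUE)
  for (sp in intersect(unique(stats::na.omit(records$cargo_species)),
                       names(species_pmids))) {
    for (country in names(country_pmids)) {
      pm <- co_citation(species_pmids[[sp]], country_pmids[[country]],
                        threshold = threshold)
      if (length(pm$pmids) || pm$passes)
        out <- add(out, sp, country, NA_character_, pm,
                   paste(out$species_id, out$country,
                         ifelse(is.na(out$region), "", out$region),
                         sep = "\r"))
    }
    for (i in seq_along(region_pmids)) {
      country <- rk[[i]][1L]; region <- rk[[i]][2L]
      if (is.null(country_pmids[[country]])) next
      rc <- region_evidence(country_pmids[[country]], region_pmids[[i]])
      pm <- co_citation(species_pmids[[sp]], rc, threshold = threshold)
      if (length(pm$pmids) || pm$passes)
        out <- add(out, sp, country, region, pm,
                   paste(out$species_id, out$country,
                         ifelse(is.na(out$region), "", out$region),
                         sep = "\r"))
    }
  }
  row.names(out) <- NULL
  out
}

category_label <- function(cat) {
  map <- c(segmented_worm = "segmented worm", other_mammal = "other mammals",
           plant = "plants", other = "others")
  out <- unname(map[cat])
  ifelse(is.na(out), cat, out)
}

carrier_category <- function(tax, ids, domestic = character()) {
  cat <- tax_category(tax, ids)
  ifelse(cat == "human", "human",
         ifelse(ids %in% domestic, "domestic", cat))
}

format_evidence <- function(ids, cap = 100L) {
  vapply(ids, function(x) paste(utils::head(sort_ids(x), cap),
                                collapse = ";"), "")
}

#' Export species-species interactions in the published CSV schema
#'
#' Columns: Cargo, Cargo classification, Carrier, Carrier classification,
#' Sequences count, Publication count, Sequences, Publications.  Evidence
#' identifier lists are semicolon-separated and truncated to the first 100
#' identifiers in ascending numeric order; the counts always reflect the
#' untruncated totals.
#'
#' @param tax a `cargomine_taxonomy`.
#' @param interactions from [build_species_interactions()].
#' @param file optional path; when given the CSV is written there.
#' @param domestic character vector of carrier species tax_ids whose
#'   carrier classification is overridden to `"domestic"` (never applied
#'   to humans).
#' @return the exported data.frame, invisibly when `file` is given.
#' @export
export_interactions_csv <- function(tax, interactions, file = NULL,
                                    domestic = character()) {
  df <- data.frame(
    Cargo = tax_name(tax, interactions$cargo_id),
    `Cargo classification` = category_label(
      tax_category(tax, interactions$cargo_id)),
    Carrier = tax_name(tax, interactions$carrier_id),
    `Carrier classification` = category_label(
      carrier_category(tax, interactions$carrier_id, domestic)),
    `Sequences count` = lengths(interactions$sequence_ids),
    `Publication count` = lengths(interactions$pmids),
    Sequences = format_evidence(interactions$sequence_ids),
    Publications = format_evidence(interactions$pmids),
    check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    df <- df[0L, , drop = FALSE]
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE, fileEncoding = "UTF-8")
    return(invisible(df))
  }
  df
}

#' Export species-location interactions in the published CSV schema
#'
#' Columns: Species, Species classification, Country, Region, Sequences
#' count, Publication count, Sequences, Publications; identifier lists
#' capped at 100 as in [export_interactions_csv()].
#'
#' @inheritParams export_interactions_csv
#' @param locations from [build_species_locations()].
#' @return the exported data.frame, invisibly when `file` is given.
#' @export
export_locations_csv <- function(tax, locations, file = NULL) {
  df <- data.frame(
    Species = tax_name(tax, locations$species_id),
    `Species classification` = category_label(
      tax_category(tax, locations$species_id)),
    Country = locations$country,
    Region = ifelse(is.na(locations$region), "", locations$region),
    `Sequences count` = lengths(locations$sequence_ids),
    `Publication count` = lengths(locations$pmids),
    Sequences = format_evidence(locations$sequence_ids),
    Publications = format_evidence(locations$pmids),
    check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(file)) {
    utils::write.csv(df, file, row.names = FALSE, fileEncoding = "UTF-8")
    return(invisible(df))
  }
  df
}

#' Cross-tabulate interactions by carrier and cargo category
#'
#' Counts unique (cargo, carrier) pairs per cell of a carrier-category by
#' cargo-category table (the summary-table layout of the interaction
#' dataset: rows are carrier categories, columns cargo categories).
#'
#' @inheritParams export_interactions_csv
#' @return integer matrix, rows = carrier categories, columns = cargo
#'   categories present in the data.
#' @export
crosstab_by_category <- function(tax, interactions, domestic = character()) {
  if (!nrow(interactions))
    return(matrix(integer(), 0L, 0L))
  key <- !duplicated(paste(interactions$cargo_id, interactions$carrier_id,
                           sep = "\r"))
  uni <- interactions[key, , drop = FALSE]
  gcat <- category_label(tax_category(tax, uni$cargo_id))
  acat <- category_label(carrier_category(tax, uni$carrier_id, domestic))
  if (anyNA(gcat) || anyNA(acat)) {
    bad <- unique(c(uni$cargo_id[is.na(gcat)], uni$carrier_id[is.na(acat)]))
    stop("uncategorized species: ", paste(bad, collapse = ", "))
  }
  table(carrier = acat, cargo = gcat)
}
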