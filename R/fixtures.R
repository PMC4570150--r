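# index -> letters-only suffix, so generated names never trip the
# digit-based rank rule
num2alpha <- function(i) {
  vapply(i, function(k) {
    out <- ""
    k <- k - 1L
    repeat {
      out <- paste0(letters[k %% 26L + 1L], out)
      k <- k %/% 26L - 1L
      if (k < 0L) break
    }
    out
  }, "")
}

#' Demonstration gazetteer
#'
#' The small gazetteer shipped with the package (also embedded in every
#' synthetic fixture): the United States, Italy, China and the United
#' Kingdom with the places needed for the worked examples ("USA: MA",
#' "Italy: Milan", "China: Shantou", "United Kingdom: Yorkshire, Old
#' Peak"), alternative country names, a historical country with a
#' successor, water bodies, a MeSH-unlisted country and a no-region
#' microstate.
#'
#' @return data.frame in the [read_gazetteer()] column layout.
#' @export
demo_gazetteer <- function() {
  e <- function(name, tier, country = "", region = "", mesh = 0, noreg = 0)
    data.frame(name = name, tier = tier, country = country, region = region,
               mesh_listed = as.character(mesh), no_region = as.character(noreg),
               stringsAsFactors = FALSE)
  rbind(
    e("United States", "country", "United States", mesh = 1),
    e("USA", "country", "United States", mesh = 1),
    e("U.S.A.", "country", "United States", mesh = 1),
    e("Italy", "country", "Italy", mesh = 1),
    e("China", "country", "China", mesh = 1),
    e("United Kingdom", "country", "United Kingdom", mesh = 1),
    e("UK", "country", "United Kingdom", mesh = 1),
    e("France", "country", "France", mesh = 1),
    e("Serbia", "country", "Serbia", mesh = 1),
    e("Andorra", "country", "Andorra", mesh = 0, noreg = 1),
    e("Massachusetts", "admin1", "United States", "Massachusetts"),
    e("MA", "state_code", "United States", "Massachusetts"),
    e("New York", "admin1", "United States", "New York"),
    e("NY", "state_code", "United States", "New York"),
    e("Regione Lombardia", "admin1", "Italy", "Regione Lombardia"),
    e("Lombardy", "admin1", "Italy", "Regione Lombardia"),
    e("Milan", "city", "Italy", "Regione Lombardia"),
    e("Quangdong sheng", "admin1", "China", "Quangdong sheng"),
    e("Shantou", "city", "China", "Quangdong sheng"),
    e("England", "admin1", "United Kingdom", "England"),
    e("Scotland", "admin1", "United Kingdom", "Scotland"),
    e("Wales", "admin1", "United Kingdom", "Wales"),
    e("Yorkshire", "admin2", "United Kingdom", "England"),
    e("Glasgow", "city", "United Kingdom", "Scotland"),
    e("Edinburgh", "capital", "United Kingdom", "Scotland"),
    e("Grad Beograd", "admin1", "Serbia", "Grad Beograd"),
    e("Belgrade", "capital", "Serbia", "Grad Beograd"),
    e("Yugoslavia", "historical_country"),
    e("USSR", "historical_country"),
    e("Pacific Ocean", "water_body"),
    e("Atlantic Ocean", "water_body"))
}

#' Historical-country successor map for the demonstration gazetteer
#' @return named list usable as the `successors` argument of [geolocate()].
#' @export
demo_successors <- function() {
  list(Yugoslavia = "Serbia", USSR = character())
}

#' Specification for a synthetic fixture corpus
#'
#' The defaults are the corpus conditions the pipeline is designed for:
#' 7.1% of records carry a host qualifier, 17.5% carry a country
#' qualifier, and 59.9% of country qualifiers carry additional sub-country
#' location text.  Noise rates default to zero (a clean corpus); the noise
#' classes (misspelled host, historical country, water body) exist to
#' exercise the discard log.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_species species count (split between cargo and carrier pools).
#' @param n_subspecies,n_norank counts of below-species organisms.
#' @param n_records corpus size.
#' @param p_host_tag probability a record carries a host qualifier.
#' @param p_country_tag probability a record carries a country qualifier.
#' @param p_region_given_country probability a country qualifier carries a
#'   sub-country location part.
#' @param p_above_species probability the sequenced organism is above
#'   species level (discarded by the pipeline by design).
#' @param p_alt_host probability a host qualifier uses a common name
#'   instead of the Latin name.
#' @param n_pub_only planted publication-only cargo-carrier pairs with at
#'   least 5 shared citations.
#' @param n_pub_weak planted pairs with 1-4 shared citations (below
#'   threshold, must never surface).
#' @param n_loc_pub planted publication-only species-country pairs;
#'   half additionally get a region-level citation overlap.
#' @param p_host_noise probability a host qualifier is garbled beyond
#'   recognition.
#' @param p_country_historical,p_country_water probabilities a country
#'   qualifier is an unresolvable historical country / a bare water body.
#' @return list of class `cargomine_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_species = 120L, n_subspecies = 24L,
                         n_norank = 36L, n_records = 2000L,
                         p_host_tag = 0.071, p_country_tag = 0.175,
                         p_region_given_country = 0.599,
                         p_above_species = 0.02, p_alt_host = 0.4,
                         n_pub_only = 6L, n_pub_weak = 6L, n_loc_pub = 6L,
                         p_host_noise = 0, p_country_historical = 0,
                         p_country_water = 0) {
  spec <- as.list(environment())
  probs <- unlist(spec[grep("^p_", names(spec))])
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  counts <- unlist(spec[grep("^n_", names(spec))])
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (spec$n_species < 20L) stop("n_species must be at least 20")
  structure(spec, class = "cargomine_fixture_spec")
}

#' Generate a synthetic fixture bundle
#'
#' Builds a coherent taxonomy (with deliberate rank misannotations for the
#' reclassifier to fix, virus names exempt, supplemental organisms forced
#' in), a gazetteer embedding the demonstration entries plus synthetic
#' countries, a sequence-metadata corpus, organism/country/region PMID
#' sets with planted co-citation overlaps, and the ground-truth interaction
#' and location tables implied by construction.  The same seed yields an
#' identical bundle.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory; when given, all input files and truth
#'   tables are written there as plain text.
#' @return list with the taxonomy and gazetteer objects, the corpus
#'   (`records`), per-record truth (`record_truth`), the three PMID-set
#'   lists, `truth_interactions`, `truth_locations`, `domestic_ids`, and
#'   (when `dir` is given) a `files` vector of written paths.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cargomine_fixture_spec"))
  set.seed(spec$seed)

  ## ---- taxonomy -------------------------------------------------------
  next_id <- local({ n <- 0L; function() { n <<- n + 1L; as.character(n) } })
  root <- next_id()
  nodes <- data.frame(tax_id = root, parent_id = root, rank_raw = "no rank",
                      name = "root", stringsAsFactors = FALSE)
  add_node <- function(name, rank, parent) {
    id <- next_id()
    nodes <<- rbind(nodes, data.frame(tax_id = id, parent_id = parent,
                                      rank_raw = rank, name = name,
                                      stringsAsFactors = FALSE))
    id
  }
  cargo_cats <- c("virus", "bacteria", "fungi", "protozoa", "helminth")
  carrier_cats <- c("other_mammal", "aves", "fish", "rodent", "primate")
  groups <- c(cargo_cats, carrier_cats)
  group_id <- vapply(groups, function(g)
    add_node(paste0("Clade", g), "superkingdom", root), "")
  anchors <- data.frame(tax_id = unname(group_id), category = groups,
                        stringsAsFactors = FALSE)

  n_cargo <- ceiling(spec$n_species * 0.6)
  n_carrier <- spec$n_species - n_cargo - 1L   # one slot for Homo sapiens
  make_species <- function(i, cat) {
    genus <- paste0("Genus", num2alpha(i))
    gid <- add_node(genus, "genus", group_id[[cat]])
    if (cat == "virus" && i %% 3L == 0L) {
      # multi-word / digit-bearing virus names: exempt from reclassification
      nm <- if (i %% 2L == 0L)
        paste(genus, "swine fever virus") else paste(genus, "virus", i)
    } else {
      nm <- paste(genus, paste0("epi", num2alpha(i)))
    }
    # a third of the dump rows carry the wrong rank on purpose
    rank <- if (i %% 3L == 0L && cat != "virus") "no rank" else "species"
    add_node(nm, rank, gid)
  }
  cargo_sp <- character(n_cargo)
  cargo_cat <- character(n_cargo)
  for (i in seq_len(n_cargo)) {
    cargo_cat[i] <- cargo_cats[(i - 1L) %% length(cargo_cats) + 1L]
    cargo_sp[i] <- make_species(i, cargo_cat[i])
  }
  carrier_sp <- character(n_carrier)
  carrier_cat <- character(n_carrier)
  for (i in seq_len(n_carrier)) {
    carrier_cat[i] <- carrier_cats[(i - 1L) %% length(carrier_cats) + 1L]
    carrier_sp[i] <- make_species(n_cargo + i, carrier_cat[i])
  }
  homo_genus <- add_node("Homo", "genus", group_id[["primate"]])
  homo <- add_node("Homo sapiens", "species", homo_genus)
  anchors <- rbind(anchors, data.frame(tax_id = homo, category = "human",
                                       stringsAsFactors = FALSE))
  carrier_sp <- c(carrier_sp, homo)
  carrier_cat <- c(carrier_cat, "human")

  # below-species organisms roll up to known parents
  parent_of <- character()
  sub_ids <- character(spec$n_subspecies)
  for (i in seq_len(spec$n_subspecies)) {
    p <- cargo_sp[(i - 1L) %% n_cargo + 1L]
    nm <- paste(nodes$name[nodes$tax_id == p], paste0("sub", num2alpha(i)))
    sub_ids[i] <- add_node(nm, "subspecies", p)
    parent_of[sub_ids[i]] <- p
  }
  nr_ids <- character(spec$n_norank)
  for (i in seq_len(spec$n_norank)) {
    p <- cargo_sp[(i * 7L - 1L) %% n_cargo + 1L]
    nm <- paste(nodes$name[nodes$tax_id == p], "strain", i)
    nr_ids[i] <- add_node(nm, "no rank", p)
    parent_of[nr_ids[i]] <- p
  }

  # name sets: every carrier gets a unique common name; some cargoes get
  # inclusion/exclusion terms for query building
  alt_of <- paste0("common ", num2alpha(seq_along(carrier_sp)))
  alt_of[length(alt_of)] <- "human"
  names(alt_of) <- carrier_sp
  name_sets <- data.frame(tax_id = carrier_sp, kind = "alt",
                          term = unname(alt_of), stringsAsFactors = FALSE)
  name_sets <- rbind(name_sets, data.frame(
    tax_id = cargo_sp[1:3], kind = "exclude",
    term = paste("not", num2alpha(1:3)), stringsAsFactors = FALSE))

  # supplemental organisms forced into the tree
  supplement <- data.frame(
    tax_id = c("900001", "900002"),
    name = c("Suppl cargoa", "Suppl carriera"),
    rank = c("species", "species"),
    parent_id = c(group_id[["bacteria"]], ""),
    category = c("bacteria", "other_mammal"),
    stringsAsFactors = FALSE)
  fallback <- c(other_mammal = unname(group_id[["other_mammal"]]),
                bacteria = unname(group_id[["bacteria"]]))

  tax <- load_taxonomy(nodes, category_anchors = anchors,
                       supplement = supplement, name_sets = name_sets,
                       fallback_parents = fallback)

  ## ---- gazetteer ------------------------------------------------------
  n_countries <- 6L
  gz <- demo_gazetteer()
  syn_countries <- paste0("Landia ", num2alpha(seq_len(n_countries)))
  for (i in seq_len(n_countries)) {
    co <- syn_countries[i]
    gz <- rbind(gz, data.frame(
      name = c(co, paste("Republic of", co)), tier = "country",
      country = co, region = "", mesh_listed = as.character(i %% 2L),
      no_region = "0", stringsAsFactors = FALSE))
    for (j in 1:3) {
      rg <- paste0("Province ", num2alpha(i), toupper(num2alpha(j)))
      gz <- rbind(gz, data.frame(
        name = c(rg, paste0("Town ", num2alpha(i), toupper(num2alpha(j)))),
        tier = c("admin1", "town"), country = co, region = rg,
        mesh_listed = "0", no_region = "0", stringsAsFactors = FALSE))
    }
  }
  gaz_file <- tempfile(fileext = ".tsv")
  utils::write.table(gz, gaz_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  gaz <- read_gazetteer(gaz_file)
  unlink(gaz_file)
  regions_of <- function(co)
    unique(gz$region[gz$country == co & gz$tier == "admin1"])

  ## ---- corpus ---------------------------------------------------------
  n <- spec$n_records
  cargo_pool <- c(cargo_sp, sub_ids, nr_ids, "900001")
  species_of <- structure(c(cargo_sp, unname(parent_of[c(sub_ids, nr_ids)]),
                            "900001"),
                          names = cargo_pool)
  above_pool <- unname(group_id)
  carrier_pool <- carrier_sp

  taxon <- character(n); host <- rep(NA_character_, n)
  country_raw <- rep(NA_character_, n)
  t_cargo <- rep(NA_character_, n); t_carrier <- rep(NA_character_, n)
  t_country <- rep(NA_character_, n); t_region <- rep(NA_character_, n)
  host_kind <- rep(NA_character_, n); loc_kind <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (stats::runif(1) < spec$p_above_species) {
      taxon[i] <- sample(above_pool, 1L)
    } else {
      taxon[i] <- sample(cargo_pool, 1L)
      t_cargo[i] <- species_of[[taxon[i]]]
    }
    if (stats::runif(1) < spec$p_host_tag) {
      ca <- sample(carrier_pool, 1L)
      if (stats::runif(1) < spec$p_host_noise) {
        host[i] <- paste0("zzq ", sample(letters, 1L), " mystery")
        host_kind[i] <- "garbled"
      } else if (stats::runif(1) < spec$p_alt_host) {
        host[i] <- alt_of[[ca]]
        host_kind[i] <- "alt"
        if (!is.na(t_cargo[i])) t_carrier[i] <- ca
      } else {
        host[i] <- tax_name(tax, ca)
        host_kind[i] <- "latin"
        if (!is.na(t_cargo[i])) t_carrier[i] <- ca
      }
    }
    if (stats::runif(1) < spec$p_country_tag) {
      u <- stats::runif(1)
      if (u < spec$p_country_historical) {
        country_raw[i] <- "Yugoslavia"
        loc_kind[i] <- "historical"
      } else if (u < spec$p_country_historical + spec$p_country_water) {
        country_raw[i] <- "Pacific Ocean"
        loc_kind[i] <- "water_body"
      } else {
        co <- sample(syn_countries, 1L)
        if (stats::runif(1) < spec$p_region_given_country) {
          rg <- sample(regions_of(co), 1L)
          place <- if (stats::runif(1) < 0.5) rg else sub("^Province", "Town", rg)
          country_raw[i] <- paste0(co, ": ", place)
          if (!is.na(t_cargo[i])) { t_country[i] <- co; t_region[i] <- rg }
          loc_kind[i] <- "country_region"
        } else {
          country_raw[i] <- co
          if (!is.na(t_cargo[i])) t_country[i] <- co
          loc_kind[i] <- "country_only"
        }
      }
    }
  }
  records <- data.frame(
    seq_id = as.character(100000L + seq_len(n)), tax_id = taxon,
    host = host, country = country_raw,
    year = sample(1993:2012, n, replace = TRUE),
    stringsAsFactors = FALSE)
  record_truth <- data.frame(
    seq_id = records$seq_id, cargo_species = t_cargo,
    carrier_species = t_carrier, host_kind = host_kind,
    country = t_country, region = t_region, loc_kind = loc_kind,
    stringsAsFactors = FALSE)

  ## ---- PMID sets with planted overlaps --------------------------------
  next_pmid <- local({ n <- 1000L
    function(k) { out <- n + seq_len(k); n <<- n + k; out } })
  org_pmids <- list()
  grant <- function(lst, id, pmids) {
    lst[[id]] <- sort(unique(c(lst[[id]], pmids))); lst }
  seen_cargo <- unique(stats::na.omit(t_cargo))
  seen_carrier <- unique(stats::na.omit(t_carrier))
  for (id in c(seen_cargo, seen_carrier))
    org_pmids <- grant(org_pmids, id, next_pmid(3L))

  seq_pairs <- unique(stats::na.omit(
    paste(t_cargo, t_carrier, sep = "\r")[!is.na(t_cargo) & !is.na(t_carrier)]))
  all_pairs <- as.vector(outer(seen_cargo, seen_carrier, paste, sep = "\r"))
  free_pairs <- setdiff(all_pairs, seq_pairs)
  free_pairs <- free_pairs[!vapply(strsplit(free_pairs, "\r"),
                                   function(p) p[1L] == p[2L], TRUE)]
  n_strong <- min(spec$n_pub_only, length(free_pairs))
  strong <- if (n_strong) sample(free_pairs, n_strong) else character()
  rest <- setdiff(free_pairs, strong)
  n_weak <- min(spec$n_pub_weak, length(rest))
  weak <- if (n_weak) sample(rest, n_weak) else character()
  plant_pair <- function(key, k) {
    p <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    block <- next_pmid(k)
    org_pmids <<- grant(org_pmids, p[1L], block)
    org_pmids <<- grant(org_pmids, p[2L], block)
  }
  for (key in strong) plant_pair(key, sample(5:9, 1L))
  for (key in weak) plant_pair(key, sample(1:4, 1L))
  # some sequence-backed pairs also get citation support (no threshold)
  backed <- utils::head(seq_pairs, max(1L, length(seq_pairs) %/% 5L))
  for (key in backed) plant_pair(key, sample(1:8, 1L))

  truth_interactions <- rbind(
    data.frame(do.call(rbind, c(list(matrix(character(), 0L, 2L)),
                                strsplit(seq_pairs, "\r", fixed = TRUE))),
               origin = rep("sequence_backed", length(seq_pairs)),
               stringsAsFactors = FALSE),
    data.frame(do.call(rbind, c(list(matrix(character(), 0L, 2L)),
                                strsplit(strong, "\r", fixed = TRUE))),
               origin = rep("publication_only", length(strong)),
               stringsAsFactors = FALSE))
  names(truth_interactions)[1:2] <- c("cargo_id", "carrier_id")

  ## ---- location PMID sets ---------------------------------------------
  country_pmids <- list(); region_pmids <- list()
  for (co in syn_countries) {
    country_pmids <- grant(country_pmids, co, next_pmid(3L))
    for (rg in regions_of(co)) {
      key <- paste(co, rg, sep = "|")
      shared <- next_pmid(2L)   # region papers also about the country
      region_pmids <- grant(region_pmids, key, c(shared, next_pmid(2L)))
      country_pmids <- grant(country_pmids, co, shared)
    }
  }
  seen_species <- unique(stats::na.omit(t_cargo))
  seq_locs <- unique(paste(t_cargo, t_country, sep = "\r")[
    !is.na(t_cargo) & !is.na(t_country)])
  free_locs <- setdiff(as.vector(outer(seen_species, syn_countries,
                                       paste, sep = "\r")), seq_locs)
  n_loc <- min(spec$n_loc_pub, length(free_locs))
  loc_pub <- if (n_loc) sample(free_locs, n_loc) else character()
  loc_pub_rows <- list()
  for (k in seq_along(loc_pub)) {
    p <- strsplit(loc_pub[k], "\r", fixed = TRUE)[[1L]]
    sp <- p[1L]; co <- p[2L]
    block <- next_pmid(sample(5:8, 1L))
    org_pmids <- grant(org_pmids, sp, block)
    country_pmids <- grant(country_pmids, co, block)
    loc_pub_rows[[length(loc_pub_rows) + 1L]] <- data.frame(
      species_id = sp, country = co, region = NA_character_,
      origin = "publication_only", stringsAsFactors = FALSE)
    if (k %% 2L == 0L) {   # half also get region-level support
      rg <- regions_of(co)[1L]
      region_pmids <- grant(region_pmids, paste(co, rg, sep = "|"), block)
      loc_pub_rows[[length(loc_pub_rows) + 1L]] <- data.frame(
        species_id = sp, country = co, region = rg,
        origin = "publication_only", stringsAsFactors = FALSE)
    }
  }

  tl <- record_truth[!is.na(record_truth$country), , drop = FALSE]
  truth_locations <- unique(rbind(
    data.frame(species_id = tl$cargo_species, country = tl$country,
               region = NA_character_, origin = "sequence_backed",
               stringsAsFactors = FALSE),
    {
      tr <- tl[!is.na(tl$region), , drop = FALSE]
      data.frame(species_id = tr$cargo_species, country = tr$country,
                 region = tr$region, origin = "sequence_backed",
                 stringsAsFactors = FALSE)
    }))
  truth_locations <- rbind(truth_locations,
                           do.call(rbind, c(list(truth_locations[0, ]),
                                            loc_pub_rows)))
  row.names(truth_locations) <- NULL

  domestic_ids <- carrier_sp[carrier_cat == "other_mammal"][1:3]

  bundle <- list(
    spec = spec, taxonomy = tax, gazetteer = gaz, gazetteer_table = gz,
    nodes = nodes, anchors = anchors, supplement = supplement,
    name_sets = name_sets, fallback_parents = fallback,
    records = records, record_truth = record_truth,
    organism_pmids = org_pmids, country_pmids = country_pmids,
    region_pmids = region_pmids,
    truth_interactions = truth_interactions,
    truth_locations = truth_locations,
    domestic_ids = domestic_ids,
    carrier_species = carrier_sp, cargo_species = cargo_sp,
    human_id = homo)
  if (!is.null(dir)) bundle$files <- write_fixture(bundle, dir)
  bundle
}

pmid_table <- function(lst) {
  data.frame(subject_id = rep(names(lst), lengths(lst)),
             pmid = unlist(lst, use.names = FALSE),
             stringsAsFactors = FALSE)
}

write_fixture <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  tsv <- function(df, f) {
    utils::write.table(df, p(f), sep = "\t", row.names = FALSE,
                       quote = FALSE, na = "")
    p(f)
  }
  nd <- bundle$nodes
  writeLines(paste0(nd$tax_id, "\t|\t", nd$parent_id, "\t|\t", nd$rank_raw,
                    "\t|"), p("nodes.dmp"))
  writeLines(paste0(nd$tax_id, "\t|\t", nd$name, "\t|\t\t|\tscientific name\t|"),
             p("names.dmp"))
  files <- c(p("nodes.dmp"), p("names.dmp"),
             tsv(bundle$anchors, "category_anchors.tsv"),
             tsv(data.frame(category = names(bundle$fallback_parents),
                            tax_id = unname(bundle$fallback_parents),
                            stringsAsFactors = FALSE),
                 "fallback_parents.tsv"),
             tsv(bundle$supplement, "supplement.tsv"),
             tsv(bundle$name_sets, "name_sets.tsv"),
             tsv(bundle$gazetteer_table, "gazetteer.tsv"),
             tsv(bundle$records, "sequences.tsv"),
             tsv(pmid_table(bundle$organism_pmids), "pmids_organisms.tsv"),
             tsv(pmid_table(bundle$country_pmids), "pmids_countries.tsv"),
             tsv(pmid_table(bundle$region_pmids), "pmids_regions.tsv"),
             tsv(bundle$truth_interactions, "truth_interactions.tsv"),
             tsv(bundle$truth_locations, "truth_locations.tsv"))
  files
}

#' Write sequence records as INSDSeq XML
#'
#' Serializes a corpus data.frame into the INSDSeq XML subset read by
#' [read_sequence_meta()]; used to check the two readers agree.
#'
#' @param records data.frame(seq_id, tax_id, host, country, year).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_sequence_xml <- function(records, file) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  qual <- function(name, value)
    sprintf("      <INSDQualifier><INSDQualifier_name>%s</INSDQualifier_name><INSDQualifier_value>%s</INSDQualifier_value></INSDQualifier>",
            name, esc(value))
  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", "<INSDSet>")
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    quals <- qual("db_xref", paste0("taxon:", r$tax_id))
    if (!is.na(r$host)) quals <- c(quals, qual("host", r$host))
    if (!is.na(r$country)) quals <- c(quals, qual("country", r$country))
    out <- c(out,
      "  <INSDSeq>",
      sprintf("    <INSDSeq_primary-accession>%s</INSDSeq_primary-accession>",
              esc(r$seq_id)),
      if (!is.na(r$year))
        sprintf("    <INSDSeq_create-date>01-JAN-%d</INSDSeq_create-date>",
                r$year),
      "    <INSDSeq_feature-table><INSDFeature>",
      "      <INSDFeature_key>source</INSDFeature_key>",
      quals,
      "    </INSDFeature></INSDSeq_feature-table>",
      "  </INSDSeq>")
  }
  out <- c(out, "</INSDSet>")
  writeLines(out, file, useBytes = TRUE)
  invisible(file)
}
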