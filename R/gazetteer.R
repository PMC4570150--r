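TIERS <- c("country", "historical_country", "water_body", "state_code",
           "admin1", "capital", "admin2", "admin3", "city", "town", "village")

# Matching rank order for sub-country tiers, highest first.  State codes
# resolve as admin1 evidence.
TIER_RANK <- c(admin1 = 1L, state_code = 1L, capital = 2L, admin2 = 3L,
               admin3 = 4L, city = 5L, town = 6L, village = 7L)

#' Read a gazetteer table
#'
#' The gazetteer is the geographic dictionary behind two-level location
#' disambiguation: countries with their alternative names, historical
#' countries, water bodies, state codes, and tiered sub-country place names
#' each mapped to a (country, admin1 region) pair.
#'
#' Expected TSV columns: `name`, `tier` (one of country, historical_country,
#' water_body, state_code, admin1, capital, admin2, admin3, city, town,
#' village), `country` (canonical country; for `country`-tier rows whose
#' `name` is an alternative spelling this holds the canonical name; empty
#' only for water bodies and unresolvable historical countries), `region`
#' (canonical admin1 name; required below admin1), `mesh_listed` (0/1,
#' country rows), `no_region` (0/1, country rows: country has no usable
#' administrative divisions so region identification is skipped).
#'
#' @param file path to the TSV.
#' @return object of class `cargomine_gazetteer`.
#' @export
read_gazetteer <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("name", "tier", "country", "region")
  if (!all(need %in% names(df)))
    stop("gazetteer needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$mesh_listed)) df$mesh_listed <- "0"
  if (is.null(df$no_region)) df$no_region <- "0"
  bad <- !df$tier %in% TIERS
  if (any(bad)) stop("unknown gazetteer tier: ",
                     paste(unique(df$tier[bad]), collapse = ", "))
  sub <- !df$tier %in% c("country", "historical_country", "water_body")
  if (any(sub & !nzchar(df$country)))
    stop("sub-country gazetteer entries must carry a country")
  below1 <- !df$tier %in% c("country", "historical_country", "water_body",
                            "admin1", "state_code")
  if (any(below1 & !nzchar(df$region)))
    stop("entries below admin1 must carry a region")
  df$mesh_listed <- df$mesh_listed %in% c("1", "TRUE", "true", "yes")
  df$no_region <- df$no_region %in% c("1", "TRUE", "true", "yes")
  df$key <- norm_key(df$name)
  # admin1 rows may leave region empty; the region is the entry itself
  fix <- df$tier %in% c("admin1", "state_code") & !nzchar(df$region)
  df$region[fix & df$tier == "admin1"] <- df$name[fix & df$tier == "admin1"]
  df$order <- seq_len(nrow(df))
  structure(list(entries = df), class = "cargomine_gazetteer")
}

#' @export
print.cargomine_gazetteer <- function(x, ...) {
  cat("<cargomine gazetteer>\n")
  tt <- table(x$entries$tier)
  cat(" ", paste(sprintf("%s=%d", names(tt), as.integer(tt)),
                 collapse = " "), "\n")
  invisible(x)
}

#' Classify a token as a country, historical country or water body
#'
#' Normalized exact match of the token against country names (canonical and
#' alternative), historical countries and water bodies.
#'
#' @param gaz a `cargomine_gazetteer`.
#' @param token one string.
#' @return list with `match` (one of `"country"`, `"historical"`,
#'   `"water_body"`, `"none"`) and `country` (canonical name or `NA`;
#'   for historical/water-body matches the matched entry's name).
#' @export
lookup_country <- function(gaz, token) {
  stopifnot(length(token) == 1L, nzchar(token))
  e <- gaz$entries
  key <- norm_key(token)
  hit <- e[e$key == key & e$tier == "country", , drop = FALSE]
  if (nrow(hit))
    return(list(match = "country", country = hit$country[1L]))
  hit <- e[e$key == key & e$tier == "historical_country", , drop = FALSE]
  if (nrow(hit))
    return(list(match = "historical", country = hit$name[1L]))
  hit <- e[e$key == key & e$tier == "water_body", , drop = FALSE]
  if (nrow(hit))
    return(list(match = "water_body", country = hit$name[1L]))
  list(match = "none", country = NA_character_)
}

country_row <- function(gaz, country) {
  e <- gaz$entries
  e[e$tier == "country" & e$country == country, , drop = FALSE]
}

#' Match a place token within one country
#'
#' All gazetteer entries of sub-country tiers matching the normalized token
#' within the given country, sorted by tier rank (admin1 and state codes
#' first, then capitals, lower administrative levels, cities, towns,
#' villages; ties by table order).  State codes only match tokens that are
#' whole uppercase strings of 2-3 letters *before* normalization, so "MA"
#' matches Massachusetts while the "ma" inside "Palma" cannot.
#'
#' @param gaz a `cargomine_gazetteer`.
#' @param token one string.
#' @param country canonical country name.
#' @return data.frame(name, tier, region) ordered best match first
#'   (zero rows when nothing matches).
#' @export
lookup_place <- function(gaz, token, country) {
  stopifnot(length(token) == 1L)
  e <- gaz$entries
  key <- norm_key(token)
  cand <- e[e$country == country & !is.na(TIER_RANK[e$tier]) &
              e$key == key, , drop = FALSE]
  if (nrow(cand)) {
    code_ok <- grepl("^[A-Z]{2,3}$", trimws(token))
    if (!code_ok) cand <- cand[cand$tier != "state_code", , drop = FALSE]
  }
  if (!nrow(cand))
    return(data.frame(name = character(), tier = character(),
                      region = character(), stringsAsFactors = FALSE))
  cand <- cand[order(TIER_RANK[cand$tier], cand$order), , drop = FALSE]
  data.frame(name = cand$name, tier = cand$tier, region = cand$region,
             row.names = NULL, stringsAsFactors = FALSE)
}
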