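#' Split a raw country qualifier into country and location parts
#'
#' Country qualifiers follow the convention `"Country: Location"`.  The
#' string is split at the first colon; both parts are trimmed; with no
#' colon the whole string is the country part.
#'
#' @param raw one non-empty string.
#' @return list with `country_part` and `location_part` (`NA` if absent).
#' @examples
#' split_location("China: Shantou")
#' split_location("UK: Yorkshire, Old Peak")
#' @export
split_location <- function(raw) {
  stopifnot(length(raw) == 1L, nzchar(raw))
  pos <- regexpr(":", raw, fixed = TRUE)
  if (pos < 0L)
    return(list(country_part = trimws(raw), location_part = NA_character_))
  loc <- trimws(substring(raw, pos + 1L))
  list(country_part = trimws(substring(raw, 1L, pos - 1L)),
       location_part = if (nzchar(loc)) loc else NA_character_)
}

# Candidate substrings for place matching: comma/semicolon/colon-delimited
# chunks, then each chunk's whitespace tokens.  Order encodes the
# tie-break preference: leftmost chunk first, whole chunk before its
# tokens.
place_candidates <- function(location_part) {
  chunks <- trimws(strsplit(location_part, "[,;:]")[[1L]])
  chunks <- chunks[nzchar(chunks)]
  out <- list()
  for (i in seq_along(chunks)) {
    toks <- strsplit(chunks[[i]], "\\s+")[[1L]]
    cand <- c(chunks[[i]], if (length(toks) > 1L) toks)
    out[[i]] <- data.frame(token = cand, chunk = i,
                           whole = c(TRUE, rep(FALSE, length(cand) - 1L)),
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(token = character(), chunk = integer(),
                      whole = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Identify the country of a split location string
#'
#' The country part is matched against the gazetteer.  Historical
#' countries are discarded unless the location part identifies a
#' present-day country (by naming the country itself or a place within a
#' configured successor country).  Water bodies are discarded unless the
#' location part resolves a country and is not itself a water body.
#'
#' @param gaz a `cargomine_gazetteer`.
#' @param country_part country token.
#' @param location_part remainder of the qualifier or `NA`.
#' @param successors named list: historical country name -> character
#'   vector of candidate present-day countries searched when rescuing a
#'   historical match.
#' @return list with `country` (canonical or `NA`), `status`
#'   (`"ok"` or `"discarded"`) and `reason` (one of `ok`,
#'   `historical_unresolvable`, `water_body`, `no_match`).
#' @export
resolve_country <- function(gaz, country_part, location_part = NA,
                            successors = list()) {
  hit <- lookup_country(gaz, country_part)
  if (hit$match == "country")
    return(list(country = hit$country, status = "ok", reason = "ok"))
  if (hit$match == "none")
    return(list(country = NA_character_, status = "discarded",
                reason = "no_match"))

  rescue <- function(reason, scope) {
    if (is.na(location_part) || !nzchar(location_part))
      return(list(country = NA_character_, status = "discarded",
                  reason = reason))
    cand <- place_candidates(location_part)
    for (i in seq_len(nrow(cand))) {
      sub <- lookup_country(gaz, cand$token[i])
      if (sub$match == "country")
        return(list(country = sub$country, status = "ok", reason = "ok"))
      if (sub$match == "water_body" && reason == "water_body")
        return(list(country = NA_character_, status = "discarded",
                    reason = "water_body"))
      for (co in scope) {
        if (nrow(lookup_place(gaz, cand$token[i], co)))
          return(list(country = co, status = "ok", reason = "ok"))
      }
    }
    list(country = NA_character_, status = "discarded", reason = reason)
  }

  if (hit$match == "historical") {
    scope <- successors[[hit$country]]
    if (is.null(scope)) scope <- character()
    return(rescue("historical_unresolvable", scope))
  }
  # water body: any country with gazetteer coverage may host the region
  all_countries <- unique(gaz$entries$country[gaz$entries$tier == "country"])
  rescue("water_body", all_countries)
}

#' Identify the admin1 region from the location part
#'
#' The location part is split into candidate substrings (comma-delimited
#' chunks and their whitespace tokens); every candidate is matched within
#' the country and the highest-tier match wins (admin1 and state codes
#' beat capitals beat lower administrative levels beat cities, towns and
#' villages).  At equal tier the leftmost candidate wins, and a
#' whole-chunk match beats a single-token match.
#'
#' @param gaz a `cargomine_gazetteer`.
#' @param country canonical country name (must not be a no-region country).
#' @param location_part non-empty location string.
#' @return canonical admin1 region name, or `NA` if nothing matches.
#' @export
resolve_region <- function(gaz, country, location_part) {
  stopifnot(length(location_part) == 1L)
  if (is.na(location_part) || !nzchar(location_part)) return(NA_character_)
  cand <- place_candidates(location_part)
  best <- NULL
  best_rank <- Inf
  for (i in seq_len(nrow(cand))) {
    m <- lookup_place(gaz, cand$token[i], country)
    if (!nrow(m)) next
    r <- TIER_RANK[m$tier[1L]]
    # candidates are pre-ordered by preference, so strict improvement only
    if (r < best_rank) {
      best_rank <- r
      best <- m$region[1L]
    }
  }
  if (is.null(best)) NA_character_ else best
}

#' Two-level disambiguation of a raw country qualifier
#'
#' Combines [split_location()], [resolve_country()] and [resolve_region()]
#' into one location assignment.  Countries flagged as having no usable
#' administrative divisions skip region identification.
#'
#' @param gaz a `cargomine_gazetteer`.
#' @param raw raw qualifier string, e.g. `"Italy: Milan"`.
#' @param successors see [resolve_country()].
#' @return list with `raw`, `country`, `region`, `status` (one of
#'   `country_and_region`, `country_only`, `discarded`) and `reason`.
#' @examples
#' # on the shipped demonstration gazetteer:
#' gaz <- read_gazetteer(system.file("extdata", "gazetteer.tsv",
#'                                   package = "cargomine"))
#' geolocate(gaz, "Italy: Milan")
#' @export
geolocate <- function(gaz, raw, successors = list()) {
  parts <- split_location(raw)
  co <- resolve_country(gaz, parts$country_part, parts$location_part,
                        successors)
  if (co$status == "discarded")
    return(list(raw = raw, country = NA_character_, region = NA_character_,
                status = "discarded", reason = co$reason))
  crow <- country_row(gaz, co$country)
  region <- NA_character_
  if (!any(crow$no_region) && !is.na(parts$location_part))
    region <- resolve_region(gaz, co$country, parts$location_part)
  status <- if (is.na(region)) "country_only" else "country_and_region"
  reason <- if (any(crow$no_region)) "no_region_country" else "ok"
  list(raw = raw, country = co$country, region = region,
       status = status, reason = reason)
}
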