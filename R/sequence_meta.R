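#' Read sequence metadata records
#'
#' Two equivalent dialects are accepted:
#'
#' * the INSDSeq XML subset: `INSDSeq` elements carrying a sequence
#'   identifier, a `db_xref` qualifier of the form `taxon:<id>`, and
#'   optional `host` and `country` source qualifiers;
#' * a TSV with columns `seq_id`, `tax_id`, `host`, `country`, `year`
#'   (empty cells mean the qualifier was absent).
#'
#' The two readers produce identical tables for equivalent content.
#' Malformed records are skipped and reported in the `skipped` attribute,
#' never raised.
#'
#' @param file path to the XML or TSV file.
#' @param format `"xml"`, `"tsv"` or `"auto"` (by file extension).
#' @return data.frame(seq_id, tax_id, host, country, year) with attribute
#'   `skipped`: data.frame(seq_id, reason) for unparseable records.
#' @export
read_sequence_meta <- function(file, format = c("auto", "xml", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.xml$", file, ignore.case = TRUE)) "xml" else "tsv"
  if (format == "tsv") read_sequence_tsv(file) else read_sequence_xml(file)
}

empty_records <- function() {
  data.frame(seq_id = character(), tax_id = character(),
             host = character(), country = character(),
             year = integer(), stringsAsFactors = FALSE)
}

read_sequence_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("seq_id", "tax_id", "host", "country", "year")
  if (!all(need %in% names(df)))
    stop("sequence TSV needs columns: ", paste(need, collapse = ", "))
  df <- df[need]
  for (col in c("host", "country"))
    df[[col]][!nzchar(trimws(df[[col]]))] <- NA_character_
  df$year <- suppressWarnings(as.integer(df$year))
  bad <- !nzchar(df$tax_id)
  skipped <- data.frame(seq_id = df$seq_id[bad],
                        reason = rep("missing tax_id", sum(bad)),
                        stringsAsFactors = FALSE)
  out <- df[!bad, , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

read_sequence_xml <- function(file) {
  doc <- xml2::read_xml(file)
  seqs <- xml2::xml_find_all(doc, ".//INSDSeq")
  rows <- vector("list", length(seqs))
  skipped <- list()
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    rec <- parse_insdseq(s)
    if (is.null(rec$tax_id)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        seq_id = if (is.null(rec$seq_id)) NA_character_ else rec$seq_id,
        reason = rec$reason, stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        seq_id = rec$seq_id, tax_id = rec$tax_id,
        host = rec$host, country = rec$country, year = rec$year,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(list(empty_records()), rows))
  row.names(out) <- NULL
  attr(out, "skipped") <- do.call(rbind, c(
    list(data.frame(seq_id = character(), reason = character(),
                    stringsAsFactors = FALSE)), skipped))
  out
}

qualifier_values <- function(s, name) {
  q <- xml2::xml_find_all(s, sprintf(
    ".//INSDQualifier[INSDQualifier_name='%s']/INSDQualifier_value", name))
  xml2::xml_text(q)
}

parse_insdseq <- function(s) {
  sid <- xml2::xml_text(xml2::xml_find_first(s, "./INSDSeq_primary-accession"))
  if (is.na(sid) || !nzchar(sid)) {
    gi <- xml2::xml_find_first(
      s, "./INSDSeq_other-seqids/INSDSeqid[starts-with(text(),'gi|')]")
    sid <- sub("^gi\\|", "", xml2::xml_text(gi))
  }
  if (is.na(sid) || !nzchar(sid))
    return(list(tax_id = NULL, seq_id = NULL, reason = "missing seq_id"))
  xrefs <- qualifier_values(s, "db_xref")
  taxon <- grep("^taxon:", xrefs, value = TRUE)
  if (!length(taxon))
    return(list(tax_id = NULL, seq_id = sid, reason = "missing taxon db_xref"))
  first_or_na <- function(x) if (length(x)) x[[1L]] else NA_character_
  date <- xml2::xml_text(xml2::xml_find_first(s, "./INSDSeq_create-date"))
  year <- NA_integer_
  if (!is.na(date)) {
    m <- regmatches(date, regexpr("[0-9]{4}", date))
    if (length(m)) year <- as.integer(m)
  }
  list(seq_id = sid, tax_id = sub("^taxon:", "", taxon[[1L]]),
       host = first_or_na(qualifier_values(s, "host")),
       country = first_or_na(qualifier_values(s, "country")),
       year = year)
}

#' Identify the cargo species of sequence records
#'
#' The sequenced organism is the cargo.  Organisms ranked above species
#' level are discarded; subspecies and no-rank organisms roll up to their
#' parent species through the taxonomy.
#'
#' @param tax a `cargomine_taxonomy`.
#' @param records data.frame from [read_sequence_meta()].
#' @return character vector of cargo species tax_ids aligned with
#'   `records` (`NA` where discarded or the tax_id is unknown).
#' @export
identify_cargo <- function(tax, records) {
  known <- records$tax_id %in% tax$nodes$tax_id
  out <- rep(NA_character_, nrow(records))
  out[known] <- resolve_to_species(tax, records$tax_id[known])
  out
}

strip_parenthetical <- function(x) {
  trimws(gsub("\\s+", " ", gsub("\\([^)]*\\)", " ", x)))
}

match_stage <- function(tax, key) {
  # species id if the key maps to exactly one species; "ambiguous" /
  # "above_species" markers stop further stages; NULL means no hit at all
  stages <- list(direct_latin = tax$sci_index, alt_name = tax$alt_index)
  for (stage in names(stages)) {
    ids <- stages[[stage]][[key]]
    if (!is.null(ids)) {
      sp <- unique(stats::na.omit(resolve_to_species(tax, unique(ids))))
      if (length(sp) == 1L) return(list(species = sp, method = stage))
      if (length(sp) > 1L) return(list(species = NA_character_,
                                       method = "ambiguous"))
      return(list(species = NA_character_, method = "above_species"))
    }
  }
  NULL
}

#' Disambiguate a host qualifier into a carrier species
#'
#' Staged matching, first stage to succeed wins:
#'
#' 1. `direct_latin` — normalized exact match against scientific names;
#' 2. `alt_name` — match against the alternative-name sets (common names,
#'    breeds, misspellings, acronyms);
#' 3. `heuristic` — strip parenthetical qualifier text (e.g.
#'    `"cattle (dairy)"`), then try the leading two-token binomial,
#'    re-running stages 1-2 on each reduced string.
#'
#' A match above species level is discarded; matches below species roll up
#' to the parent species.  A key matching two or more distinct species at
#' the same stage is never guessed: the string stays unresolved.
#'
#' @param tax a `cargomine_taxonomy` (with name sets loaded).
#' @param host_string one non-empty host qualifier.
#' @return list with `raw`, `species_id` (or `NA`) and `method` (one of
#'   `direct_latin`, `alt_name`, `heuristic`, `unresolved`).
#' @export
disambiguate_host <- function(tax, host_string) {
  stopifnot(length(host_string) == 1L)
  if (is.na(host_string) || !nzchar(trimws(host_string)))
    stop("empty host string")
  key <- norm_key(host_string)
  hit <- match_stage(tax, key)
  if (!is.null(hit) && !is.na(hit$species))
    return(list(raw = host_string, species_id = hit$species,
                method = hit$method))
  if (is.null(hit)) {
    # heuristic variants: parentheses stripped, then leading binomial
    variants <- character()
    stripped <- strip_parenthetical(host_string)
    if (nzchar(stripped) && norm_key(stripped) != key)
      variants <- c(variants, stripped)
    toks <- strsplit(trimws(host_string), "\\s+")[[1L]]
    if (length(toks) > 2L)
      variants <- c(variants, paste(toks[1:2], collapse = " "))
    for (v in variants) {
      hit <- match_stage(tax, norm_key(v))
      if (!is.null(hit) && !is.na(hit$species))
        return(list(raw = host_string, species_id = hit$species,
                    method = "heuristic"))
    }
  }
  list(raw = host_string, species_id = NA_character_, method = "unresolved")
}

#' Classify every record of a corpus
#'
#' Partitions a corpus into the four disjoint outcomes of evidence
#' extraction: cargo discarded (sequenced organism above species or
#' unknown), host absent, host unresolved, and interaction-eligible.
#'
#' @param tax a `cargomine_taxonomy`.
#' @param records data.frame from [read_sequence_meta()].
#' @return `records` with added columns `cargo_species`, `carrier_species`,
#'   `carrier_method` and `outcome`.
#' @export
classify_records <- function(tax, records) {
  records$cargo_species <- identify_cargo(tax, records)
  carrier <- rep(NA_character_, nrow(records))
  method <- rep(NA_character_, nrow(records))
  has_host <- !is.na(records$host)
  if (any(has_host)) {
    uniq <- unique(records$host[has_host])
    res <- lapply(uniq, function(h) disambiguate_host(tax, h))
    sp <- structure(vapply(res, function(r) r$species_id, ""), names = uniq)
    me <- structure(vapply(res, function(r) r$method, ""), names = uniq)
    carrier[has_host] <- unname(sp[records$host[has_host]])
    method[has_host] <- unname(me[records$host[has_host]])
  }
  records$carrier_species <- carrier
  records$carrier_method <- method
  records$outcome <- ifelse(is.na(records$cargo_species), "cargo_discarded",
                     ifelse(!has_host, "host_absent",
                     ifelse(is.na(carrier), "host_unresolved",
                            "interaction_eligible")))
  records
}
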