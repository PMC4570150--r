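# Render one OR group in the PubMed-dialect query language.  Each element
# is a curly-quoted term followed by its field tag.  In groups of two or
# more the final element carries no space before its tag, matching the
# published query dialect exactly.
or_group <- function(terms, tag, joiner = " OR ") {
  n <- length(terms)
  sep <- c(rep(" ", max(n - 1L, 0L)), if (n > 1L) "" else " ")
  paste(paste0("‘", terms, "’", sep, tag), collapse = joiner)
}

#' Build the PubMed search term for one organism
#'
#' The query follows the rule: ((any of the organism names and alternative
#' names) AND (all of the inclusion terms)) NOT (any of the exclusion
#' terms).  Names are lowercased, deduplicated and ordered alphabetically;
#' every term is curly-quoted and tagged `[Text Word]`.
#'
#' @param scientific_name the organism's scientific name.
#' @param alt_names character vector of alternative names (may be empty).
#' @param include character vector of inclusion (AND) terms.
#' @param exclude character vector of exclusion (NOT) terms.
#' @param subject_id identifier attached to the query.
#' @return list with `subject_id`, `query_text`, `scope = "text_word"`.
#' @examples
#' build_organism_query("Classical swine fever virus",
#'   alt_names = c("CSFV", "hog cholera virus", "pestivirus type 2",
#'                 "swine fever virus"),
#'   exclude = "african swine fever")$query_text
#' @export
build_organism_query <- function(scientific_name, alt_names = character(),
                                 include = character(),
                                 exclude = character(), subject_id = NA) {
  names <- sort(unique(tolower(trimws(c(scientific_name, alt_names)))))
  names <- names[nzchar(names)]
  if (!length(names)) stop("at least one organism name is required")
  q <- paste0("(", or_group(names, "[Text Word]"), ")")
  for (term in sort(unique(tolower(trimws(include)))))
    q <- paste0(q, " AND (", or_group(term, "[Text Word]"), ")")
  exclude <- sort(unique(tolower(trimws(exclude))))
  exclude <- exclude[nzchar(exclude)]
  if (length(exclude) == 1L) {
    q <- paste0(q, " NOT ", or_group(exclude, "[Text Word]"))
  } else if (length(exclude) > 1L) {
    q <- paste0(q, " NOT (", or_group(exclude, "[Text Word]"), ")")
  }
  list(subject_id = subject_id, query_text = q, scope = "text_word")
}

#' Build the PubMed search terms for a country and its regions
#'
#' Countries listed in the MeSH vocabulary get a MeSH-based country query;
#' others get a title-and-abstract query over the official and alternative
#' country names.  Every region gets a title-and-abstract query OR-joining
#' the region name with its configured major cities and landmarks (the
#' Scotland pattern: region name, then Glasgow, Edinburgh, ...).
#'
#' @param country canonical country name.
#' @param mesh_listed is the country in the MeSH vocabulary?
#' @param alt_names alternative country names (used when not MeSH-listed).
#' @param regions named list: region name -> character vector of major
#'   places within the region.
#' @return list of search terms; the first is the country query
#'   (scope `"mesh"` or `"title_abstract"`), then one
#'   `"title_abstract"` query per region.
#' @export
build_location_queries <- function(country, mesh_listed = TRUE,
                                   alt_names = character(),
                                   regions = list()) {
  out <- list()
  if (mesh_listed) {
    out[[1L]] <- list(subject_id = country,
                      query_text = paste0("‘", country,
                                          "’ [MeSH Terms]"),
                      scope = "mesh")
  } else {
    names <- unique(c(country, alt_names))
    out[[1L]] <- list(
      subject_id = country,
      query_text = paste0("(", or_group(names, "[title or abstract]",
                                        joiner = " or "), ")"),
      scope = "title_abstract")
  }
  for (r in names(regions)) {
    terms <- unique(c(r, regions[[r]]))
    out[[length(out) + 1L]] <- list(
      subject_id = r,
      query_text = paste0("(", or_group(terms, "[title or abstract]",
                                        joiner = " or "), ")"),
      scope = "title_abstract")
  }
  out
}

as_pmids <- function(x) {
  x <- unique(as.integer(x))
  x <- x[!is.na(x) & x > 0L]
  sort(x)
}

#' Read PMID sets from a TSV
#'
#' TSV with columns `subject_id` and `pmid`; one row per citation of the
#' subject (an organism, a country or a region).
#'
#' @param file path.
#' @return named list of sorted integer PMID vectors.
#' @export
read_pmid_sets <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "pmid") %in% names(df)))
    stop("PMID table needs columns subject_id, pmid")
  lapply(split(df$pmid, as.character(df$subject_id)), as_pmids)
}

#' Region evidence: citations about both the region and its country
#'
#' Region PMID sets are only trusted where the paper is also about the
#' country, i.e. the intersection of the region set with the country set.
#'
#' @param pmid_c country PMID set.
#' @param pmid_r region PMID set.
#' @return sorted integer vector (the region-within-country set).
#' @export
region_evidence <- function(pmid_c, pmid_r) {
  intersect(as_pmids(pmid_c), as_pmids(pmid_r))
}

#' Co-citation evidence between two PMID sets
#'
#' Intersects two citation sets and tests the support threshold used for
#' publication-only interactions: five or more shared papers.
#'
#' @param pmids_a,pmids_b integer PMID vectors.
#' @param threshold minimum shared papers (default 5).
#' @return list with `pmids` (sorted intersection) and `passes`
#'   (`TRUE` iff the intersection has at least `threshold` members).
#' @export
co_citation <- function(pmids_a, pmids_b, threshold = 5L) {
  stopifnot(threshold >= 1L)
  shared <- intersect(as_pmids(pmids_a), as_pmids(pmids_b))
  list(pmids = shared, passes = length(shared) >= threshold)
}

#' Match title/abstract records into PMID sets
#'
#' A thin adapter producing PMID sets from raw citation records by
#' case-insensitive substring matching of subject names, for corpora where
#' pre-computed PMID sets are not available.
#'
#' @param citations data.frame(pmid, text) — `text` is the concatenated
#'   title and abstract.
#' @param subjects named list: subject_id -> character vector of names to
#'   match.
#' @return named list of sorted integer PMID vectors.
#' @export
pmids_from_text <- function(citations, subjects) {
  text <- tolower(citations$text)
  lapply(subjects, function(names) {
    hit <- rep(FALSE, length(text))
    for (nm in tolower(names))
      hit <- hit | grepl(nm, text, fixed = TRUE)
    as_pmids(citations$pmid[hit])
  })
}
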