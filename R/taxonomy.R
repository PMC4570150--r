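RANKS <- c("species", "subspecies", "no_rank", "higher")

CATEGORIES <- c(
  "virus", "viroid", "bacteria", "fungi", "protozoa", "helminth",
  "arthropod", "plant", "algae", "cnidaria", "bryozoa", "mollusca",
  "segmented_worm", "porifera", "fish", "amphibian", "reptile", "aves",
  "rodent", "primate", "human", "domestic", "other_mammal", "other"
)

#' Reclassify the rank of a non-viral organism name
#'
#' Taxonomy dumps tag many strains, isolates and unclassified groups as
#' "species".  For everything except viruses and viroids the stored rank is
#' replaced using the shape of the scientific name.  Rules are applied in
#' order, first match wins:
#'
#' 1. name contains any decimal digit -> `no_rank`;
#' 2. name contains the token `unclassified`, `uncultured` or `var`
#'    (case-insensitive, token-boundary match, so "var." matches but
#'    "varanus" does not) -> `no_rank`;
#' 3. exactly two whitespace tokens -> `species` (a binomial);
#' 4. three or more tokens -> `subspecies`;
#' 5. a single token -> `no_rank` (one word cannot be a binomial).
#'
#' Viruses and viroids keep their original rank unchanged.
#'
#' @param name character vector of scientific names (non-empty).
#' @param original_rank character vector in
#'   `c("species","subspecies","no_rank")`, recycled.
#' @param is_virus_or_viroid logical vector, recycled.
#' @return character vector of effective ranks.
#' @examples
#' reclassify_rank("uncultured bacterium", "species", FALSE)   # no_rank
#' reclassify_rank("Homo sapiens", "no_rank", FALSE)           # species
#' reclassify_rank("Canis lupus familiaris", "species", FALSE) # subspecies
#' @export
reclassify_rank <- function(name, original_rank, is_virus_or_viroid) {
  name <- as.character(name)
  if (any(is.na(name) | !nzchar(trimws(name))))
    stop("empty organism name")
  n <- length(name)
  original_rank <- rep_len(as.character(original_rank), n)
  bad <- !original_rank %in% c("species", "subspecies", "no_rank")
  if (any(bad))
    stop("original_rank must be species/subspecies/no_rank, got: ",
         paste(unique(original_rank[bad]), collapse = ", "))
  is_virus_or_viroid <- rep_len(as.logical(is_virus_or_viroid), n)

  has_digit <- grepl("\\p{Nd}", name, perl = TRUE)
  has_kw <- grepl("(^|[^[:alnum:]])(unclassified|uncultured|var)([^[:alnum:]]|$)",
                  tolower(name))
  wc <- word_count(name)

  out <- ifelse(has_digit | has_kw, "no_rank",
         ifelse(wc == 2L, "species",
         ifelse(wc >= 3L, "subspecies", "no_rank")))
  ifelse(is_virus_or_viroid, original_rank, out)
}

map_dump_rank <- function(rank) {
  rank <- tolower(trimws(rank))
  out <- rep("higher", length(rank))
  out[rank == "species"] <- "species"
  out[rank == "subspecies"] <- "subspecies"
  out[rank %in% c("no rank", "no_rank", "norank")] <- "no_rank"
  out
}

# Parse one tab-pipe-delimited taxdump table ("a\t|\tb\t|\t...\t|").
parse_dmp <- function(file) {
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t\\|\t")
}

#' Read a taxonomy dump (node + name tables)
#'
#' Reads the standard tab-pipe-delimited dialect: `nodes.dmp` columns
#' tax_id, parent tax_id, rank; `names.dmp` columns tax_id, name_txt,
#' unique name, name class.  Only `scientific name` rows of the name table
#' are used (a bare 3-column name table is accepted and treated as all
#' scientific names).
#'
#' @param nodes_file,names_file paths.
#' @return data.frame with columns tax_id, parent_id, rank_raw, name.
#' @export
read_taxdump <- function(nodes_file, names_file) {
  nd <- parse_dmp(nodes_file)
  nodes <- data.frame(
    tax_id = vapply(nd, `[`, "", 1L),
    parent_id = vapply(nd, `[`, "", 2L),
    rank_raw = vapply(nd, `[`, "", 3L),
    stringsAsFactors = FALSE
  )
  nm <- parse_dmp(names_file)
  name_txt <- vapply(nm, `[`, "", 2L)
  cls <- vapply(nm, function(x) if (length(x) >= 4L) x[[4L]] else "scientific name", "")
  keep <- trimws(cls) == "scientific name"
  name_map <- name_txt[keep]
  names(name_map) <- vapply(nm, `[`, "", 1L)[keep]
  nodes$name <- unname(name_map[nodes$tax_id])
  if (anyNA(nodes$name))
    stop("nodes without a scientific name: ",
         paste(utils::head(nodes$tax_id[is.na(nodes$name)], 5L), collapse = ", "))
  nodes
}

#' Read a name-set table
#'
#' TSV with columns `tax_id`, `kind` (one of `alt`, `include`, `exclude`)
#' and `term`.  Alternative names, inclusion (AND) and exclusion (NOT)
#' terms drive both host-string disambiguation and search-term generation.
#'
#' @param file path to the TSV.
#' @return data.frame(tax_id, kind, term).
#' @export
read_name_sets <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("tax_id", "kind", "term")
  if (!all(need %in% names(df)))
    stop("name-set table needs columns: ", paste(need, collapse = ", "))
  bad <- !df$kind %in% c("alt", "include", "exclude")
  if (any(bad)) stop("unknown name-set kind: ",
                     paste(unique(df$kind[bad]), collapse = ", "))
  df[need]
}

#' Build a taxonomy object
#'
#' Assembles the working taxonomy: the dump tree, category assignment by
#' nearest anchored ancestor, rank reclassification (viruses and viroids
#' exempt), forced insertion of supplemental organisms, and the name sets.
#'
#' @param nodes data.frame from [read_taxdump()] (or equivalent with
#'   columns tax_id, parent_id, rank_raw or original_rank, name).
#' @param category_anchors data.frame(tax_id, category): internal nodes
#'   anchoring a category; every node takes the category of its nearest
#'   anchored ancestor (itself included), else `"other"`.
#' @param supplement optional data.frame(tax_id, name, rank, parent_id,
#'   category) of organisms to force into the tree, or a path to such a TSV.
#' @param name_sets optional data.frame from [read_name_sets()] or a path.
#' @param fallback_parents named character vector, category -> tax_id, used
#'   when a supplemental organism has no parent in the tree.
#' @return an object of class `cargomine_taxonomy`.
#' @export
load_taxonomy <- function(nodes, category_anchors = NULL, supplement = NULL,
                          name_sets = NULL, fallback_parents = character()) {
  stopifnot(is.data.frame(nodes))
  nodes <- nodes[!duplicated(nodes$tax_id), , drop = FALSE]
  tax <- structure(list(), class = "cargomine_taxonomy")
  tab <- data.frame(
    tax_id = as.character(nodes$tax_id),
    name = as.character(nodes$name),
    parent_id = as.character(nodes$parent_id),
    original_rank = if ("original_rank" %in% names(nodes))
      as.character(nodes$original_rank) else map_dump_rank(nodes$rank_raw),
    source = "ncbi_dump",
    stringsAsFactors = FALSE
  )
  tab$category <- assign_categories(tab, category_anchors)
  reclass <- tab$original_rank %in% c("species", "subspecies", "no_rank")
  tab$effective_rank <- tab$original_rank
  tab$effective_rank[reclass] <- reclassify_rank(
    tab$name[reclass], tab$original_rank[reclass],
    tab$category[reclass] %in% c("virus", "viroid"))
  tax$nodes <- tab
  tax$fallback_parents <- fallback_parents
  check_tree(tax)

  if (!is.null(supplement)) {
    if (is.character(supplement))
      supplement <- utils::read.delim(supplement, stringsAsFactors = FALSE,
                                      colClasses = "character")
    for (i in seq_len(nrow(supplement))) {
      s <- supplement[i, ]
      pp <- s$parent_id
      if (is.na(pp) || !nzchar(pp)) pp <- NULL
      tax <- insert_supplemental(
        tax,
        list(tax_id = s$tax_id, name = s$name, rank = s$rank,
             category = s$category),
        preferred_parent = pp)$taxonomy
    }
  }

  if (!is.null(name_sets)) {
    if (is.character(name_sets)) name_sets <- read_name_sets(name_sets)
  } else {
    name_sets <- data.frame(tax_id = character(), kind = character(),
                            term = character(), stringsAsFactors = FALSE)
  }
  tax$name_sets <- name_sets
  tax <- reindex(tax)
  tax
}

# Nearest anchored ancestor category, "other" if no anchor on the root path.
assign_categories <- function(tab, anchors) {
  if (is.null(anchors) || nrow(anchors) == 0L)
    return(rep("other", nrow(tab)))
  bad <- !anchors$category %in% CATEGORIES
  if (any(bad)) stop("unknown category: ",
                     paste(unique(anchors$category[bad]), collapse = ", "))
  anchor <- structure(as.character(anchors$category),
                      names = as.character(anchors$tax_id))
  parent <- structure(tab$parent_id, names = tab$tax_id)
  out <- unname(anchor[tab$tax_id])
  cur <- tab$tax_id
  active <- is.na(out)
  for (step in seq_len(nrow(tab) + 1L)) {
    if (!any(active)) break
    nxt <- unname(parent[cur[active]])
    at_root <- is.na(nxt) | nxt == cur[active]
    cur[active] <- ifelse(at_root, NA_character_, nxt)
    hit <- active & !is.na(cur)
    out[hit] <- unname(anchor[cur[hit]])
    active <- is.na(out) & !is.na(cur)
  }
  out[is.na(out)] <- "other"
  out
}

reindex <- function(tax) {
  tab <- tax$nodes
  tax$row <- structure(seq_len(nrow(tab)), names = tab$tax_id)
  sci <- norm_key(tab$name)
  tax$sci_index <- split(tab$tax_id, sci)
  ns <- tax$name_sets
  if (!is.null(ns) && nrow(ns) > 0L) {
    alt <- ns[ns$kind == "alt", , drop = FALSE]
    tax$alt_index <- split(alt$tax_id, norm_key(alt$term))
  } else {
    tax$alt_index <- list()
  }
  tax
}

check_tree <- function(tax) {
  tab <- tax$nodes
  if (anyDuplicated(tab$tax_id)) stop("duplicate tax_id in taxonomy")
  root <- tab$tax_id[is.na(tab$parent_id) | tab$parent_id == tab$tax_id]
  if (length(root) != 1L)
    stop("taxonomy must have exactly one root, found ", length(root))
  known <- tab$parent_id %in% tab$tax_id | is.na(tab$parent_id)
  if (!all(known))
    stop("parent_id not in tree: ",
         paste(utils::head(tab$parent_id[!known], 5L), collapse = ", "))
  # cycle check: every node must reach the root within n steps
  parent <- structure(tab$parent_id, names = tab$tax_id)
  cur <- tab$tax_id
  for (step in seq_len(nrow(tab))) {
    done <- is.na(cur) | cur == root
    if (all(done)) return(invisible(TRUE))
    nxt <- unname(parent[cur[!done]])
    stuck <- nxt == cur[!done]
    nxt[stuck] <- NA_character_
    cur[!done] <- nxt
  }
  stop("cycle detected in taxonomy parent links")
}

#' Force a supplemental organism into the taxonomy tree
#'
#' Organisms of interest missing from the dump are attached to the most
#' suitable parent; when no parent is given the configured fallback node
#' for the organism's category is used.
#'
#' @param tax a `cargomine_taxonomy`.
#' @param node list with `tax_id`, `name`, `rank` (species/subspecies/
#'   no_rank/higher) and `category`.
#' @param preferred_parent tax_id of the parent, or `NULL` for the
#'   category fallback.
#' @return list with elements `taxonomy` (updated) and `parent_id`
#'   (the assigned parent).
#' @export
insert_supplemental <- function(tax, node, preferred_parent = NULL) {
  stopifnot(inherits(tax, "cargomine_taxonomy"))
  id <- as.character(node$tax_id)
  if (id %in% tax$nodes$tax_id)
    stop("tax_id already present: ", id)
  if (is.null(preferred_parent)) {
    parent <- unname(tax$fallback_parents[node$category])
    if (is.na(parent) || is.null(parent))
      stop("no fallback parent configured for category: ", node$category)
  } else {
    parent <- as.character(preferred_parent)
    if (!parent %in% tax$nodes$tax_id)
      stop("preferred parent not in tree: ", parent)
  }
  orank <- map_dump_rank(node$rank)
  erank <- if (orank %in% c("species", "subspecies", "no_rank"))
    reclassify_rank(node$name, orank,
                    node$category %in% c("virus", "viroid"))
  else orank
  tax$nodes <- rbind(tax$nodes, data.frame(
    tax_id = id, name = as.character(node$name), parent_id = parent,
    original_rank = orank, source = "supplemental",
    category = as.character(node$category), effective_rank = erank,
    stringsAsFactors = FALSE))
  tax <- reindex(tax)
  list(taxonomy = tax, parent_id = parent)
}

#' Resolve organisms to their species-level ancestor
#'
#' Species map to themselves; subspecies and no-rank organisms walk parent
#' links upward to the first species-level ancestor; organisms at genus
#' level or above, and organisms with no species ancestor, resolve to `NA`
#' (callers discard such records).
#'
#' @param tax a `cargomine_taxonomy`.
#' @param tax_id character vector of identifiers (all must exist).
#' @return character vector of species tax_ids, `NA` where unresolvable.
#' @export
resolve_to_species <- function(tax, tax_id) {
  stopifnot(inherits(tax, "cargomine_taxonomy"))
  ids <- as.character(tax_id)
  row <- tax$row[ids]
  if (anyNA(row))
    stop("unknown tax_id: ",
         paste(utils::head(ids[is.na(row)], 5L), collapse = ", "))
  tab <- tax$nodes
  out <- rep(NA_character_, length(ids))
  cur <- ids
  active <- rep(TRUE, length(ids))
  for (step in seq_len(nrow(tab) + 1L)) {
    if (!any(active)) break
    r <- tax$row[cur[active]]
    rk <- tab$effective_rank[r]
    hit <- rk == "species"
    idx <- which(active)
    out[idx[hit]] <- cur[idx[hit]]
    dead <- rk == "higher"
    parent <- tab$parent_id[r]
    at_root <- is.na(parent) | parent == cur[active]
    active[idx[hit | dead | at_root]] <- FALSE
    keep <- which(active)
    if (length(keep)) cur[keep] <- tab$parent_id[tax$row[cur[keep]]]
  }
  out
}

#' @export
print.cargomine_taxonomy <- function(x, ...) {
  tab <- x$nodes
  cat("<cargomine taxonomy>\n")
  cat("  nodes:", nrow(tab),
      sprintf("(%d supplemental)", sum(tab$source == "supplemental")), "\n")
  cat("  effective ranks:",
      paste(sprintf("%s=%d", names(table(tab$effective_rank)),
                    as.integer(table(tab$effective_rank))), collapse = " "),
      "\n")
  cat("  name-set terms:", nrow(x$name_sets), "\n")
  invisible(x)
}

tax_field <- function(tax, ids, field) {
  r <- tax$row[as.character(ids)]
  if (anyNA(r)) stop("unknown tax_id: ",
                     paste(utils::head(ids[is.na(r)], 5L), collapse = ", "))
  tax$nodes[[field]][r]
}

#' Look up scientific names or categories by tax_id
#' @param tax a `cargomine_taxonomy`.
#' @param ids character vector of tax_ids.
#' @return character vector.
#' @export
tax_name <- function(tax, ids) tax_field(tax, ids, "name")

#' @rdname tax_name
#' @export
tax_category <- function(tax, ids) tax_field(tax, ids, "category")

#' Name set attached to one organism
#'
#' @param tax a `cargomine_taxonomy`.
#' @param tax_id one identifier.
#' @return list with character vectors `alt`, `include`, `exclude`.
#' @export
name_set <- function(tax, tax_id) {
  ns <- tax$name_sets
  ns <- ns[ns$tax_id == as.character(tax_id), , drop = FALSE]
  list(alt = ns$term[ns$kind == "alt"],
       include = ns$term[ns$kind == "include"],
       exclude = ns$term[ns$kind == "exclude"])
}
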