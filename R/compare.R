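#' Overlap statistics between two identifier sets
#'
#' The share/union arithmetic used to validate the interaction dataset
#' against external pathogen lists: set sizes, shared count, the two
#' directed share percentages (rounded half-up to 2 decimal places) and
#' the union size.
#'
#' @param set_a,set_b identifier vectors (pre-harmonized; duplicates are
#'   ignored).
#' @return object of class `cargomine_overlap`: list with `n_a`, `n_b`,
#'   `n_shared`, `pct_a_in_b` (share of A found in B), `pct_b_in_a`,
#'   `n_union`.
#' @examples
#' o <- overlap(letters[1:10], letters[6:15])
#' o$pct_a_in_b  # 50
#' @export
overlap <- function(set_a, set_b) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  overlap_counts(length(a), length(b), length(intersect(a, b)))
}

#' @rdname overlap
#' @param n_a,n_b,n_shared counts, for computing the same statistics from
#'   published table counts rather than the sets themselves.
#' @export
overlap_counts <- function(n_a, n_b, n_shared) {
  if (n_a == 0L || n_b == 0L)
    stop("overlap percentage undefined for an empty set")
  if (n_shared > min(n_a, n_b)) stop("n_shared exceeds a set size")
  structure(list(
    n_a = n_a, n_b = n_b, n_shared = n_shared,
    pct_a_in_b = round_half_up(100 * n_shared / n_a),
    pct_b_in_a = round_half_up(100 * n_shared / n_b),
    n_union = n_a + n_b - n_shared), class = "cargomine_overlap")
}

#' @export
print.cargomine_overlap <- function(x, ...) {
  cat(sprintf(
    "<overlap> |A|=%d |B|=%d shared=%d union=%d  A-in-B=%.2f%%  B-in-A=%.2f%%\n",
    x$n_a, x$n_b, x$n_shared, x$n_union, x$pct_a_in_b, x$pct_b_in_a))
  invisible(x)
}

#' Overlap statistics per cargo category
#'
#' Computes [overlap()] within each category plus a totals entry over the
#' full sets; when the categories partition the identifier space the
#' per-category shared counts sum to the total shared count.
#'
#' @param set_a,set_b identifier vectors.
#' @param category_map named character vector, identifier -> category;
#'   every identifier in either set must be categorized.
#' @return named list of `cargomine_overlap`, one per category present,
#'   plus `"Totals"`.
#' @export
overlap_by_category <- function(set_a, set_b, category_map) {
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  ids <- union(a, b)
  cat <- category_map[ids]
  if (anyNA(cat))
    stop("uncategorized identifiers: ",
         paste(utils::head(ids[is.na(cat)], 5L), collapse = ", "))
  out <- list()
  for (k in sort(unique(unname(cat)))) {
    in_k <- ids[cat == k]
    out[[k]] <- overlap(intersect(a, in_k), intersect(b, in_k))
  }
  out$Totals <- overlap(a, b)
  out
}

#' Cargo overlap at the pathogen level within a host scope
#'
#' When an external dataset lists only a few hosts, comparison happens at
#' the cargo (pathogen) level: each interaction set is projected to the
#' set of cargo species interacting with at least one host in scope, and
#' the two projections are compared with [overlap()].
#'
#' @param interactions_a,interactions_b interaction data.frames (columns
#'   cargo_id, carrier_id).
#' @param host_scope non-empty character vector of carrier species ids.
#' @return a `cargomine_overlap` over the projected cargo sets.
#' @export
pathogen_level_overlap <- function(interactions_a, interactions_b,
                                   host_scope) {
  if (!length(host_scope)) stop("host_scope must be nonempty")
  project <- function(x)
    unique(x$cargo_id[x$carrier_id %in% host_scope])
  overlap(project(interactions_a), project(interactions_b))
}

#' Shared-cargo network among carriers
#'
#' Builds the undirected weighted graph summarizing cargo sharing: one
#' node per in-scope carrier, node attribute `n_cargo` = number of unique
#' cargo species it carries (restricted to the given cargo categories),
#' and an edge between two carriers iff they share at least one cargo
#' species, weighted by the shared count.  No self-loops.
#'
#' @param tax a `cargomine_taxonomy`.
#' @param interactions interaction data.frame.
#' @param carrier_scope carrier species ids to include as nodes.
#' @param cargo_categories cargo categories to count (default: the
#'   pathogen-associated groups).
#' @return an [igraph::igraph] object with vertex attributes `name` and
#'   `n_cargo` and edge attribute `weight`.
#' @export
shared_cargo_network <- function(tax, interactions, carrier_scope,
                                 cargo_categories = c("virus", "bacteria",
                                                      "fungi", "helminth",
                                                      "protozoa")) {
  keep <- interactions$carrier_id %in% carrier_scope &
    tax_category(tax, interactions$cargo_id) %in% cargo_categories
  x <- interactions[keep, , drop = FALSE]
  cargo_of <- lapply(split(x$cargo_id, x$carrier_id), unique)
  nodes <- as.character(carrier_scope)
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  nc <- lengths(cargo_of)[nodes]
  nc[is.na(nc)] <- 0L
  g <- igraph::set_vertex_attr(g, "n_cargo", value = as.integer(nc))
  carriers <- names(cargo_of)
  if (length(carriers) >= 2L) {
    pairs <- utils::combn(carriers, 2L)
    w <- apply(pairs, 2L, function(p)
      length(intersect(cargo_of[[p[1L]]], cargo_of[[p[2L]]])))
    keep <- w >= 1L
    if (any(keep)) {
      g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
      g <- igraph::set_edge_attr(g, "weight", value = w[keep])
    }
  }
  g
}

#' Export a shared-cargo network
#'
#' Writes the graph as a tab-separated edge list (`from`, `to`, `weight`)
#' or as GraphML text.
#'
#' @param graph an igraph object from [shared_cargo_network()].
#' @param file output path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `file`, invisibly.
#' @export
write_network <- function(graph, file, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, file, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    df <- data.frame(from = el[, 1L], to = el[, 2L],
                     weight = if (nrow(el))
                       igraph::E(graph)$weight else numeric(),
                     stringsAsFactors = FALSE)
    utils::write.table(df, file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(file)
}

#' Read an external comparison list
#'
#' External validation datasets enter as plain TSVs with columns
#' `identifier`, `category` and optionally `host` and `prevalence`.  For
#' presence-only comparison, rows with negative prevalence can be dropped
#' at read time (`nonnegative_prevalence = TRUE`), since a presence-only
#' database cannot represent "pathogen P is absent from host H".
#'
#' @param file path to the TSV.
#' @param nonnegative_prevalence drop rows with `prevalence < 0`?
#' @return data.frame of the remaining rows.
#' @export
read_comparison_list <- function(file, nonnegative_prevalence = FALSE) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!"identifier" %in% names(df))
    stop("comparison list needs an 'identifier' column")
  if (nonnegative_prevalence) {
    if (is.null(df$prevalence))
      stop("nonnegative_prevalence requires a 'prevalence' column")
    df <- df[df$prevalence >= 0, , drop = FALSE]
  }
  row.names(df) <- NULL
  df
}
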