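# Shared in-code fixtures for the unit tests.

# A hand-built taxonomy: a virus clade, a bacterial clade and a mammal
# clade with species, a subspecies, a strain and common-name sets.
make_tiny_tax <- function() {
  n <- function(id, parent, rank, name)
    data.frame(tax_id = id, parent_id = parent, rank_raw = rank,
               name = name, stringsAsFactors = FALSE)
  nodes <- rbind(
    n("1", "1", "no rank", "root"),
    n("10", "1", "superkingdom", "Viruses"),
    n("20", "1", "superkingdom", "Bacteria"),
    n("30", "1", "superkingdom", "Mammalia"),
    n("11", "10", "genus", "Pestivirus"),
    n("12", "11", "species", "Classical swine fever virus"),
    n("13", "12", "no rank", "CSFV isolate 39"),
    n("21", "20", "genus", "Bacillus"),
    n("22", "21", "species", "Bacillus anthracis"),
    n("23", "22", "no rank", "Bacillus anthracis str. Ames"),
    n("31", "30", "genus", "Ovis"),
    n("32", "31", "species", "Ovis aries"),
    n("33", "32", "subspecies", "Ovis aries aries"),
    n("34", "30", "genus", "Homo"),
    n("35", "34", "species", "Homo sapiens"),
    n("36", "30", "genus", "Bos"),
    n("37", "36", "species", "Bos taurus"))
  anchors <- data.frame(
    tax_id = c("10", "20", "30", "35"),
    category = c("virus", "bacteria", "other_mammal", "human"),
    stringsAsFactors = FALSE)
  name_sets <- data.frame(
    tax_id = c("32", "37", "37", "12", "12", "12", "12", "12"),
    kind = c("alt", "alt", "alt", "alt", "alt", "alt", "alt", "exclude"),
    term = c("sheep", "cattle", "cow", "CSFV", "hog cholera virus",
             "pestivirus type 2", "swine fever virus", "african swine fever"),
    stringsAsFactors = FALSE)
  load_taxonomy(nodes, category_anchors = anchors, name_sets = name_sets,
                fallback_parents = c(bacteria = "20", other_mammal = "30"))
}

demo_gaz <- function() {
  read_gazetteer(system.file("extdata", "gazetteer.tsv",
                             package = "cargomine"))
}

# independent re-statement of the rank rules, used as a brute-force oracle
oracle_rank <- function(name, rank, virus) {
  if (virus) return(rank)
  if (grepl("[0-9]", name)) return("no_rank")
  toks <- strsplit(tolower(trimws(name)), "[^[:alnum:]]+")[[1]]
  if (any(toks %in% c("unclassified", "uncultured", "var"))) return("no_rank")
  wc <- length(strsplit(trimws(name), "[[:space:]]+")[[1]])
  if (wc == 2) "species" else if (wc >= 3) "subspecies" else "no_rank"
}
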