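#' Normalize free-text names for dictionary matching
#'
#' Source qualifiers in sequence metadata are free text; matching against
#' taxonomy names or the gazetteer therefore goes through a single
#' normalization: case-fold, strip diacritics, collapse internal whitespace,
#' and strip leading/trailing punctuation.  Normalization is idempotent, so
#' looking up an already-normalized key gives the same result as looking up
#' the raw key.
#'
#' @param x character vector.
#' @return character vector of normalized keys.
#' @examples
#' norm_key(c("  Sao  Paulo. ", "MILAN"))
#' @export
norm_key <- function(x) {
  x <- as.character(x)
  out <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  # iconv returns NA for untranslatable bytes; fall back to the raw string
  out[is.na(out)] <- x[is.na(out)]
  out <- tolower(out)
  out <- gsub("\\s+", " ", out)
  out <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", out)
  out
}

#' Count whitespace-delimited tokens in a name
#'
#' @param name character vector.
#' @return integer vector of token counts (0 for empty strings).
#' @keywords internal
word_count <- function(name) {
  name <- trimws(name)
  ifelse(nchar(name) == 0L, 0L,
         lengths(strsplit(name, "\\s+")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Decimal rounding, ties away from zero (half-up).  base::round() rounds
# half to even, which disagrees with the printed validation tables on .xx5
# boundaries.
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
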