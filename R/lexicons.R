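the_lexicon_cache <- new.env(parent = emptyenv())

#' Load the detector lexicons
#'
#' All pattern classes used by the deterministic detectors — criterion
#' keyword/phrase lexicons (with optional proximity-context and exclusion
#' lists), the vendor list, the known-software registry, and the
#' methods-section title lexicon — live in an editable JSON config shipped
#' with the package. Supplying your own file lets you extend recall (e.g.,
#' add software tools to the registry) without touching code.
#'
#' @param path Path to a lexicon JSON file. Defaults to the copy shipped in
#'   `inst/extdata/lexicons.json`.
#' @return A named list with elements `methods_titles`, `criteria`,
#'   `vendors`, `software_registry`, `cell_line_registry`, `name_stopwords`.
#' @export
#' @examples
#' lex <- default_lexicons()
#' names(lex$criteria)
default_lexicons <- function(path = NULL) {
  use_cache <- is.null(path)
  if (use_cache) {
    if (!is.null(the_lexicon_cache$default)) {
      return(the_lexicon_cache$default)
    }
    path <- system.file("extdata", "lexicons.json", package = "rtindex")
  }
  lex <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(all(RIGOR_CRITERIA %in% names(lex$criteria)))
  lex <- compile_lexicons(lex)
  if (use_cache) the_lexicon_cache$default <- lex
  lex
}

# Pre-compile alternation patterns so sentence scans are single regex calls.
compile_lexicons <- function(lex) {
  alt <- function(pats) {
    pats <- pats[nzchar(pats %||% character(0))]
    if (length(pats) == 0) return(NULL)
    paste0("(?:", pats, ")", collapse = "|")
  }
  literal_alt <- function(words) {
    words <- words[order(-nchar(words))]
    paste0("\\b(?:", paste(vapply(words, escape_regex, ""), collapse = "|"),
           ")\\b")
  }
  lex$vendor_pattern <- literal_alt(lex$vendors)
  lex$software_pattern <- literal_alt(lex$software_registry)
  lex$criteria_compiled <- lapply(lex$criteria, function(rules) {
    list(include = alt(rules$include), weak = alt(rules$weak),
         context = alt(rules$context), exclude = alt(rules$exclude))
  })
  all_pats <- unlist(lapply(lex$criteria, function(r) c(r$include, r$weak)))
  lex$any_criterion_pattern <- alt(all_pats)
  lex
}
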