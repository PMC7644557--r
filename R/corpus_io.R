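#' Build a document tibble from raw pieces
#'
#' The corpus container is a tibble with one row per article: identifier,
#' journal metadata, the raw methods-section text, a flag recording whether a
#' methods section was located, and a list-column of sentence spans.
#' Documents whose methods section could not be found are retained with empty
#' `methods_text` and `methods_found = FALSE`; downstream they score 0 and
#' count as unscorable.
#'
#' @param doc_id Character scalar identifying the article.
#' @param journal,issn Journal name and ISSN (`issn` may be `""`).
#' @param year Publication year (integer, 1900..current year + 1).
#' @param methods_text Methods-section text (UTF-8).
#' @param methods_found Whether a methods section was located.
#' @return A one-row document tibble with a `sentences` list-column.
#' @export
#' @examples
#' new_document("d1", "J Test", "0000-0000", 2019, "Mice were randomized.")
new_document <- function(doc_id, journal, issn, year, methods_text,
                         methods_found = nzchar(methods_text)) {
  year <- as.integer(year)
  cur <- as.integer(format(Sys.Date(), "%Y"))
  if (is.na(year) || year < 1900L || year > cur + 1L) {
    abort_rtindex(sprintf("year must be in [1900, %d], got %s", cur + 1L, year),
                  "bad_year")
  }
  tibble::tibble(
    doc_id = as.character(doc_id),
    journal = as.character(journal),
    issn = as.character(issn %||% ""),
    year = year,
    methods_text = as.character(methods_text),
    methods_found = isTRUE(methods_found),
    sentences = list(segment_sentences(methods_text))
  )
}

#' Read a JATS XML article
#'
#' Parses a PMC Open Access style JATS article, pulls journal name, ISSN and
#' publication year from the front matter, locates the methods section by
#' `sec-type` attribute or section title (see [extract_methods_section()]),
#' and segments it into sentences. When no methods section can be found the
#' document is still returned, with empty `methods_text`,
#' `methods_found = FALSE`, and a `"rtindex_methods_missing"` condition
#' signalled as a warning — mirroring how articles whose methods live in a
#' supplementary PDF are effectively invisible to text mining.
#'
#' @param xml A file path, raw vector, or XML string containing one JATS
#'   `<article>`.
#' @param doc_id Optional identifier; defaults to the first `<article-id>` or
#'   `"unknown"`.
#' @param lexicons Lexicon list from [default_lexicons()].
#' @return A one-row document tibble (see [new_document()]).
#' @export
read_jats <- function(xml, doc_id = NULL, lexicons = default_lexicons()) {
  doc <- xml2::read_xml(xml)

  text1 <- function(xpath) {
    node <- xml2::xml_find_first(doc, xpath)
    if (inherits(node, "xml_missing")) "" else stringr::str_squish(xml2::xml_text(node))
  }
  journal <- text1(".//front//journal-meta//journal-title")
  issn <- text1(".//front//journal-meta//issn")
  year <- suppressWarnings(as.integer(text1(".//front//article-meta//pub-date/year")))
  if (is.na(year)) year <- suppressWarnings(as.integer(text1(".//pub-date/year")))
  if (is.null(doc_id)) {
    doc_id <- text1(".//front//article-meta//article-id")
    if (!nzchar(doc_id)) doc_id <- "unknown"
  }

  body <- xml2::xml_find_first(doc, ".//body")
  methods_text <- if (inherits(body, "xml_missing")) "" else {
    extract_methods_section(body, lexicons = lexicons)
  }
  if (!nzchar(methods_text)) {
    rlang::warn(
      sprintf("no methods section found in document '%s'", doc_id),
      class = "rtindex_methods_missing"
    )
  }
  new_document(doc_id, journal, issn, year, methods_text,
               methods_found = nzchar(methods_text))
}

#' Extract methods-section text from a parsed section tree
#'
#' Walks the `<sec>` elements of a JATS body and concatenates the paragraph
#' text of every section whose `sec-type` attribute contains "methods" or
#' "materials", or whose `<title>` matches the configurable methods-title
#' lexicon (case-insensitive). Returns `""` when nothing matches; an empty
#' result is a valid outcome, not an error.
#'
#' @param body An `xml_node` for the article `<body>` (or any node holding
#'   `<sec>` children).
#' @param lexicons Lexicon list; `lexicons$methods_titles` is the title list.
#' @return A single string: matched section paragraphs joined by spaces.
#' @export
extract_methods_section <- function(body, lexicons = default_lexicons()) {
  secs <- xml2::xml_find_all(body, ".//sec")
  titles <- tolower(lexicons$methods_titles)
  keep <- vapply(secs, function(sec) {
    st <- tolower(xml2::xml_attr(sec, "sec-type") %||% "")
    if (!is.na(st) && nzchar(st) &&
        grepl("methods|materials", st, fixed = FALSE)) {
      return(TRUE)
    }
    tt <- xml2::xml_find_first(sec, "./title")
    if (inherits(tt, "xml_missing")) return(FALSE)
    stringr::str_squish(tolower(xml2::xml_text(tt))) %in% titles
  }, logical(1))
  secs <- secs[keep]
  # Drop matched sections nested inside an already-matched section so
  # paragraph text is not duplicated.
  if (length(secs) > 1) {
    paths <- xml2::xml_path(secs)
    nested <- vapply(seq_along(paths), function(i) {
      any(startsWith(paths[i], paste0(paths[-i], "/")))
    }, logical(1))
    secs <- secs[!nested]
  }
  paras <- unlist(lapply(secs, function(sec) {
    vapply(xml2::xml_find_all(sec, ".//p"), function(p) {
      stringr::str_squish(xml2::xml_text(p))
    }, character(1))
  }))
  paras <- paras[nzchar(paras %||% character(0))]
  paste(paras, collapse = " ")
}

#' Read a plain-text methods section with a JSON metadata sidecar
#'
#' @param txt_path Path to a UTF-8 text file holding the methods section.
#' @param json_path Path to a JSON sidecar `{doc_id, journal, issn, year}`;
#'   defaults to `txt_path` with extension `.json`.
#' @return A one-row document tibble.
#' @export
read_methods_text <- function(txt_path, json_path = NULL) {
  if (is.null(json_path)) {
    json_path <- paste0(tools::file_path_sans_ext(txt_path), ".json")
  }
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  text <- paste(readLines(txt_path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  new_document(meta$doc_id, meta$journal, meta$issn %||% "", meta$year, text)
}

# Abbreviations after which a period never ends a sentence.
SENTENCE_ABBREVS <- c(
  "no", "fig", "figs", "al", "e.g", "i.e", "i.m", "i.p", "i.v", "s.c",
  "vs", "cf", "dr", "drs", "ca", "approx", "inc", "co", "ltd", "st",
  "cat", "vol", "eq", "ref", "refs", "min", "max", "resp", "etc"
)

#' Segment text into sentences with character offsets
#'
#' A deterministic rule-based splitter: a sentence ends at `.`, `!` or `?`
#' followed by whitespace and an upper-case letter, digit or opening bracket.
#' Splits are suppressed after known abbreviations (e.g. "Fig.", "et al.",
#' "i.m."), after single-initial tokens ("J. Neurosci"), inside decimal
#' numbers, and never inside an `RRID:` token. Offsets are 0-based,
#' half-open; `text[start:end]` in that convention reproduces each sentence
#' exactly, and concatenating spans with the original inter-span whitespace
#' reconstructs the input.
#'
#' @param text A string (may be empty).
#' @return A tibble with columns `index` (0-based), `start`, `end`
#'   (0-based, half-open character offsets) and `text`.
#' @export
#' @examples
#' segment_sentences("Mice were randomized. Cells were washed.")
segment_sentences <- function(text) {
  empty <- tibble::tibble(index = integer(), start = integer(),
                          end = integer(), text = character())
  if (is.null(text) || is.na(text) || !nzchar(text)) return(empty)

  chars <- stringr::str_split(text, "")[[1]]
  n <- length(chars)
  # Candidate breakpoints: position i (1-based) holds a terminator.
  breaks <- integer(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(".", "!", "?")) {
      # consume a run of closing quotes/brackets after the terminator
      j <- i + 1L
      while (j <= n && chars[j] %in% c("\"", "'", ")", "]", "”", "’")) {
        j <- j + 1L
      }
      followed_ws <- j <= n && grepl("\\s", chars[j])
      k <- j
      while (k <= n && grepl("\\s", chars[k])) k <- k + 1L
      next_ok <- k > n || grepl("[A-Z0-9(\\[\"“]", chars[k])
      boundary_ok <- (j > n) || (followed_ws && next_ok)
      if (boundary_ok) {
        ok <- TRUE
        if (ch == ".") {
          prefix <- substr(text, max(1L, i - 12L), i - 1L)
          last_tok <- stringr::str_extract(prefix, "[A-Za-z.]+$")
          if (!is.na(last_tok)) {
            tok <- tolower(sub("\\.$", "", last_tok))
            if (tok %in% SENTENCE_ABBREVS) ok <- FALSE
            # single initial like "J." or part of dotted abbreviation "e.g."
            if (nchar(gsub("\\.", "", last_tok)) == 1L) ok <- FALSE
          }
          # "et al." handled via "al"; decimal numbers need a digit after the
          # period with no whitespace, which already fails followed_ws.
        }
        if (ok) breaks <- c(breaks, j - 1L)
      }
    }
    i <- i + 1L
  }

  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]

  out <- purrr::map2_dfr(starts, ends, function(s, e) {
    raw <- substr(text, s, e)
    lead <- nchar(stringr::str_extract(raw, "^\\s*"))
    trail <- nchar(stringr::str_extract(raw, "\\s*$"))
    s2 <- s + lead
    e2 <- e - trail
    if (s2 > e2) return(NULL)
    tibble::tibble(start = s2 - 1L, end = e2, text = substr(text, s2, e2))
  })
  if (nrow(out) == 0) return(empty)
  out$index <- seq_len(nrow(out)) - 1L
  out[, c("index", "start", "end", "text")]
}

#' Flatten a corpus into one row per sentence
#'
#' @param documents A document tibble.
#' @return A tibble with `doc_id`, `index`, `start`, `end`, `text`.
#' @export
corpus_sentences <- function(documents) {
  documents |>
    dplyr::select("doc_id", "sentences") |>
    tidyr::unnest("sentences")
}

#' Read an impact-factor table
#'
#' Reads a CSV with header columns `journal`, `issn`, `year`, `jif` for the
#' RTI-versus-impact-factor comparison. ISSN is the preferred join key when
#' present, making the comparison robust to journal-name spelling variants.
#'
#' @param csv_path Path to the CSV file.
#' @return A tibble with columns `journal`, `issn`, `year` (integer), `jif`
#'   (double), one row per (journal, year).
#' @export
read_if_table <- function(csv_path) {
  tab <- readr::read_csv(csv_path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("journal", "issn", "year", "jif")
  if (!all(need %in% names(tab))) {
    abort_rtindex(paste("impact-factor CSV must have columns:",
                        paste(need, collapse = ", ")), "if_columns")
  }
  jif <- suppressWarnings(as.numeric(tab$jif))
  if (anyNA(jif)) {
    bad <- which(is.na(jif))[1]
    abort_rtindex(sprintf("non-numeric jif value '%s' in row %d",
                          tab$jif[bad], bad), "if_nonnumeric")
  }
  year <- suppressWarnings(as.integer(tab$year))
  if (anyNA(year)) {
    abort_rtindex("non-integer year in impact-factor CSV", "if_year")
  }
  dup <- duplicated(tab[, c("journal", "year")])
  if (any(dup)) {
    bad <- which(dup)[1]
    abort_rtindex(sprintf("duplicate (journal, year) row %d: %s, %s",
                          bad, tab$journal[bad], tab$year[bad]), "if_duplicate")
  }
  tibble::tibble(journal = tab$journal, issn = tab$issn %||% "",
                 year = year, jif = jif)
}
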