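#' Detect rigor-criterion statements
#'
#' Scans every sentence of every document with the per-criterion
#' keyword/phrase lexicons. Each criterion has `include` patterns (sufficient
#' on their own), optional `weak` patterns that additionally require a
#' proximity `context` term in the same sentence (e.g. a blinding term plus
#' an investigator/analysis term), and `exclude` patterns that both mask
#' their matches (so "Sex-lethal" cannot satisfy the sex criterion) and
#' disable the weak patterns for that sentence (so "approved by the ...
#' Animal Care and Use Committee" is not read as IRB approval). The engine is
#' fully deterministic: identical text always yields identical hits, with
#' confidence 1.
#'
#' @param documents A document tibble (see [new_document()], [read_jats()]).
#' @param lexicons Lexicon list from [default_lexicons()].
#' @return A tibble of criterion hits: `doc_id`, `criterion`,
#'   `sentence_index`, `evidence` (verbatim substring of the sentence),
#'   `confidence`. At most one hit per (criterion, sentence).
#' @export
#' @examples
#' doc <- new_document("d1", "J", "", 2019,
#'   "Animals were assigned to experimental groups using simple randomization.")
#' detect_rigor_criteria(doc)
detect_rigor_criteria <- function(documents, lexicons = default_lexicons()) {
  sents <- corpus_sentences(documents)
  if (nrow(sents) == 0) return(empty_hits())
  # cheap prescreen: most sentences contain no criterion vocabulary at all
  maybe <- stringr::str_detect(
    sents$text,
    stringr::regex(lexicons$any_criterion_pattern, ignore_case = TRUE))
  sents <- sents[maybe, ]
  if (nrow(sents) == 0) return(empty_hits())
  hits <- purrr::pmap_dfr(
    list(sents$doc_id, sents$index, sents$text),
    function(doc_id, index, text) {
      purrr::map_dfr(RIGOR_CRITERIA, function(crit) {
        ev <- match_criterion(text, lexicons$criteria_compiled[[crit]])
        if (is.na(ev)) return(NULL)
        tibble::new_tibble(list(doc_id = doc_id, criterion = crit,
                                sentence_index = index, evidence = ev,
                                confidence = 1), nrow = 1L)
      })
    }
  )
  if (nrow(hits) == 0) empty_hits() else hits
}

empty_hits <- function() {
  tibble::tibble(doc_id = character(), criterion = character(),
                 sentence_index = integer(), evidence = character(),
                 confidence = double())
}

# Returns the evidence substring (verbatim from the original sentence) or NA.
# `rules` holds the pre-compiled alternation patterns (compile_lexicons()).
match_criterion <- function(text, rules) {
  masked <- text
  excluded <- FALSE
  if (!is.null(rules$exclude)) {
    loc <- stringr::str_locate_all(
      masked, stringr::regex(rules$exclude, ignore_case = TRUE))[[1]]
    if (nrow(loc) > 0) {
      excluded <- TRUE
      masked <- mask_spans(masked, tibble::tibble(start = loc[, 1] - 1L,
                                                  end = loc[, 2]))
    }
  }
  first_match <- function(pat) {
    loc <- stringr::str_locate(masked, stringr::regex(pat, ignore_case = TRUE))
    if (is.na(loc[1, 1])) return(NA_character_)
    substr(text, loc[1, 1], loc[1, 2])
  }
  if (!is.null(rules$include)) {
    ev <- first_match(rules$include)
    if (!is.na(ev)) return(ev)
  }
  if (is.null(rules$weak) || excluded) return(NA_character_)
  if (!is.null(rules$context) &&
      !stringr::str_detect(masked, stringr::regex(rules$context,
                                                  ignore_case = TRUE))) {
    return(NA_character_)
  }
  first_match(rules$weak)
}

#' Merge criterion hits into a per-document presence map
#'
#' @param hits A criterion-hit tibble from [detect_rigor_criteria()].
#' @param doc_ids Optional character vector of documents the map must cover
#'   (documents with no hits get all-`FALSE` rows). Defaults to the documents
#'   present in `hits`; with empty `hits` and no `doc_ids`, a single
#'   anonymous all-`FALSE` map is returned.
#' @return A tibble `doc_id`, `criterion`, `addressed` covering all nine
#'   criteria for every document; `addressed` is `TRUE` iff at least one hit
#'   exists (idempotent in the number of hits).
#' @export
merge_hits <- function(hits, doc_ids = NULL) {
  if (is.null(doc_ids)) doc_ids <- unique(hits$doc_id)
  if (length(doc_ids) == 0) doc_ids <- NA_character_
  grid <- tidyr::expand_grid(doc_id = doc_ids, criterion = RIGOR_CRITERIA)
  if (nrow(hits) == 0) {
    grid$addressed <- FALSE
    return(grid)
  }
  seen <- dplyr::distinct(hits, .data$doc_id, .data$criterion) |>
    dplyr::mutate(addressed = TRUE)
  grid |>
    dplyr::left_join(seen, by = c("doc_id", "criterion")) |>
    dplyr::mutate(addressed = !is.na(.data$addressed))
}

ORGANISM_SPECIES <- paste0(
  "(mice|mouse|rats|rat|zebrafish|macaques?|monkeys?|rabbits?|hamsters?|",
  "ferrets?|marmosets?|piglets?|dogs?|cats\\b|larvae)"
)
CELL_NOUNS <- "(cells?|cell lines?|monocytes|macrophages|fibroblasts|lymphocytes|myoblasts|hepatocytes|neurons)"
NAME_TOKEN <- "[A-Za-z0-9][\\w./\\-]*"

#' Detect key-resource mentions
#'
#' Finds antibody, organism, cell-line, plasmid, oligonucleotide and software
#' mentions in each sentence, populating vendor, catalog number, clone ID,
#' RRID and URL metadata when co-occurring patterns match in the same
#' sentence. RRIDs found in a sentence are attached to the first same-type
#' mention lacking one; RRIDs with no matching first-pass mention are handled
#' by [relaxed_second_pass()].
#'
#' @inheritParams detect_rigor_criteria
#' @param second_pass If `TRUE` (default) run the relaxed RRID-driven second
#'   pass per document after the pattern pass.
#' @return A mention tibble: `doc_id`, `resource_type`, `sentence_index`,
#'   `name`, `name_start` (0-based offset in the sentence), `vendor`,
#'   `catalog_number`, `clone_id`, `rrid` (normalized `AUTHORITY_ACCESSION`),
#'   `url`, `second_pass`. One mention per distinct resource name per
#'   sentence.
#' @export
detect_resources <- function(documents, lexicons = default_lexicons(),
                             second_pass = TRUE) {
  out <- purrr::map_dfr(seq_len(nrow(documents)), function(i) {
    doc <- documents[i, ]
    sents <- doc$sentences[[1]]
    m <- purrr::map_dfr(seq_len(nrow(sents)), function(j) {
      sentence_mentions(sents$text[j], doc$doc_id, sents$index[j], lexicons)
    })
    m <- ensure_mention_cols(m)
    if (second_pass) m <- relaxed_second_pass(doc, m, lexicons = lexicons)
    m
  })
  if (nrow(out) == 0) empty_mentions() else out
}

sentence_mentions <- function(text, doc_id, sentence_index, lexicons) {
  # shared per-sentence metadata, computed once
  rrids <- parse_rrids(text)
  sctx <- list(
    vendor = find_vendor(text, lexicons),
    masked = mask_spans(text, rrids),
    rrids = rrids,
    clone_id = stringr::str_match(text, "\\bclone\\s+([A-Za-z0-9.\\-]+)")[, 2],
    url = stringr::str_extract(text, "https?://[^\\s)\"]+")
  )
  found <- dplyr::bind_rows(
    find_antibodies(text, lexicons, sctx),
    find_organisms(text, lexicons, sctx),
    find_cell_lines(text, lexicons, sctx),
    find_plasmids(text, lexicons, sctx),
    find_oligos(text),
    find_software(text, lexicons, sctx)
  )
  if (nrow(found) == 0) return(empty_mentions())
  # one mention per distinct (type, name) per sentence
  found <- dplyr::distinct(found, .data$resource_type, .data$name,
                           .keep_all = TRUE)
  found$doc_id <- doc_id
  found$sentence_index <- as.integer(sentence_index)
  found$second_pass <- FALSE
  found <- attach_sentence_rrids(found, sctx$rrids)
  ensure_mention_cols(found)
}

new_found <- function(type, name, name_start, sctx,
                      with_metadata = TRUE) {
  if (length(name) == 0) return(NULL)
  n <- length(name)
  name_start <- unname(name_start)
  tibble::new_tibble(list(
    resource_type = rep(type, n),
    name = name,
    name_start = as.integer(name_start),
    vendor = rep(if (with_metadata) sctx$vendor else NA_character_, n),
    catalog_number = if (with_metadata) {
      vapply(name_start, function(s) {
        catalog_from_masked(sctx$masked, s, !is.na(sctx$vendor))
      }, character(1))
    } else rep(NA_character_, n),
    clone_id = rep(sctx$clone_id, n),
    rrid = rep(NA_character_, n),
    url = rep(sctx$url, n)
  ), nrow = n)
}

clean_name <- function(x) {
  x <- sub("[.,;:]+$", "", x)
  # drop an unbalanced trailing close-paren
  open <- stringr::str_count(x, "\\(")
  close <- stringr::str_count(x, "\\)")
  while (close > open && endsWith(x, ")")) {
    x <- sub("\\)$", "", x)
    close <- close - 1L
  }
  x
}

locate_all <- function(text, pattern, ignore_case = FALSE) {
  stringr::str_locate_all(text, stringr::regex(pattern, ignore_case = ignore_case))[[1]]
}

find_antibodies <- function(text, lexicons, sctx) {
  stop_words <- c(lexicons$name_stopwords, "monoclonal", "polyclonal",
                  "anti", "labeled", "conjugated", "control", "isotype")
  out <- NULL
  pat <- paste0("\\b(", NAME_TOKEN, ")\\s+(antibod(?:y|ies))")
  loc <- locate_all(text, pat)
  if (nrow(loc) > 0) {
    for (k in seq_len(nrow(loc))) {
      full <- substr(text, loc[k, 1], loc[k, 2])
      head_tok <- stringr::str_match(full, pat)[, 2]
      if (tolower(head_tok) %in% tolower(stop_words)) next
      out <- dplyr::bind_rows(out, new_found(
        "ANTIBODY", clean_name(full), loc[k, 1] - 1L, sctx))
    }
  }
  pat2 <- "anti-[A-Za-z0-9][\\w./\\-]*(?:\\s+[A-Za-z]*[A-Z0-9][\\w./\\-]*)?"
  loc2 <- locate_all(text, pat2)
  if (nrow(loc2) > 0) {
    for (k in seq_len(nrow(loc2))) {
      nm <- clean_name(substr(text, loc2[k, 1], loc2[k, 2]))
      # "anti-inflammatory" and kin: require an uppercase/digit in the target
      # or a second (target) token
      target <- sub("^anti-", "", nm)
      if (!grepl("[A-Z0-9]", target) && !grepl("\\s", target)) next
      out <- dplyr::bind_rows(out, new_found(
        "ANTIBODY", nm, loc2[k, 1] - 1L, sctx))
    }
  }
  out
}

find_organisms <- function(text, lexicons, sctx) {
  out <- NULL
  loc <- locate_all(text, "Tg\\([^()]*\\)[\\w\\-/]*")
  if (nrow(loc) > 0) {
    for (k in seq_len(nrow(loc))) {
      out <- dplyr::bind_rows(out, new_found(
        "ORGANISM", clean_name(substr(text, loc[k, 1], loc[k, 2])),
        loc[k, 1] - 1L, sctx))
    }
  }
  pat <- paste0("([\\w/:.\\-]+)\\s+", ORGANISM_SPECIES, "\\b")
  loc <- locate_all(text, pat, ignore_case = TRUE)
  bad_prefix <- c(lexicons$name_stopwords, "male", "female", "adult",
                  "juvenile", "old", "young", "naive", "in", "from", "for",
                  "wild", "transgenic", "mutant", "knockout", "control")
  if (nrow(loc) > 0) {
    for (k in seq_len(nrow(loc))) {
      full <- substr(text, loc[k, 1], loc[k, 2])
      m <- stringr::str_match(full, stringr::regex(pat, ignore_case = TRUE))
      prefix <- m[, 2]
      if (tolower(prefix) %in% tolower(bad_prefix) ||
          !grepl("[A-Za-z]", prefix)) next
      out <- dplyr::bind_rows(out, new_found(
        "ORGANISM", clean_name(full), loc[k, 1] - 1L, sctx))
    }
  }
  out
}

find_cell_lines <- function(text, lexicons, sctx) {
  out <- NULL
  loc <- locate_all(text, "cell lines?,?\\s+([A-Z][\\w.\\-]*)",
                    ignore_case = TRUE)
  if (nrow(loc) > 0) {
    for (k in seq_len(nrow(loc))) {
      full <- substr(text, loc[k, 1], loc[k, 2])
      nm <- stringr::str_match(full, "cell lines?,?\\s+([A-Z][\\w.\\-]*)")[, 2]
      if (is.na(nm)) next
      out <- dplyr::bind_rows(out, new_found(
        "CELL_LINE", clean_name(nm), loc[k, 2] - nchar(nm), sctx))
    }
  }
  pat <- paste0("\\b([A-Z][A-Za-z]*\\d[\\w.\\-]*)\\b",
                "(?=(?:\\s+[a-z\\-]+){0,2}\\s+", CELL_NOUNS, "\\b)")
  loc <- locate_all(text, pat)
  if (nrow(loc) > 0) {
    for (k in seq_len(nrow(loc))) {
      nm <- substr(text, loc[k, 1], loc[k, 2])
      out <- dplyr::bind_rows(out, new_found(
        "CELL_LINE", clean_name(nm), loc[k, 1] - 1L, sctx))
    }
  }
  for (line in lexicons$cell_line_registry) {
    loc <- locate_all(text, paste0("\\b", escape_regex(line), "\\b"))
    if (nrow(loc) > 0) {
      out <- dplyr::bind_rows(out, new_found(
        "CELL_LINE", line, loc[1, 1] - 1L, sctx))
    }
  }
  out
}

find_plasmids <- function(text, lexicons, sctx) {
  if (!stringr::str_detect(text, stringr::regex(
    "plasmid|vector|clon(?:e|ed|ing)|subclon|transfect|construct|addgene",
    ignore_case = TRUE))) {
    return(NULL)
  }
  loc <- locate_all(text, "\\bp[A-Z][\\w().\\-/]*")
  out <- NULL
  if (nrow(loc) > 0) {
    for (k in seq_len(nrow(loc))) {
      nm <- clean_name(substr(text, loc[k, 1], loc[k, 2]))
      if (nchar(nm) < 3) next
      out <- dplyr::bind_rows(out, new_found(
        "PLASMID", nm, loc[k, 1] - 1L, sctx))
    }
  }
  out
}

find_oligos <- function(text) {
  out <- NULL
  loc <- locate_all(text, "\\b[ACGTU]{8,}\\b")
  if (nrow(loc) > 0) {
    for (k in seq_len(nrow(loc))) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        resource_type = "OLIGO",
        name = substr(text, loc[k, 1], loc[k, 2]),
        name_start = loc[k, 1] - 1L,
        vendor = NA_character_, catalog_number = NA_character_,
        clone_id = NA_character_, rrid = NA_character_,
        url = NA_character_
      ))
    }
  }
  out
}

find_software <- function(text, lexicons, sctx) {
  out <- NULL
  seen <- character(0)
  # alternation is ordered longest-first, so "GraphPad Prism" beats "Prism"
  loc <- locate_all(text, lexicons$software_pattern)
  if (nrow(loc) > 0) {
    for (k in seq_len(nrow(loc))) {
      tool <- substr(text, loc[k, 1], loc[k, 2])
      if (tool %in% seen) next
      seen <- c(seen, tool)
      out <- dplyr::bind_rows(out, new_found(
        "SOFTWARE", tool, loc[k, 1] - 1L, sctx,
        with_metadata = FALSE))
    }
  }
  pat <- "([A-Z][\\w+.\\-]*)\\s+(?:software|simulation environment)\\b"
  loc <- locate_all(text, pat)
  if (nrow(loc) > 0) {
    for (k in seq_len(nrow(loc))) {
      nm <- stringr::str_match(substr(text, loc[k, 1], loc[k, 2]), pat)[, 2]
      if (nm %in% seen || tolower(nm) %in% lexicons$name_stopwords) next
      out <- dplyr::bind_rows(out, new_found(
        "SOFTWARE", clean_name(nm), loc[k, 1] - 1L, sctx,
        with_metadata = FALSE))
    }
  }
  out
}

attach_sentence_rrids <- function(mentions, rrids) {
  if (nrow(rrids) == 0) return(mentions)
  for (i in seq_len(nrow(rrids))) {
    norm <- rrid_string(rrids$authority[i], rrids$accession[i])
    ty <- rrid_type(rrids$authority[i])
    open <- which(mentions$resource_type == ty & is.na(mentions$rrid))
    if (length(open) > 0) mentions$rrid[open[1]] <- norm
  }
  mentions
}

#' De-duplicate resource mentions for counting
#'
#' Entity-level counting: mentions are unique per document on
#' (resource type, normalized name, catalog-number-or-RRID), so repeating the
#' same reagent string does not inflate detected counts.
#'
#' @param mentions A mention tibble.
#' @return The de-duplicated mention tibble.
#' @export
dedupe_mentions <- function(mentions) {
  if (nrow(mentions) == 0) return(mentions)
  mentions |>
    dplyr::mutate(
      .norm = tolower(stringr::str_replace_all(.data$name, "[^a-zA-Z0-9]", "")),
      .key = dplyr::coalesce(.data$catalog_number, .data$rrid, "")
    ) |>
    dplyr::distinct(.data$doc_id, .data$resource_type, .data$.norm, .data$.key,
                    .keep_all = TRUE) |>
    dplyr::select(-".norm", -".key")
}
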