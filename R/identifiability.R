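# Mapping from RRID authority prefix to the resource class it identifies.
# Stock-center authorities (IMSR, BDSC, MGI, ZFIN, ...) identify organisms;
# unknown authorities default to ORGANISM since new authorities have so far
# been organism stock centers.
RRID_AUTHORITY_TYPE <- c(
  AB = "ANTIBODY", CVCL = "CELL_LINE", SCR = "SOFTWARE",
  ADDGENE = "PLASMID", IMSR = "ORGANISM", BDSC = "ORGANISM",
  MGI = "ORGANISM", ZFIN = "ORGANISM", RGD = "ORGANISM",
  FLYBASE = "ORGANISM", WB = "ORGANISM", DGGR = "ORGANISM"
)

RRID_PATTERN <- "(?i)RRID:\\s*([A-Za-z]+)[_:]([A-Za-z0-9][A-Za-z0-9_:\\-]*)"

#' Parse Research Resource Identifiers from text
#'
#' Matches the RRID grammar: a case-insensitive `RRID:` tag, optional
#' whitespace, an alphabetic authority token, an underscore or colon, and an
#' alphanumeric accession that may itself contain colons (e.g.
#' `RRID:IMSR_JAX:000664`). Both the spaced (`RRID: AB_777714`) and unspaced
#' (`RRID:BDSC_51324`) dialects seen in print are accepted. Matches are
#' non-overlapping, left to right. Parsing is purely syntactic; no registry
#' resolution is attempted.
#'
#' @param text A string.
#' @return A tibble with columns `authority`, `accession`, `raw` (the exact
#'   matched text), and 0-based half-open offsets `start`, `end`.
#' @export
#' @examples
#' parse_rrids("(Abcam, ab37144, RRID: AB_777714)")
parse_rrids <- function(text) {
  empty <- tibble::tibble(authority = character(), accession = character(),
                          raw = character(), start = integer(),
                          end = integer())
  if (is.null(text) || is.na(text) || !nzchar(text)) return(empty)
  loc <- stringr::str_locate_all(text, RRID_PATTERN)[[1]]
  if (nrow(loc) == 0) return(empty)
  raw <- stringr::str_sub(text, loc[, 1], loc[, 2])
  parts <- stringr::str_match(raw, RRID_PATTERN)
  tibble::tibble(
    authority = parts[, 2],
    accession = parts[, 3],
    raw = raw,
    start = as.integer(loc[, 1] - 1L),
    end = as.integer(loc[, 2])
  )
}

#' Format an RRID record
#'
#' `format_rrid()` renders the canonical `RRID:AUTHORITY_ACCESSION` form;
#' re-parsing it yields an equal (authority, accession) record. `rrid_string()`
#' gives the normalized `AUTHORITY_ACCESSION` used in CSV reports.
#'
#' @param authority,accession Character vectors.
#' @return Character vector.
#' @export
format_rrid <- function(authority, accession) {
  paste0("RRID:", authority, "_", accession)
}

#' @rdname format_rrid
#' @export
rrid_string <- function(authority, accession) {
  paste0(authority, "_", accession)
}

rrid_type <- function(authority) {
  ty <- RRID_AUTHORITY_TYPE[toupper(authority)]
  ifelse(is.na(ty), "ORGANISM", unname(ty))
}

# Catalog-number patterns, in priority order. Cue-anchored patterns first
# ("#62988", "ab37144", "number TIB-67", "Cat. No. X"); a bare vendor-code
# shape is only accepted when a vendor name occurs in the sentence.
CATALOG_PATTERNS <- c(
  "#\\s*([A-Za-z0-9][A-Za-z0-9\\-]*)",
  "\\b(ab\\d{4,})\\b",
  "(?i)(?:cat(?:alog(?:ue)?)?\\.?\\s*(?:no\\.?|number|#)?|\\bno\\.|\\bnumber)\\s*[:#]?\\s*((?:[A-Za-z]+-?)?\\d[A-Za-z0-9\\-]*)"
)
CATALOG_VENDOR_CODE <- "\\b([A-Z]{1,5}-\\d{2,}[A-Za-z0-9\\-]*)\\b"

#' Extract a catalog number near a resource name
#'
#' Searches a sentence for the nearest catalog-like token following the
#' resource-name anchor (falling back to the whole sentence). Recognized
#' shapes: `#62988`, Abcam-style `ab37144`, cue-anchored codes
#' (`number TIB-67`, `Cat. No. X`), and — only when a vendor name is present
#' in the sentence — bare vendor codes such as `CRL-1573`. RRID spans are
#' masked first so an accession is never mistaken for a catalog number.
#'
#' @param sentence Sentence text.
#' @param anchor_start 0-based offset of the resource name within the
#'   sentence; search prefers material at or after this point.
#' @param lexicons Lexicon list (for the vendor list).
#' @return A string, or `NA_character_` when no catalog-like token is found.
#' @export
#' @examples
#' extract_catalog_number("(Addgene plasmid #62988; RRID: Addgene_62988)", 0)
#' extract_catalog_number("(ATCC, number TIB-67)", 0)
#' extract_catalog_number("(Santa Cruz Biotechnology)", 0)
extract_catalog_number <- function(sentence, anchor_start = 0L,
                                   lexicons = default_lexicons()) {
  if (is.null(sentence) || is.na(sentence) || !nzchar(sentence)) {
    return(NA_character_)
  }
  masked <- mask_spans(sentence, parse_rrids(sentence))
  has_vendor <- !is.na(find_vendor(sentence, lexicons))
  catalog_from_masked(masked, anchor_start, has_vendor)
}

catalog_from_masked <- function(masked, anchor_start, has_vendor) {
  pats <- CATALOG_PATTERNS
  if (has_vendor) pats <- c(pats, CATALOG_VENDOR_CODE)
  regions <- unique(c(substr(masked, anchor_start + 1L, nchar(masked)), masked))
  for (region in regions) {
    for (pat in pats) {
      m <- stringr::str_match(region, pat)
      if (!is.na(m[1, 2])) return(m[1, 2])
    }
  }
  NA_character_
}

# Replace character spans (tibble with 0-based start/end) with spaces,
# preserving offsets.
mask_spans <- function(text, spans) {
  if (nrow(spans) == 0) return(text)
  chars <- strsplit(text, "")[[1]]
  for (i in seq_len(nrow(spans))) {
    idx <- seq.int(spans$start[i] + 1L, spans$end[i])
    chars[idx] <- " "
  }
  paste(chars, collapse = "")
}

find_vendor <- function(sentence, lexicons = default_lexicons()) {
  # single pre-compiled alternation, longest names first, so e.g.
  # "Santa Cruz Biotechnology" wins over any shorter vendor substring
  hit <- stringr::str_extract(
    sentence, stringr::regex(lexicons$vendor_pattern, ignore_case = TRUE))
  if (is.na(hit)) return(NA_character_)
  canon <- lexicons$vendors[tolower(lexicons$vendors) == tolower(hit)]
  if (length(canon) > 0) canon[1] else hit
}

escape_regex <- function(x) {
  stringr::str_replace_all(x, "([.\\\\+*?\\[^\\]$(){}=!<>|:#&-])", "\\\\\\1")
}

#' Decide whether a resource mention is uniquely identifiable
#'
#' Applies the per-type identifiability rules: an antibody is identifiable
#' with a catalog number or an RRID (optionally also vendor + clone ID, off by
#' default); organisms, cell lines and plasmids need an RRID or both vendor
#' and catalog number; a software tool needs an RRID, a URL, or a name in the
#' known-tool registry; oligonucleotides are always treated as identifiable
#' for reporting but never enter the score.
#'
#' @param mentions A resource-mention tibble (see [detect_resources()]).
#' @param lexicons Lexicon list (for the software registry).
#' @param clone_with_vendor If `TRUE`, a clone ID together with a vendor also
#'   identifies an antibody (the laxer reading; default is the stricter
#'   catalog/RRID rule).
#' @return For `annotate_identifiability()`, the mentions tibble with a
#'   logical `identifiable` column; `is_identifiable()` returns the logical
#'   vector itself.
#' @export
#' @examples
#' m <- tibble::tibble(resource_type = "ANTIBODY", name = "ATF3 antibody",
#'                     vendor = "Santa Cruz Biotechnology",
#'                     catalog_number = NA, clone_id = NA, rrid = NA, url = NA)
#' is_identifiable(m)
is_identifiable <- function(mentions, lexicons = default_lexicons(),
                            clone_with_vendor = FALSE) {
  if (nrow(mentions) == 0) return(logical(0))
  registry <- lexicons$software_registry
  has <- function(x) !is.na(x) & nzchar(as.character(x))
  type <- mentions$resource_type
  rrid_ok <- has(mentions$rrid)
  cat_ok <- has(mentions$catalog_number)
  ven_ok <- has(mentions$vendor)
  url_ok <- if ("url" %in% names(mentions)) has(mentions$url) else rep(FALSE, nrow(mentions))
  clone_ok <- if ("clone_id" %in% names(mentions)) has(mentions$clone_id) else rep(FALSE, nrow(mentions))
  in_registry <- mentions$name %in% registry

  out <- rep(FALSE, nrow(mentions))
  ab <- type == "ANTIBODY"
  out[ab] <- rrid_ok[ab] | cat_ok[ab] |
    (clone_with_vendor & clone_ok[ab] & ven_ok[ab])
  vc <- type %in% c("ORGANISM", "CELL_LINE", "PLASMID")
  out[vc] <- rrid_ok[vc] | (ven_ok[vc] & cat_ok[vc])
  sw <- type == "SOFTWARE"
  out[sw] <- rrid_ok[sw] | url_ok[sw] | in_registry[sw]
  out[type == "OLIGO"] <- TRUE
  out
}

#' @rdname is_identifiable
#' @export
annotate_identifiability <- function(mentions, lexicons = default_lexicons(),
                                     clone_with_vendor = FALSE) {
  mentions$identifiable <- is_identifiable(mentions, lexicons,
                                           clone_with_vendor)
  mentions
}

#' Relaxed second pass driven by detected RRIDs
#'
#' An RRID found by the grammar is certain evidence that a key resource is
#' being described, so any RRID not already carried by a first-pass mention
#' either augments an existing same-sentence mention of the matching type or
#' creates a new mention. The new mention is named after the nearest
#' preceding resource-like token in the sentence (falling back to the
#' canonical RRID string), typed by the RRID authority, and flagged
#' `second_pass = TRUE`. The pass never removes a mention and never lowers
#' identifiability; afterwards every RRID in the document is carried by
#' exactly one mention.
#'
#' @param document A one-row document tibble.
#' @param mentions First-pass mentions for that document.
#' @param rrids Optional pre-parsed RRID tibble for the document's
#'   `methods_text` (computed when `NULL`).
#' @param lexicons Lexicon list.
#' @return The augmented mentions tibble.
#' @export
relaxed_second_pass <- function(document, mentions, rrids = NULL,
                                lexicons = default_lexicons()) {
  stopifnot(nrow(document) == 1)
  if (is.null(rrids)) rrids <- parse_rrids(document$methods_text)
  if (nrow(rrids) == 0) return(mentions)
  sents <- document$sentences[[1]]
  mentions <- ensure_mention_cols(mentions)

  for (i in seq_len(nrow(rrids))) {
    norm <- rrid_string(rrids$authority[i], rrids$accession[i])
    if (any(!is.na(mentions$rrid) & mentions$rrid == norm)) next
    s_row <- which(sents$start <= rrids$start[i] & sents$end >= rrids$end[i])
    s_idx <- if (length(s_row)) sents$index[s_row[1]] else NA_integer_
    ty <- rrid_type(rrids$authority[i])
    open <- which(mentions$sentence_index == s_idx &
                    mentions$resource_type == ty & is.na(mentions$rrid))
    if (!is.na(s_idx) && length(open) > 0) {
      mentions$rrid[open[1]] <- norm
      mentions$second_pass[open[1]] <- TRUE
      next
    }
    sent_text <- if (length(s_row)) sents$text[s_row[1]] else document$methods_text
    local_start <- if (length(s_row)) rrids$start[i] - sents$start[s_row[1]] else rrids$start[i]
    nm <- preceding_resource_name(sent_text, local_start, lexicons)
    if (is.na(nm)) nm <- format_rrid(rrids$authority[i], rrids$accession[i])
    mentions <- dplyr::bind_rows(mentions, tibble::tibble(
      doc_id = document$doc_id,
      resource_type = ty,
      sentence_index = s_idx,
      name = nm,
      name_start = NA_integer_,
      vendor = find_vendor(sent_text, lexicons),
      catalog_number = NA_character_,
      clone_id = NA_character_,
      rrid = norm,
      url = NA_character_,
      second_pass = TRUE
    ))
  }
  mentions
}

# Nearest preceding resource-like token before a (0-based) offset: scan
# backwards over whitespace tokens, skipping punctuation-only and
# digit/catalog tokens, generic cue words, and vendor names; extend left over
# capitalized tokens that are not themselves clause-final.
preceding_resource_name <- function(sentence, offset, lexicons = default_lexicons()) {
  before <- substr(sentence, 1L, offset)
  before <- sub("[\\s(,;:]*(RRID[:\\s]*)?$", "", before, perl = TRUE, ignore.case = TRUE)
  toks <- strsplit(before, "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) return(NA_character_)
  cues <- c("plasmid", "antibody", "antibodies", "rrid", "cat", "cat.",
            "catalog", "no", "no.", "number", "from", "a", "an", "the",
            "gift", "was", "were", "which", "and", "or", "with", "using",
            "in", "into", "by", "of", "for", "to")
  vendors <- tolower(lexicons$vendors)
  strip <- function(x) gsub("^[^A-Za-z0-9#]+|[^A-Za-z0-9)]+$", "", x)
  i <- length(toks)
  while (i >= 1) {
    tok <- strip(toks[i])
    low <- tolower(tok)
    skip <- !nzchar(tok) || !grepl("[A-Za-z]", tok) ||
      startsWith(tok, "#") || low %in% cues || low %in% vendors
    if (!skip) break
    i <- i - 1L
  }
  if (i < 1) return(NA_character_)
  name <- strip(toks[i])
  j <- i - 1L
  while (j >= 1 && grepl("^[A-Z0-9]", toks[j]) &&
         !grepl("[.,;:)]$", toks[j]) &&
         !(tolower(strip(toks[j])) %in% c(cues, vendors)) && (i - j) < 3L) {
    name <- paste(strip(toks[j]), name)
    j <- j - 1L
  }
  if (!nzchar(name)) NA_character_ else name
}

ensure_mention_cols <- function(mentions) {
  template <- empty_mentions()
  for (col in names(template)) {
    if (!col %in% names(mentions)) {
      mentions[[col]] <- template[[col]][rep(NA_integer_, nrow(mentions))]
      if (col == "second_pass") mentions[[col]] <- rep(FALSE, nrow(mentions))
    }
  }
  mentions[, names(template)]
}

empty_mentions <- function() {
  tibble::tibble(
    doc_id = character(), resource_type = character(),
    sentence_index = integer(), name = character(),
    name_start = integer(), vendor = character(),
    catalog_number = character(), clone_id = character(),
    rrid = character(), url = character(), second_pass = logical()
  )
}
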