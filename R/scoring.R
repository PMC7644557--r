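#' Scoring configuration
#'
#' @param ethics_mode `"merged"` (default): IRB/consent statements and IACUC
#'   statements jointly form one ethics block satisfied by any of the three,
#'   so a purely human or purely animal study is not penalized for the other
#'   approval type. `"strict"`: human ethics (IRB or consent) and IACUC are
#'   separate blocks.
#' @param rounding If `TRUE`, the total is rounded half-up to an integer
#'   (scores are kept continuous by default).
#' @param block_weights Optional named numeric vector of per-block weights;
#'   equal weights by default (the published score defines only the 5-point
#'   section caps, not a per-block split).
#' @param type_weights Optional named numeric vector over the scoreable
#'   resource types; equal by default.
#' @param clone_with_vendor Passed to [is_identifiable()].
#' @return A list of class `"rtindex_config"`.
#' @export
score_config <- function(ethics_mode = c("merged", "strict"),
                         rounding = FALSE, block_weights = NULL,
                         type_weights = NULL, clone_with_vendor = FALSE) {
  structure(
    list(ethics_mode = match.arg(ethics_mode), rounding = isTRUE(rounding),
         block_weights = block_weights, type_weights = type_weights,
         clone_with_vendor = isTRUE(clone_with_vendor)),
    class = "rtindex_config"
  )
}

score_blocks <- function(ethics_mode) {
  if (ethics_mode == "merged") {
    list(
      ETHICS = c("IRB", "CONSENT", "IACUC"),
      RANDOMIZATION = "RANDOMIZATION",
      BLINDING = "BLINDING",
      POWER = "POWER",
      SEX = "SEX",
      CELL_AUTH = c("CELL_AUTH", "CELL_CONTAM")
    )
  } else {
    list(
      ETHICS_HUMAN = c("IRB", "CONSENT"),
      IACUC = "IACUC",
      RANDOMIZATION = "RANDOMIZATION",
      BLINDING = "BLINDING",
      POWER = "POWER",
      SEX = "SEX",
      CELL_AUTH = c("CELL_AUTH", "CELL_CONTAM")
    )
  }
}

#' Score one paper on the 0-10 composite scale
#'
#' Rigor criteria carry 5 points: the nine criteria collapse into blocks
#' (ethics; randomization; blinding; power; sex; cell-line
#' authentication/contamination, which is applicable only when a cell line is
#' detected), and the rigor component is 5 x (weighted addressed applicable
#' blocks / weighted applicable blocks). Key resources carry the other 5
#' points: over the detected scoreable types (antibody, organism, cell line,
#' software) the component is 5 x the (weighted) mean per-type fraction of
#' identifiable mentions, and 0 when no scoreable resource is detected.
#' Plasmids are recorded but unscored; oligonucleotides never affect the
#' score. A paper with no criteria and no mentions is not applicable and
#' scores 0.
#'
#' @param presence_map A tibble `criterion`/`addressed` (or named logical
#'   vector) over the nine criteria, as from [merge_hits()] for one document.
#' @param mentions Mention tibble for the same document, de-duplicated with
#'   [dedupe_mentions()]; an `identifiable` column is honored and computed
#'   via [is_identifiable()] when absent.
#' @param config A [score_config()].
#' @param lexicons Lexicon list (used only if identifiability must be
#'   computed).
#' @return A `paper_score` object: fields `rigor_points`, `resource_points`,
#'   `total`, `applicable`, a `blocks` tibble (block, applicable, addressed,
#'   weight) and a `resource_counts` tibble (resource_type, detected,
#'   identifiable, scoreable). [tidy()] returns the blocks, [glance()] the
#'   one-row summary.
#' @export
score_paper <- function(presence_map, mentions = empty_mentions(),
                        config = score_config(),
                        lexicons = default_lexicons()) {
  presence <- as_presence_vector(presence_map)
  mentions <- ensure_mention_cols2(mentions)
  if (!"identifiable" %in% names(mentions)) {
    mentions <- annotate_identifiability(mentions, lexicons,
                                         config$clone_with_vendor)
  }

  counts <- mentions |>
    dplyr::count(.data$resource_type, wt = NULL, name = "detected") |>
    dplyr::left_join(
      mentions |>
        dplyr::filter(.data$identifiable) |>
        dplyr::count(.data$resource_type, name = "identifiable"),
      by = "resource_type"
    ) |>
    dplyr::mutate(identifiable = dplyr::coalesce(.data$identifiable, 0L))
  counts <- tibble::tibble(resource_type = RESOURCE_TYPES) |>
    dplyr::left_join(counts, by = "resource_type") |>
    dplyr::mutate(
      detected = dplyr::coalesce(.data$detected, 0L),
      identifiable = dplyr::coalesce(.data$identifiable, 0L),
      scoreable = .data$resource_type %in% SCOREABLE_TYPES
    )
  if (any(counts$identifiable > counts$detected)) {
    abort_rtindex("identifiable count exceeds detected count", "count_invariant")
  }

  has_cell_line <- counts$detected[counts$resource_type == "CELL_LINE"] > 0
  blocks_def <- score_blocks(config$ethics_mode)
  blocks <- tibble::tibble(
    block = names(blocks_def),
    applicable = ifelse(names(blocks_def) == "CELL_AUTH", has_cell_line, TRUE),
    addressed = vapply(blocks_def, function(cr) any(presence[cr]), logical(1))
  )
  w <- rep(1, nrow(blocks))
  if (!is.null(config$block_weights)) {
    w <- unname(config$block_weights[blocks$block])
    if (anyNA(w)) abort_rtindex("block_weights must name every block", "weights")
  }
  blocks$weight <- w

  applicable_w <- sum(w[blocks$applicable])
  rigor_points <- if (applicable_w > 0) {
    5 * sum(w[blocks$applicable & blocks$addressed]) / applicable_w
  } else 0

  sc <- counts[counts$scoreable & counts$detected > 0, ]
  if (nrow(sc) > 0) {
    tw <- rep(1, nrow(sc))
    if (!is.null(config$type_weights)) {
      tw <- unname(config$type_weights[sc$resource_type])
      if (anyNA(tw)) abort_rtindex("type_weights must cover detected types", "weights")
    }
    ratios <- sc$identifiable / sc$detected
    resource_points <- 5 * sum(tw * ratios) / sum(tw)
  } else {
    resource_points <- 0
  }

  applicable <- any(presence) || any(counts$detected > 0)
  if (!applicable) {
    rigor_points <- 0
    resource_points <- 0
  }
  total <- rigor_points + resource_points
  if (config$rounding) total <- round_half_up(total)

  structure(
    list(rigor_points = rigor_points, resource_points = resource_points,
         total = total, applicable = applicable, blocks = blocks,
         resource_counts = counts[, c("resource_type", "detected",
                                      "identifiable", "scoreable")]),
    class = "paper_score"
  )
}

as_presence_vector <- function(presence_map) {
  presence <- stats::setNames(rep(FALSE, length(RIGOR_CRITERIA)),
                              RIGOR_CRITERIA)
  if (is.data.frame(presence_map)) {
    if (nrow(presence_map) > 0) {
      ok <- presence_map$criterion %in% RIGOR_CRITERIA
      presence[presence_map$criterion[ok]] <- presence_map$addressed[ok]
    }
  } else if (length(presence_map) > 0) {
    nm <- intersect(names(presence_map), RIGOR_CRITERIA)
    presence[nm] <- as.logical(presence_map[nm])
  }
  presence
}

ensure_mention_cols2 <- function(mentions) {
  keep_id <- "identifiable" %in% names(mentions)
  idf <- if (keep_id) mentions$identifiable else NULL
  out <- ensure_mention_cols(mentions)
  if (keep_id) out$identifiable <- idf
  out
}

#' @export
print.paper_score <- function(x, ...) {
  cat(sprintf("<paper_score> total %.2f (rigor %.2f + resources %.2f)%s\n",
              x$total, x$rigor_points, x$resource_points,
              if (x$applicable) "" else " [not applicable]"))
  invisible(x)
}

#' @method tidy paper_score
#' @export
tidy.paper_score <- function(x, ...) {
  x$blocks
}

#' @method glance paper_score
#' @export
glance.paper_score <- function(x, ...) {
  tibble::tibble(rigor_points = x$rigor_points,
                 resource_points = x$resource_points,
                 total = x$total, applicable = x$applicable)
}

#' Score every document in a corpus
#'
#' Runs the full pipeline — criterion detection, resource detection with the
#' relaxed RRID second pass, identifiability annotation, entity
#' de-duplication, and composite scoring — and returns one row per document.
#'
#' @param documents A document tibble.
#' @param config A [score_config()].
#' @param lexicons Lexicon list.
#' @return A tibble with document metadata, `rigor_points`,
#'   `resource_points`, `total`, `applicable`, per-criterion logical columns
#'   `crit_<CRITERION>`, and per-type counts `det_<TYPE>` / `idf_<TYPE>`.
#' @export
#' @examples
#' docs <- new_document("d1", "J", "", 2019,
#'   "Animals were assigned to groups using simple randomization.")
#' score_corpus(docs)
score_corpus <- function(documents, config = score_config(),
                         lexicons = default_lexicons()) {
  hits <- detect_rigor_criteria(documents, lexicons)
  mentions <- detect_resources(documents, lexicons, second_pass = TRUE)
  mentions <- annotate_identifiability(dedupe_mentions(mentions), lexicons,
                                       config$clone_with_vendor)
  presence <- merge_hits(hits, doc_ids = documents$doc_id)

  purrr::map_dfr(seq_len(nrow(documents)), function(i) {
    id <- documents$doc_id[i]
    pres_i <- presence[presence$doc_id == id, ]
    men_i <- mentions[mentions$doc_id == id, ]
    ps <- score_paper(pres_i, men_i, config, lexicons)
    pres_v <- as_presence_vector(pres_i)
    cnt <- ps$resource_counts
    row <- tibble::tibble(
      doc_id = id, journal = documents$journal[i], issn = documents$issn[i],
      year = documents$year[i], methods_found = documents$methods_found[i],
      rigor_points = ps$rigor_points, resource_points = ps$resource_points,
      total = ps$total, applicable = ps$applicable
    )
    for (cr in RIGOR_CRITERIA) row[[paste0("crit_", cr)]] <- unname(pres_v[cr])
    for (ty in RESOURCE_TYPES) {
      row[[paste0("det_", ty)]] <- cnt$detected[cnt$resource_type == ty]
      row[[paste0("idf_", ty)]] <- cnt$identifiable[cnt$resource_type == ty]
    }
    row
  })
}

#' Score rate
#'
#' Percentage of analyzed papers that received a non-zero score, reported to
#' one decimal place.
#'
#' @param n_scored Number of scored (non-zero) papers.
#' @param n_total Number of papers analyzed; must be positive and at least
#'   `n_scored`.
#' @return The percentage, rounded half-up to one decimal.
#' @export
#' @examples
#' score_rate(1381072, 1578964) # 87.5
score_rate <- function(n_scored, n_total) {
  if (any(n_total <= 0)) abort_rtindex("n_total must be positive", "score_rate")
  if (any(n_scored < 0 | n_scored > n_total)) {
    abort_rtindex("need 0 <= n_scored <= n_total", "score_rate")
  }
  round_half_up(100 * n_scored / n_total, 1)
}
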