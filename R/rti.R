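#' Aggregate paper scores into journal-year summaries
#'
#' The Rigor and Transparency Index (RTI) of a journal in a given year is the
#' mean composite score of its scored papers. Papers that scored 0 (no
#' criteria, no resources: "not applicable") are excluded from the mean and
#' the rates but reported as `n_zero` for transparency. Journal-years with
#' fewer than `min_n` scored papers are suppressed.
#'
#' @param scores A per-paper score tibble from [score_corpus()].
#' @param min_n Minimum number of scored papers for a summary to be emitted.
#' @return A tibble with one row per (journal, issn, year): `n_scored`,
#'   `n_zero`, `rti`, `sd`, per-criterion adherence rates `rate_<CRITERION>`
#'   (fraction of scored papers addressing it), and per-type identifiability
#'   columns `det_<TYPE>`, `idf_<TYPE>`, `rate_<TYPE>`.
#' @export
aggregate_journal_year <- function(scores, min_n = 10) {
  grouped <- scores |>
    dplyr::group_by(.data$journal, .data$issn, .data$year)
  zeros <- grouped |>
    dplyr::summarise(n_zero = sum(.data$total == 0), .groups = "drop")
  scored <- scores |> dplyr::filter(.data$total > 0)
  if (nrow(scored) == 0) {
    return(scored_summary_prototype())
  }
  out <- scored |>
    dplyr::group_by(.data$journal, .data$issn, .data$year) |>
    dplyr::summarise(
      n_scored = dplyr::n(),
      rti = mean(.data$total),
      sd = stats::sd(.data$total),
      dplyr::across(dplyr::starts_with("crit_"), ~ mean(.x)),
      dplyr::across(dplyr::starts_with("det_"), ~ sum(.x)),
      dplyr::across(dplyr::starts_with("idf_"), ~ sum(.x)),
      .groups = "drop"
    ) |>
    dplyr::rename_with(~ sub("^crit_", "rate_", .x),
                       dplyr::starts_with("crit_")) |>
    dplyr::left_join(zeros, by = c("journal", "issn", "year")) |>
    dplyr::filter(.data$n_scored >= min_n)
  for (ty in RESOURCE_TYPES) {
    det <- out[[paste0("det_", ty)]]
    idf <- out[[paste0("idf_", ty)]]
    out[[paste0("rate_", ty)]] <- ifelse(det > 0, idf / det, NA_real_)
  }
  dplyr::relocate(out, "n_zero", .after = "n_scored")
}

scored_summary_prototype <- function() {
  out <- tibble::tibble(journal = character(), issn = character(),
                        year = integer(), n_scored = integer(),
                        n_zero = integer(), rti = double(), sd = double())
  for (cr in RIGOR_CRITERIA) out[[paste0("rate_", cr)]] <- double()
  for (ty in RESOURCE_TYPES) {
    out[[paste0("det_", ty)]] <- integer()
    out[[paste0("idf_", ty)]] <- integer()
    out[[paste0("rate_", ty)]] <- double()
  }
  out
}

#' Identifiability rate for league tables
#'
#' @param detected Number of detected resources (must be positive).
#' @param identifiable Number of those that are uniquely identifiable.
#' @return `100 * identifiable / detected`, rounded half-up to the nearest
#'   integer. `detected == 0` is undefined and signalled as a
#'   `"rtindex_no_denominator"` warning, returning `NA`.
#' @export
#' @examples
#' identifiability_rate(242, 236) # 98
#' identifiability_rate(2476, 2218) # 90
identifiability_rate <- function(detected, identifiable) {
  if (any(identifiable > detected) || any(identifiable < 0)) {
    abort_rtindex("need 0 <= identifiable <= detected", "rate_bounds")
  }
  out <- rep(NA_real_, length(detected))
  if (any(detected == 0)) {
    rlang::warn("identifiability rate undefined at detected == 0",
                class = "rtindex_no_denominator")
  }
  ok <- detected > 0
  out[ok] <- round_half_up(100 * identifiable[ok] / detected[ok])
  out
}

#' Cell-line authentication rate
#'
#' Percent of papers containing an authentication or contamination statement
#' among papers in which at least one cell line was found.
#'
#' @param papers_with_cell_lines Denominator (must be positive).
#' @param papers_with_auth_or_contam Numerator.
#' @return The percentage (not rounded).
#' @export
authentication_rate <- function(papers_with_cell_lines,
                                papers_with_auth_or_contam) {
  if (any(papers_with_cell_lines == 0)) {
    rlang::warn("authentication rate undefined with no cell-line papers",
                class = "rtindex_no_denominator")
  }
  ifelse(papers_with_cell_lines > 0,
         100 * papers_with_auth_or_contam / papers_with_cell_lines,
         NA_real_)
}

#' Restrict to the vertebrate-animal subset
#'
#' Retains exactly the documents with at least one IACUC hit, a proxy for
#' vertebrate-animal studies where the rigor criteria are most relevant.
#'
#' @param scores Per-paper score tibble from [score_corpus()].
#' @param hits Optional criterion-hit tibble; when supplied, membership is
#'   taken from IACUC hits there instead of the `crit_IACUC` column.
#' @return The filtered score tibble.
#' @export
vertebrate_subset <- function(scores, hits = NULL) {
  if (!is.null(hits)) {
    ids <- unique(hits$doc_id[hits$criterion == "IACUC"])
    return(dplyr::filter(scores, .data$doc_id %in% ids))
  }
  dplyr::filter(scores, .data$crit_IACUC)
}

new_correlation <- function(method, n, coefficient) {
  structure(list(method = method, n = as.integer(n),
                 coefficient = coefficient),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s, n = %d, coefficient = %.6f\n",
              x$method, x$n, x$coefficient))
  invisible(x)
}

#' @method tidy correlation_result
#' @export
tidy.correlation_result <- function(x, ...) {
  tibble::tibble(method = x$method, n = x$n, estimate = x$coefficient)
}

#' @method glance correlation_result
#' @export
glance.correlation_result <- function(x, ...) {
  tidy(x)
}

check_cor_input <- function(x, y) {
  if (length(x) != length(y)) abort_rtindex("x and y must have equal length",
                                            "cor_length")
  if (length(x) < 2) abort_rtindex("need at least 2 observations", "cor_n")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort_rtindex("x and y must be finite", "cor_finite")
  }
}

#' Spearman rank-order correlation
#'
#' Pearson correlation of average-ranked values; with no ties this equals
#' `1 - 6 * sum(d^2) / (n (n^2 - 1))`. Zero rank variance in either argument
#' is undefined and signalled, returning an `NA` coefficient.
#'
#' @param x,y Equal-length finite numeric vectors, n >= 2.
#' @return A `correlation_result` (fields `method`, `n`, `coefficient`) with
#'   [tidy()]/[glance()] methods.
#' @export
#' @examples
#' rti_spearman(c(1, 2, 3, 4), c(2, 1, 4, 3)) # 0.6
rti_spearman <- function(x, y) {
  check_cor_input(x, y)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    rlang::warn("zero rank variance: Spearman correlation undefined",
                class = "rtindex_degenerate")
    return(new_correlation("spearman", length(x), NA_real_))
  }
  new_correlation("spearman", length(x), stats::cor(rx, ry))
}

#' Pearson product-moment correlation
#'
#' @inheritParams rti_spearman
#' @return A `correlation_result`.
#' @export
rti_pearson <- function(x, y) {
  check_cor_input(x, y)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    rlang::warn("zero variance: Pearson correlation undefined",
                class = "rtindex_degenerate")
    return(new_correlation("pearson", length(x), NA_real_))
  }
  new_correlation("pearson", length(x), stats::cor(x, y))
}

#' Percentile ranks and quartile labels
#'
#' Percentile is `100 * rank / n` with average ranks for ties, so the highest
#' value gets the highest percentile. Quartile labels follow the league-table
#' convention that the top quartile is Q1.
#'
#' @param values Numeric vector, n >= 1, finite.
#' @return A tibble `value`, `percentile`, `quartile` (factor Q1..Q4).
#' @export
#' @examples
#' percentile_ranks(c(1, 2, 3, 4))
percentile_ranks <- function(values) {
  if (length(values) < 1 || !all(is.finite(values))) {
    abort_rtindex("values must be finite and non-empty", "percentiles")
  }
  pct <- 100 * rank(values, ties.method = "average") / length(values)
  quart <- cut(pct, breaks = c(-Inf, 25, 50, 75, Inf),
               labels = c("Q4", "Q3", "Q2", "Q1"))
  quart <- factor(as.character(quart), levels = c("Q1", "Q2", "Q3", "Q4"))
  tibble::tibble(value = values, percentile = pct, quartile = quart)
}

#' Corpus-wide yearly trend table
#'
#' Per-year mean and standard deviation of the composite score over scored
#' (non-zero) papers, plus per-year criterion-adherence and resource
#' identifiability rates. Years with no scored papers are dropped.
#'
#' @param scores Per-paper score tibble from [score_corpus()].
#' @return A tibble with one row per year, of class `rti_trend` (for
#'   [ggplot2::autoplot()]).
#' @export
trend_table <- function(scores) {
  scored <- dplyr::filter(scores, .data$total > 0)
  zeros <- scores |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(n_zero = sum(.data$total == 0), .groups = "drop")
  out <- scored |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      n_scored = dplyr::n(),
      mean_score = mean(.data$total),
      sd_score = stats::sd(.data$total),
      dplyr::across(dplyr::starts_with("crit_"), ~ mean(.x)),
      dplyr::across(dplyr::starts_with("det_"), ~ sum(.x)),
      dplyr::across(dplyr::starts_with("idf_"), ~ sum(.x)),
      .groups = "drop"
    ) |>
    dplyr::rename_with(~ sub("^crit_", "rate_", .x),
                       dplyr::starts_with("crit_")) |>
    dplyr::left_join(zeros, by = "year") |>
    dplyr::arrange(.data$year)
  for (ty in RESOURCE_TYPES) {
    det <- out[[paste0("det_", ty)]]
    idf <- out[[paste0("idf_", ty)]]
    out[[paste0("rate_", ty)]] <- ifelse(det > 0, idf / det, NA_real_)
  }
  class(out) <- c("rti_trend", class(out))
  out
}

#' Compare journal RTI against impact factors
#'
#' Computes per-journal RTI over the scoring window preceding the impact
#' factor year (by default years `jif_year - 2` and `jif_year - 1`, so a 2018
#' impact factor is compared with scores of 2016-2017 papers), joins on ISSN
#' when both sides have one (falling back to exact journal name), and reports
#' Spearman rank correlations for the raw values and for their percentile
#' ranks.
#'
#' @param scores Per-paper score tibble from [score_corpus()].
#' @param if_table Impact-factor tibble from [read_if_table()].
#' @param jif_year The impact-factor year to compare against.
#' @param window Integer vector of offsets (years before `jif_year`) whose
#'   papers enter the RTI; default `c(2, 1)`.
#' @param min_n Minimum scored papers per journal in the window.
#' @return A list of class `rti_jif_comparison`: `data` (journal, issn, n,
#'   rti, jif, rti_percentile, jif_percentile), `spearman_raw`,
#'   `spearman_percentile` (both `correlation_result`).
#' @export
compare_with_jif <- function(scores, if_table, jif_year, window = c(2, 1),
                             min_n = 10) {
  years <- jif_year - window
  rti <- scores |>
    dplyr::filter(.data$year %in% years, .data$total > 0) |>
    dplyr::group_by(.data$journal, .data$issn) |>
    dplyr::summarise(n = dplyr::n(), rti = mean(.data$total),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= min_n)
  jif <- dplyr::filter(if_table, .data$year == jif_year)

  by_issn <- rti |>
    dplyr::filter(nzchar(.data$issn)) |>
    dplyr::inner_join(dplyr::filter(jif, nzchar(.data$issn)) |>
                        dplyr::select("issn", "jif"),
                      by = "issn")
  rest <- rti |> dplyr::anti_join(by_issn, by = c("journal", "issn"))
  by_name <- rest |>
    dplyr::inner_join(dplyr::select(jif, "journal", "jif"), by = "journal")
  joined <- dplyr::bind_rows(by_issn, by_name)

  if (nrow(joined) < 2) {
    abort_rtindex("fewer than 2 journals matched between RTI and JIF tables",
                  "jif_join")
  }
  joined$rti_percentile <- percentile_ranks(joined$rti)$percentile
  joined$jif_percentile <- percentile_ranks(joined$jif)$percentile

  structure(
    list(
      data = joined,
      spearman_raw = rti_spearman(joined$rti, joined$jif),
      spearman_percentile = rti_spearman(joined$rti_percentile,
                                         joined$jif_percentile)
    ),
    class = "rti_jif_comparison"
  )
}

#' @export
print.rti_jif_comparison <- function(x, ...) {
  cat(sprintf(
    "<rti_jif_comparison> %d journals; Spearman raw %.4f, percentile %.4f\n",
    nrow(x$data), x$spearman_raw$coefficient,
    x$spearman_percentile$coefficient))
  invisible(x)
}

#' @method tidy rti_jif_comparison
#' @export
tidy.rti_jif_comparison <- function(x, ...) {
  dplyr::bind_rows(
    tidy(x$spearman_raw) |> dplyr::mutate(comparison = "raw"),
    tidy(x$spearman_percentile) |> dplyr::mutate(comparison = "percentile")
  )
}
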