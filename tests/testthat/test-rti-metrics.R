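# independent first-principles implementations used as oracles
brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}
brute_rank <- function(x) {
  # average ranks by explicit counting
  vapply(seq_along(x), function(i) {
    less <- sum(x < x[i])
    ties <- sum(x == x[i])
    less + (ties + 1) / 2
  }, numeric(1))
}
brute_spearman <- function(x, y) brute_pearson(brute_rank(x), brute_rank(y))

fake_scores <- function(journal, year, totals, issn = "1111-1111") {
  n <- length(totals)
  out <- tibble::tibble(
    doc_id = paste0(journal, year, "_", seq_len(n)),
    journal = journal, issn = issn, year = as.integer(year),
    methods_found = TRUE,
    rigor_points = pmin(totals, 5), resource_points = pmax(totals - 5, 0),
    total = totals, applicable = totals > 0
  )
  for (cr in c("IRB", "CONSENT", "IACUC", "RANDOMIZATION", "BLINDING",
               "POWER", "SEX", "CELL_AUTH", "CELL_CONTAM")) {
    out[[paste0("crit_", cr)]] <- FALSE
  }
  for (ty in c("ANTIBODY", "ORGANISM", "CELL_LINE", "PLASMID", "OLIGO",
               "SOFTWARE")) {
    out[[paste0("det_", ty)]] <- 0L
    out[[paste0("idf_", ty)]] <- 0L
  }
  out
}

test_that("journal-year aggregation averages scored papers and excludes zeros", {
  scores <- dplyr::bind_rows(
    fake_scores("Alpha", 2018, c(2, 4, 6, rep(3, 9))),
    fake_scores("Alpha", 2018, c(0, 0))
  )
  summ <- aggregate_journal_year(scores, min_n = 1)
  expect_equal(nrow(summ), 1)
  expect_equal(summ$rti, mean(c(2, 4, 6, rep(3, 9))))
  expect_equal(summ$n_scored, 12)
  expect_equal(summ$n_zero, 2)

  # zero-score-only journal-years emit no summary
  only_zero <- fake_scores("Beta", 2018, c(0, 0, 0))
  expect_equal(nrow(aggregate_journal_year(only_zero, min_n = 1)), 0)

  # order invariance
  shuffled <- scores[sample.int(nrow(scores)), ]
  expect_equal(aggregate_journal_year(shuffled, min_n = 1)$rti, summ$rti)

  # min_n suppression
  expect_equal(nrow(aggregate_journal_year(scores, min_n = 13)), 0)
})

test_that("mean of journal RTIs weighted by n_scored equals the global mean", {
  corpus <- generate_corpus(corpus_spec(n_docs = 60, seed = 52))
  scores <- score_corpus(corpus$documents)
  summ <- aggregate_journal_year(scores, min_n = 1)
  scored <- scores[scores$total > 0, ]
  expect_equal(sum(summ$rti * summ$n_scored) / sum(summ$n_scored),
               mean(scored$total))
})

test_that("identifiability rate reproduces the printed league-table rows", {
  expect_equal(identifiability_rate(242, 236), 98)
  expect_equal(identifiability_rate(2476, 2218), 90)
  expect_equal(identifiability_rate(5, 5), 100)
  # half-up integer rounding
  expect_equal(identifiability_rate(200, 185), 93)  # 92.5 rounds up
  expect_warning(r <- identifiability_rate(0, 0),
                 class = "rtindex_no_denominator")
  expect_true(is.na(r))
  expect_error(identifiability_rate(3, 4), class = "rtindex_rate_bounds")
})

test_that("authentication rate is the share of cell-line papers with a check", {
  expect_equal(authentication_rate(10, 5), 50.0)
  expect_equal(authentication_rate(4, 0), 0.0)
  expect_warning(r <- authentication_rate(0, 0),
                 class = "rtindex_no_denominator")
  expect_true(is.na(r))

  corpus <- generate_corpus(corpus_spec(n_docs = 40, seed = 53))
  scores <- score_corpus(corpus$documents)
  with_cl <- scores[scores$det_CELL_LINE > 0, ]
  n_auth <- sum(with_cl$crit_CELL_AUTH | with_cl$crit_CELL_CONTAM)
  expect_equal(authentication_rate(nrow(with_cl), n_auth),
               100 * n_auth / nrow(with_cl))
})

test_that("vertebrate subset retains exactly the IACUC documents", {
  corpus <- generate_corpus(corpus_spec(n_docs = 40, seed = 54))
  scores <- score_corpus(corpus$documents)
  hits <- detect_rigor_criteria(corpus$documents)
  truth_ids <- sort(unique(corpus$ground_truth$criteria$doc_id[
    corpus$ground_truth$criteria$criterion == "IACUC"]))
  sub <- vertebrate_subset(scores, hits)
  expect_equal(sort(sub$doc_id), truth_ids)
  expect_equal(sort(vertebrate_subset(scores)$doc_id), truth_ids)

  none <- fake_scores("Alpha", 2018, c(1, 2))
  expect_equal(nrow(vertebrate_subset(none)), 0)
})

test_that("spearman and pearson match brute force on 100 random vectors", {
  set.seed(606)
  for (rep in 1:100) {
    n <- sample(3:6, 1)
    x <- sample(1:4, n, replace = TRUE) + runif(n) * sample(0:1, 1)
    y <- sample(1:4, n, replace = TRUE) + runif(n) * sample(0:1, 1)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(rti_pearson(x, y)$coefficient, brute_pearson(x, y),
                 tolerance = 1e-12)
    expect_equal(rti_spearman(x, y)$coefficient, brute_spearman(x, y),
                 tolerance = 1e-12)
  }
})

test_that("spearman matches the no-ties closed form", {
  res <- rti_spearman(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$coefficient, 1 - 6 * 4 / (4 * 15))  # 0.6
  expect_equal(res$coefficient, 0.6)
  expect_equal(rti_spearman(c(1, 2, 3), c(10, 20, 30))$coefficient, 1.0)
  expect_equal(rti_spearman(c(1, 2, 3), c(30, 20, 10))$coefficient, -1.0)
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(607)
  for (rep in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    base <- rti_spearman(x, y)$coefficient
    expect_equal(rti_spearman(exp(x), y)$coefficient, base, tolerance = 1e-12)
    expect_equal(rti_spearman(x, y^3 + 5 * y)$coefficient, base,
                 tolerance = 1e-12)
  }
})

test_that("correlation contracts: errors and degenerate signals", {
  expect_error(rti_spearman(1:3, 1:4), class = "rtindex_cor_length")
  expect_error(rti_spearman(1, 1), class = "rtindex_cor_n")
  expect_error(rti_pearson(c(1, NA, 3), 1:3), class = "rtindex_cor_finite")
  expect_warning(r <- rti_spearman(c(2, 2, 2), 1:3),
                 class = "rtindex_degenerate")
  expect_true(is.na(r$coefficient))
  expect_equal(rti_pearson(1:5, -(1:5))$coefficient, -1)
  td <- generics::tidy(rti_spearman(1:4, c(2, 1, 4, 3)))
  expect_equal(td$estimate, 0.6)
  expect_equal(td$method, "spearman")
})

test_that("percentile ranks use average ranks with Q1 on top", {
  single <- percentile_ranks(5)
  expect_equal(single$percentile, 100)
  expect_equal(as.character(single$quartile), "Q1")

  four <- percentile_ranks(c(1, 2, 3, 4))
  expect_equal(as.character(four$quartile[four$value == 4]), "Q1")
  expect_equal(as.character(four$quartile[four$value == 1]), "Q4")
  expect_equal(four$percentile, c(25, 50, 75, 100))

  ties <- percentile_ranks(c(2, 2, 2))
  expect_equal(length(unique(ties$percentile)), 1)
  expect_equal(ties$percentile[1], 100 * 2 / 3)
})

test_that("trend table gives per-year means and drops empty years", {
  scores <- dplyr::bind_rows(
    fake_scores("Alpha", 2017, c(2, 2, 2)),
    fake_scores("Alpha", 2019, c(4, 6))
  )
  tr <- trend_table(scores)
  expect_equal(tr$year, c(2017L, 2019L))
  expect_equal(tr$mean_score, c(2, 5))
  expect_equal(tr$sd_score[1], 0)

  # rising configured prevalence does not apply here; instead check the
  # zero-exclusion convention
  with_zero <- dplyr::bind_rows(scores, fake_scores("Alpha", 2018, c(0)))
  tr2 <- trend_table(with_zero)
  expect_false(2018L %in% tr2$year)
})

test_that("JIF comparison joins on ISSN despite journal-name variants", {
  scores <- dplyr::bind_rows(
    fake_scores("The Alpha Journal", 2016, rep(c(2, 3), 10), issn = "1111-1111"),
    fake_scores("The Alpha Journal", 2017, rep(c(3, 4), 10), issn = "1111-1111"),
    fake_scores("Beta Journal", 2016, rep(c(6, 7), 10), issn = "2222-2222"),
    fake_scores("Beta Journal", 2017, rep(c(7, 8), 10), issn = "2222-2222"),
    fake_scores("Gamma Journal", 2016, rep(5, 15), issn = "3333-3333"),
    fake_scores("Gamma Journal", 2017, rep(4, 15), issn = "3333-3333")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("journal,issn,year,jif",
               "Alpha Journal,1111-1111,2018,30.0",  # name variant, same ISSN
               "Beta Journal,2222-2222,2018,3.0",
               "Gamma Journal,3333-3333,2018,10.0"), path)
  jif <- read_if_table(path)
  cmpres <- compare_with_jif(scores, jif, jif_year = 2018, min_n = 10)
  expect_equal(nrow(cmpres$data), 3)
  expect_s3_class(cmpres$spearman_raw, "correlation_result")
  # per-journal RTI over 2016-2017 only
  alpha <- cmpres$data[cmpres$data$issn == "1111-1111", ]
  expect_equal(alpha$rti, 3)
  # highest RTI has lowest JIF here: perfect rank inversion
  expect_equal(cmpres$spearman_raw$coefficient,
               brute_spearman(cmpres$data$rti, cmpres$data$jif))
})
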