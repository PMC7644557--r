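presence_of <- function(...) {
  crits <- c(...)
  tibble::tibble(criterion = crits, addressed = TRUE)
}

mention_rows <- function(type, n, n_identifiable) {
  tibble::tibble(
    doc_id = "d", resource_type = type,
    sentence_index = seq_len(n) - 1L,
    name = paste0(type, "_", seq_len(n)),
    vendor = NA_character_, catalog_number = NA_character_,
    clone_id = NA_character_, rrid = NA_character_, url = NA_character_,
    second_pass = FALSE,
    identifiable = seq_len(n) <= n_identifiable
  )
}

test_that("fully addressed and fully identifiable scores exactly 10", {
  pres <- presence_of("IRB", "IACUC", "RANDOMIZATION", "BLINDING", "POWER",
                      "SEX", "CELL_AUTH")
  mentions <- dplyr::bind_rows(
    mention_rows("ANTIBODY", 2, 2),
    mention_rows("CELL_LINE", 1, 1),
    mention_rows("SOFTWARE", 1, 1)
  )
  ps <- score_paper(pres, mentions)
  expect_equal(ps$rigor_points, 5)
  expect_equal(ps$resource_points, 5)
  expect_equal(ps$total, 10)
  expect_true(ps$applicable)
})

test_that("no criteria and no mentions is not applicable and scores 0", {
  ps <- score_paper(tibble::tibble(criterion = character(),
                                   addressed = logical()))
  expect_false(ps$applicable)
  expect_equal(ps$total, 0)
})

test_that("rigor component caps at exactly 5", {
  pres <- presence_of("IRB", "CONSENT", "IACUC", "RANDOMIZATION", "BLINDING",
                      "POWER", "SEX", "CELL_AUTH", "CELL_CONTAM")
  ps <- score_paper(pres, mention_rows("CELL_LINE", 1, 0))
  expect_equal(ps$rigor_points, 5)
  expect_equal(ps$resource_points, 0)
  expect_equal(ps$total, 5)
})

test_that("resource component caps at exactly 5", {
  mentions <- dplyr::bind_rows(
    mention_rows("ANTIBODY", 3, 3),
    mention_rows("ORGANISM", 2, 2),
    mention_rows("CELL_LINE", 1, 1),
    mention_rows("SOFTWARE", 4, 4)
  )
  ps <- score_paper(tibble::tibble(criterion = character(),
                                   addressed = logical()), mentions)
  expect_equal(ps$resource_points, 5)
  expect_equal(ps$rigor_points, 0)
})

test_that("merged-ethics arithmetic matches the stated formula", {
  # cell lines absent: 6 blocks - CELL_AUTH = 5 applicable;
  # SEX and RANDOMIZATION addressed -> 5 * 2/5 = 2.0
  ps <- score_paper(presence_of("SEX", "RANDOMIZATION"))
  expect_equal(ps$rigor_points, 2.0)
  expect_equal(sum(ps$blocks$applicable), 5)
})

test_that("4 antibodies with 2 identifiable gives 2.5 resource points", {
  ps <- score_paper(tibble::tibble(criterion = character(),
                                   addressed = logical()),
                    mention_rows("ANTIBODY", 4, 2))
  expect_equal(ps$resource_points, 2.5)
})

test_that("plasmids and oligos are recorded but never scored", {
  mentions <- dplyr::bind_rows(
    mention_rows("ANTIBODY", 2, 2),
    mention_rows("PLASMID", 3, 0),
    mention_rows("OLIGO", 2, 2)
  )
  ps <- score_paper(tibble::tibble(criterion = character(),
                                   addressed = logical()), mentions)
  expect_equal(ps$resource_points, 5)  # antibody ratio only
  cnt <- ps$resource_counts
  expect_equal(cnt$detected[cnt$resource_type == "PLASMID"], 3)
  expect_false(any(cnt$scoreable[cnt$resource_type %in% c("PLASMID", "OLIGO")]))
})

test_that("the cell-authentication block is conditional on a detected cell line", {
  # CELL_AUTH addressed but no cell line: block not applicable
  ps <- score_paper(presence_of("CELL_AUTH"))
  blocks <- ps$blocks
  expect_false(blocks$applicable[blocks$block == "CELL_AUTH"])
  # with a cell line, either auth or contamination addresses the block
  ps2 <- score_paper(presence_of("CELL_CONTAM"), mention_rows("CELL_LINE", 1, 0))
  b2 <- ps2$blocks
  expect_true(b2$applicable[b2$block == "CELL_AUTH"])
  expect_true(b2$addressed[b2$block == "CELL_AUTH"])
})

test_that("strict ethics mode separates human ethics from IACUC", {
  cfg <- score_config(ethics_mode = "strict")
  ps <- score_paper(presence_of("IACUC"), config = cfg)
  b <- ps$blocks
  expect_true(all(c("ETHICS_HUMAN", "IACUC") %in% b$block))
  expect_false(b$addressed[b$block == "ETHICS_HUMAN"])
  expect_true(b$addressed[b$block == "IACUC"])
  # 6 applicable blocks without cell lines; 1 addressed
  expect_equal(ps$rigor_points, 5 * 1 / 6)
})

test_that("all 2^7 block patterns match the closed-form score (exhaustive oracle)", {
  # independent oracle: with no resources and strict mode (7 blocks,
  # CELL_AUTH inapplicable without cell lines -> 6 applicable), the score is
  # 5 * addressed/applicable over the first six blocks
  cfg <- score_config(ethics_mode = "strict")
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 7))
  names(combos) <- c("IRB", "IACUC", "RANDOMIZATION", "BLINDING", "POWER",
                     "SEX", "CELL_AUTH")
  for (i in seq_len(nrow(combos))) {
    row <- unlist(combos[i, ])
    pres <- tibble::tibble(criterion = names(row), addressed = unname(row))
    ps <- score_paper(pres, config = cfg)
    addressed <- sum(row[c("IRB", "IACUC", "RANDOMIZATION", "BLINDING",
                           "POWER", "SEX")])
    expected_rigor <- 5 * addressed / 6  # CELL_AUTH inapplicable
    expect_equal(ps$rigor_points, expected_rigor, info = paste(row, collapse = ""))
    expect_equal(ps$total, expected_rigor + 0)
    expect_equal(ps$applicable, any(row))
  }
})

test_that("scores are bounded and monotone under randomized inputs", {
  set.seed(404)
  for (rep in 1:50) {
    crits <- sample(c("IRB", "CONSENT", "IACUC", "RANDOMIZATION", "BLINDING",
                      "POWER", "SEX", "CELL_AUTH", "CELL_CONTAM"),
                    sample(0:9, 1))
    pres <- tibble::tibble(criterion = crits,
                           addressed = rep(TRUE, length(crits)))
    n_ab <- sample(0:4, 1); k_ab <- if (n_ab > 0) sample(0:n_ab, 1) else 0
    mentions <- if (n_ab > 0) mention_rows("ANTIBODY", n_ab, k_ab) else {
      mention_rows("ANTIBODY", 1, 0)[0, ]
    }
    ps <- score_paper(pres, mentions)

    expect_gte(ps$rigor_points, 0); expect_lte(ps$rigor_points, 5)
    expect_gte(ps$resource_points, 0); expect_lte(ps$resource_points, 5)
    expect_equal(ps$total, ps$rigor_points + ps$resource_points)

    # adding an addressed block never decreases the total
    missing <- setdiff(c("IRB", "RANDOMIZATION", "BLINDING", "POWER", "SEX"),
                       crits)
    if (length(missing) > 0) {
      pres2 <- dplyr::bind_rows(pres, tibble::tibble(criterion = missing[1],
                                                     addressed = TRUE))
      ps2 <- score_paper(pres2, mentions)
      expect_gte(ps2$total, ps$total - 1e-12)
    }
    # flipping a mention identifiable never decreases the total
    if (n_ab > 0 && k_ab < n_ab) {
      m3 <- mention_rows("ANTIBODY", n_ab, k_ab + 1)
      ps3 <- score_paper(pres, m3)
      expect_gte(ps3$total, ps$total - 1e-12)
    }
  }
})

test_that("total is 10 exactly when everything applicable is satisfied", {
  set.seed(405)
  for (rep in 1:30) {
    full_pres <- presence_of("IRB", "IACUC", "RANDOMIZATION", "BLINDING",
                             "POWER", "SEX", "CELL_AUTH")
    n <- sample(1:3, 1); k <- sample(0:n, 1)
    mentions <- dplyr::bind_rows(mention_rows("ANTIBODY", n, k),
                                 mention_rows("CELL_LINE", 1, 1))
    ps <- score_paper(full_pres, mentions)
    all_identifiable <- k == n
    expect_equal(ps$total == 10, all_identifiable)
  }
})

test_that("score_rate reproduces the printed corpus arithmetic", {
  expect_error(score_rate(5, 4), class = "rtindex_score_rate")
  expect_equal(score_rate(1381072, 1578964), 87.5)
  expect_equal(score_rate(0, 10), 0.0)
  expect_equal(score_rate(7, 8), 87.5)
  expect_error(score_rate(1, 0), class = "rtindex_score_rate")
})

test_that("optional rounding mode rounds half up to integers", {
  ps <- score_paper(presence_of("SEX", "RANDOMIZATION"),
                    config = score_config(rounding = TRUE))
  # continuous 2.0 stays 2; a half point rounds up
  expect_equal(ps$total, 2)
  ps2 <- score_paper(presence_of("SEX", "RANDOMIZATION", "BLINDING"),
                     mention_rows("ANTIBODY", 4, 2),
                     config = score_config(rounding = TRUE))
  # 3 + 2.5 = 5.5 -> 6
  expect_equal(ps2$total, 6)
})

test_that("tidy and glance methods expose blocks and totals", {
  ps <- score_paper(presence_of("SEX"), mention_rows("ANTIBODY", 2, 1))
  td <- generics::tidy(ps)
  expect_true(all(c("block", "applicable", "addressed") %in% names(td)))
  gl <- generics::glance(ps)
  expect_equal(gl$total, ps$total)
  expect_equal(nrow(gl), 1)
})
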