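# Evaluate code with a local RNG state so corpus generation is reproducible
# and does not disturb the caller's random stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic methods-section corpus
#'
#' Defines the statistical structure of a generated corpus: how many
#' documents, which journals and years, the per-criterion prevalence of rigor
#' statements, and per resource type the mean number of mentions per document
#' and the probability that a mention carries identifying metadata (catalog
#' number or RRID). Defaults reflect recently reported corpus-wide rates:
#' randomization 30.3%, blinding 8.7%, power analysis 9.6%, sex 37.5%, IACUC
#' 24.6%; identifiability 43.3% for antibodies, 22% organisms, 39.3% cell
#' lines, 86.7% software. Cell-line authentication/contamination statements
#' are planted only in documents that received a cell-line mention (their
#' prevalence is conditional), matching the conditional scoring rule.
#'
#' @param n_docs Number of documents (>= 1).
#' @param journals Tibble or data frame with columns `journal`, `issn`.
#' @param year_range Inclusive integer pair.
#' @param criterion_prevalence Named probability vector over the nine
#'   criteria.
#' @param resource_config Tibble with columns `resource_type`,
#'   `mean_mentions` (>= 0), `identifiable_prob`. Mention counts per document
#'   are `floor(m)` plus a Bernoulli draw on the fractional part, so the
#'   configured mean is exact and `mean_mentions >= 1` guarantees at least
#'   one mention.
#' @param distractor_sentences Number of hard-negative filler sentences per
#'   document.
#' @param seed Integer seed; the same spec and seed yield a byte-identical
#'   corpus.
#' @return A list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_docs = 500,
                        journals = default_journals(),
                        year_range = c(2016L, 2019L),
                        criterion_prevalence = default_prevalence(),
                        resource_config = default_resource_config(),
                        distractor_sentences = 4,
                        seed = 1L) {
  journals <- tibble::as_tibble(journals)
  if (nrow(journals) == 0) abort_rtindex("journal list must be non-empty",
                                         "empty_journals")
  if (n_docs < 1) abort_rtindex("n_docs must be >= 1", "n_docs")
  prev <- default_prevalence()
  prev[names(criterion_prevalence)] <- criterion_prevalence
  if (any(prev < 0 | prev > 1)) abort_rtindex("prevalences must be in [0,1]",
                                              "prevalence")
  rc <- tibble::as_tibble(resource_config)
  if (any(rc$identifiable_prob < 0 | rc$identifiable_prob > 1) ||
      any(rc$mean_mentions < 0)) {
    abort_rtindex("invalid resource_config", "resource_config")
  }
  structure(
    list(n_docs = as.integer(n_docs), journals = journals,
         year_range = as.integer(year_range), criterion_prevalence = prev,
         resource_config = rc, distractor_sentences = distractor_sentences,
         seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

#' @rdname corpus_spec
#' @export
default_journals <- function() {
  tibble::tibble(
    journal = paste("Journal of Synthetic Biology", LETTERS[1:8]),
    issn = sprintf("1234-%04d", 5670 + 1:8)
  )
}

#' @rdname corpus_spec
#' @export
default_prevalence <- function() {
  c(IRB = 0.25, CONSENT = 0.20, IACUC = 0.246, RANDOMIZATION = 0.303,
    BLINDING = 0.087, POWER = 0.096, SEX = 0.375, CELL_AUTH = 0.40,
    CELL_CONTAM = 0.30)
}

#' @rdname corpus_spec
#' @export
default_resource_config <- function() {
  tibble::tibble(
    resource_type = c("ANTIBODY", "ORGANISM", "CELL_LINE", "SOFTWARE",
                      "PLASMID", "OLIGO"),
    mean_mentions = c(1.5, 1.0, 1.0, 1.2, 0.2, 0.3),
    identifiable_prob = c(0.433, 0.22, 0.393, 0.867, 0.5, 1.0)
  )
}

# --- template pools ---------------------------------------------------------

SYN_UNIVERSITIES <- c("Stanford", "Michigan", "Pennsylvania", "Toronto",
                      "Kyoto", "Heidelberg", "Melbourne", "Uppsala")
SYN_AB_TARGETS <- c("GFP", "ATF3", "GFAP", "NeuN", "Iba1", "MAP2", "TH",
                    "PSD95", "ChAT", "DCX")
SYN_STRAINS <- c("C57BL/6", "BALB/c", "CD-1", "129S1", "FVB/N", "DBA/2",
                 "C3H/HeJ", "NOD/ShiLtJ")
SYN_CELL_LINES <- c("H1299", "HEK293", "J774A.1", "U2OS", "A549", "MCF7",
                    "HCT116", "K562", "PC12", "HT22")
SYN_TISSUES <- c("lung", "breast", "colon", "ovarian")
SYN_REGISTRY_TOOLS <- c("ImageJ", "FlowJo", "CellProfiler", "GraphPad Prism",
                        "MATLAB", "Cytoscape")
SYN_FAKE_TOOLS <- c("BlotQuant", "MicroTracer", "CellMapPro", "TraceAlign")
SYN_PLASMIDS <- c("pEGFP-C3", "pGADT7.3", "pLKO.1", "pCMV6", "pU6-BbsI")

SYN_DISTRACTORS <- c(
  "The samples were centrifuged at 12,000 g for ten minutes.",
  "Protein concentration was determined using a BCA assay.",
  "Sections were incubated overnight in blocking buffer.",
  "The blind-ended duct was ligated and examined histologically.",
  "Expression of the doublesex gene was quantified by qPCR.",
  "The reaction was stopped by the addition of EDTA.",
  "Supernatants were collected and stored until analysis.",
  "Membranes were washed three times in TBST.",
  "The pellet was resuspended in ice-cold lysis buffer.",
  "Plates were read at 450 nm on a microplate reader."
)

criterion_sentence <- function(criterion) {
  u <- sample(SYN_UNIVERSITIES, 1)
  variants <- switch(
    criterion,
    IRB = c(
      sprintf("All procedures involving human participants were approved by the %s Institutional Review Board.", u),
      sprintf("The study protocol was reviewed and approved by the ethics committee of %s.", u)
    ),
    CONSENT = c(
      "Written informed consent was obtained from all participants.",
      "All subjects provided informed consent prior to enrollment."
    ),
    IACUC = c(
      sprintf("All animal experiments were approved by the %s Institutional Animal Care and Use Committee.", u),
      "Animal procedures were performed in accordance with institutional guidelines and national ethical approval."
    ),
    RANDOMIZATION = c(
      "Subjects were assigned to experimental groups using simple randomization.",
      "Treatment order was randomized across sessions."
    ),
    BLINDING = c(
      "Outcomes were scored by an experimenter blinded to group assignment.",
      "All analyses were performed by an investigator unaware of treatment condition."
    ),
    POWER = c(
      "Sample size was determined by a power analysis with significance level 0.05 and power 0.9.",
      "A priori power calculations were used to choose group sizes."
    ),
    SEX = c(
      "Both male and female subjects were included in each experimental group.",
      "The sex of all subjects was recorded at enrollment."
    ),
    CELL_AUTH = c(
      "All cell lines were authenticated by STR profiling.",
      "Cell line identity was verified by short tandem repeat analysis."
    ),
    CELL_CONTAM = c(
      "All cell lines tested negative for mycoplasma contamination.",
      "Cultures were confirmed to be mycoplasma free by PCR."
    )
  )
  sample(variants, 1)
}

rand_digits <- function(n) {
  paste(sample(0:9, n, replace = TRUE), collapse = "")
}

# Returns list(text=, name=) for one resource mention.
resource_sentence <- function(type, name, identifiable) {
  switch(
    type,
    ANTIBODY = {
      nm <- paste(name, "antibody")
      if (identifiable) {
        if (runif(1) < 0.5) {
          list(text = sprintf("Membranes were probed with %s (Abcam, ab%s).",
                              nm, rand_digits(5)), name = nm)
        } else {
          list(text = sprintf(
            "Sections were stained with %s (Cell Signaling Technology, RRID: AB_%s).",
            nm, rand_digits(6)), name = nm)
        }
      } else {
        list(text = sprintf("Lysates were probed with %s (Santa Cruz Biotechnology).",
                            nm), name = nm)
      }
    },
    ORGANISM = {
      nm <- paste(name, "mice")
      if (identifiable) {
        list(text = sprintf("Adult %s mice (RRID:IMSR_JAX:%s) were group-housed.",
                            name, rand_digits(6)), name = nm)
      } else {
        list(text = sprintf("Adult %s mice were group-housed under standard conditions.",
                            name), name = nm)
      }
    },
    CELL_LINE = {
      if (identifiable) {
        if (runif(1) < 0.5) {
          list(text = sprintf("%s cells (ATCC, number CRL-%s) were maintained in culture.",
                              name, rand_digits(4)), name = name)
        } else {
          list(text = sprintf("%s cells (RRID:CVCL_%s) were maintained in culture.",
                              name, rand_digits(4)), name = name)
        }
      } else {
        if (runif(1) < 0.5) {
          list(text = sprintf(
            "The %s carcinoma cell line, %s, was obtained from the American Tissue Culture Collection.",
            sample(SYN_TISSUES, 1), name), name = name)
        } else {
          list(text = sprintf("%s cells were cultured in supplemented growth medium.",
                              name), name = name)
        }
      }
    },
    SOFTWARE = {
      if (identifiable) {
        if (runif(1) < 0.5) {
          tool <- sample(SYN_REGISTRY_TOOLS, 1)
          list(text = sprintf("Images were analyzed with %s.", tool),
               name = tool)
        } else {
          list(text = sprintf("Data were processed with %s software (RRID:SCR_%s).",
                              name, rand_digits(6)), name = name)
        }
      } else {
        list(text = sprintf("Data were quantified using %s software.", name),
             name = name)
      }
    },
    PLASMID = {
      if (identifiable) {
        acc <- rand_digits(5)
        list(text = sprintf(
          "The insert was cloned into %s (Addgene plasmid #%s; RRID: Addgene_%s).",
          name, acc, acc), name = name)
      } else {
        list(text = sprintf("The fragment was subcloned into %s for expression.",
                            name), name = name)
      }
    },
    OLIGO = {
      seqs <- paste(sample(c("A", "C", "G", "T"), 18, replace = TRUE),
                    collapse = "")
      list(text = sprintf("The forward primer %s was used for amplification.",
                          seqs), name = seqs)
    }
  )
}

resource_name_pool <- function(type) {
  switch(type,
         ANTIBODY = SYN_AB_TARGETS,
         ORGANISM = SYN_STRAINS,
         CELL_LINE = SYN_CELL_LINES,
         SOFTWARE = SYN_FAKE_TOOLS,
         PLASMID = SYN_PLASMIDS,
         OLIGO = "SEQ")
}

#' Generate a synthetic corpus with ground truth
#'
#' Each document is assembled from slot-filled criterion-sentence templates
#' (planted per configured prevalence), resource-mention templates with or
#' without identifying metadata (per `identifiable_prob`), and hard-negative
#' distractor sentences; sentence order is shuffled. The ground truth records
#' every planted criterion sentence and resource mention with its sentence
#' index and identifiability, so detector output can be scored exactly. The
#' same spec and seed always produce an identical corpus.
#'
#' @param spec A [corpus_spec()].
#' @return A list with `documents` (document tibble), and `ground_truth`:
#'   `criteria` (`doc_id`, `criterion`, `sentence_index`) and `mentions`
#'   (`doc_id`, `resource_type`, `sentence_index`, `name`, `identifiable`).
#' @export
#' @examples
#' corpus <- generate_corpus(corpus_spec(n_docs = 3, seed = 42))
#' corpus$ground_truth$criteria
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_local_seed(spec$seed, {
    docs <- vector("list", spec$n_docs)
    gt_crit <- vector("list", spec$n_docs)
    gt_ment <- vector("list", spec$n_docs)

    for (d in seq_len(spec$n_docs)) {
      doc_id <- sprintf("doc%05d", d)
      jrow <- spec$journals[sample.int(nrow(spec$journals), 1), ]
      year <- sample(seq(spec$year_range[1], spec$year_range[2]), 1)

      sent <- character(0)
      crit_of <- character(0)   # criterion per sentence ("" = none)
      ment_of <- vector("list", 0)

      add_sentence <- function(text, criterion = "", mention = NULL) {
        sent[[length(sent) + 1L]] <<- text
        crit_of[[length(crit_of) + 1L]] <<- criterion
        ment_of[[length(ment_of) + 1L]] <<- mention
      }

      # resources first (cell-line presence gates the auth criteria)
      rc <- spec$resource_config
      for (r in seq_len(nrow(rc))) {
        ty <- rc$resource_type[r]
        m <- rc$mean_mentions[r]
        count <- floor(m) + rbinom(1, 1, m - floor(m))
        if (count < 1) next
        pool <- resource_name_pool(ty)
        names_r <- sample(pool, min(count, length(pool)))
        for (nm in names_r) {
          idf <- runif(1) < rc$identifiable_prob[r]
          rs <- resource_sentence(ty, nm, idf)
          add_sentence(rs$text, mention = list(
            resource_type = ty, name = rs$name, identifiable = idf))
        }
      }
      has_cell_line <- any(vapply(ment_of, function(m) {
        !is.null(m) && m$resource_type == "CELL_LINE"
      }, logical(1)))

      for (cr in RIGOR_CRITERIA) {
        p <- spec$criterion_prevalence[[cr]]
        if (cr %in% c("CELL_AUTH", "CELL_CONTAM") && !has_cell_line) next
        if (runif(1) < p) add_sentence(criterion_sentence(cr), criterion = cr)
      }

      if (spec$distractor_sentences > 0) {
        for (tx in sample(SYN_DISTRACTORS, spec$distractor_sentences,
                          replace = spec$distractor_sentences > length(SYN_DISTRACTORS))) {
          add_sentence(tx)
        }
      }

      ord <- sample.int(length(sent))
      sent <- sent[ord]; crit_of <- crit_of[ord]; ment_of <- ment_of[ord]
      text <- paste(sent, collapse = " ")
      doc <- new_document(doc_id, jrow$journal, jrow$issn, year, text)
      segs <- doc$sentences[[1]]
      if (nrow(segs) != length(sent) || !identical(segs$text, sent)) {
        abort_rtindex("generated sentences did not segment cleanly",
                      "generator_segmentation")
      }
      docs[[d]] <- doc

      idx <- seq_along(sent) - 1L
      has_crit <- nzchar(crit_of)
      if (any(has_crit)) {
        gt_crit[[d]] <- tibble::tibble(doc_id = doc_id,
                                       criterion = crit_of[has_crit],
                                       sentence_index = idx[has_crit])
      }
      is_ment <- !vapply(ment_of, is.null, logical(1))
      if (any(is_ment)) {
        gt_ment[[d]] <- tibble::tibble(
          doc_id = doc_id,
          resource_type = vapply(ment_of[is_ment], `[[`, "", "resource_type"),
          sentence_index = idx[is_ment],
          name = vapply(ment_of[is_ment], `[[`, "", "name"),
          identifiable = vapply(ment_of[is_ment], `[[`, NA, "identifiable")
        )
      }
    }

    crit_proto <- tibble::tibble(doc_id = character(), criterion = character(),
                                 sentence_index = integer())
    ment_proto <- tibble::tibble(doc_id = character(),
                                 resource_type = character(),
                                 sentence_index = integer(),
                                 name = character(), identifiable = logical())
    list(
      documents = dplyr::bind_rows(docs),
      ground_truth = list(
        criteria = dplyr::bind_rows(crit_proto, gt_crit),
        mentions = dplyr::bind_rows(ment_proto, gt_ment)
      )
    )
  })
}

#' Evaluate detector output against planted ground truth
#'
#' Exact-match evaluation on (document, sentence index, label): a planted
#' criterion or resource counts as recovered only if a hit/mention with the
#' same label lands on the same sentence.
#'
#' @param documents The generated document tibble.
#' @param ground_truth The `ground_truth` list from [generate_corpus()].
#' @param hits Criterion hits from [detect_rigor_criteria()].
#' @param mentions Resource mentions from [detect_resources()].
#' @return A tibble per label: `label`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
evaluate_detectors <- function(documents, ground_truth, hits, mentions) {
  truth <- dplyr::bind_rows(
    ground_truth$criteria |>
      dplyr::transmute(doc_id = .data$doc_id, label = .data$criterion,
                       sentence_index = .data$sentence_index),
    ground_truth$mentions |>
      dplyr::transmute(doc_id = .data$doc_id, label = .data$resource_type,
                       sentence_index = .data$sentence_index)
  ) |> dplyr::distinct()
  unknown <- setdiff(truth$doc_id, documents$doc_id)
  if (length(unknown) > 0) {
    abort_rtindex(paste("ground truth references unknown documents:",
                        paste(head(unknown, 3), collapse = ", ")),
                  "unknown_doc")
  }
  pred <- dplyr::bind_rows(
    hits |> dplyr::transmute(doc_id = .data$doc_id, label = .data$criterion,
                             sentence_index = .data$sentence_index),
    mentions |> dplyr::transmute(doc_id = .data$doc_id,
                                 label = .data$resource_type,
                                 sentence_index = .data$sentence_index)
  ) |> dplyr::distinct()

  labels <- sort(unique(c(truth$label, pred$label)))
  purrr::map_dfr(labels, function(lb) {
    t <- truth[truth$label == lb, c("doc_id", "sentence_index")]
    p <- pred[pred$label == lb, c("doc_id", "sentence_index")]
    tp <- nrow(dplyr::inner_join(t, p, by = c("doc_id", "sentence_index")))
    fp <- nrow(p) - tp
    fn <- nrow(t) - tp
    precision <- if (nrow(p) > 0) tp / nrow(p) else NA_real_
    recall <- if (nrow(t) > 0) tp / nrow(t) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
      2 * precision * recall / (precision + recall)
    } else if (isTRUE(precision == 0) || isTRUE(recall == 0)) 0 else NA_real_
    tibble::tibble(label = lb, tp = tp, fp = fp, fn = fn,
                   precision = precision, recall = recall, f1 = f1)
  })
}
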