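# Valid IOB2 label universe: O plus B-/I- over resource types and criteria.
tagger_taxonomy <- function() {
  base <- c(RESOURCE_TYPES, RIGOR_CRITERIA)
  c("O", paste0("B-", base), paste0("I-", base))
}

token_shape <- function(tokens) {
  s <- gsub("[A-Z]", "X", tokens)
  s <- gsub("[a-z]", "x", s)
  s <- gsub("[0-9]", "9", s)
  gsub("(.)\\1+", "\\1", s)
}

majority_map <- function(keys, labels) {
  tab <- tibble::tibble(key = keys, label = labels) |>
    dplyr::count(.data$key, .data$label) |>
    dplyr::arrange(.data$key, dplyr::desc(.data$n), .data$label) |>
    dplyr::distinct(.data$key, .keep_all = TRUE)
  stats::setNames(tab$label, tab$key)
}

#' Train the optional token-level sequence tagger
#'
#' The default detection engine is the deterministic pattern engine; this
#' tagger provides the trainable-model interface on top of IOB2 token labels.
#' It is a deliberately simple, fully deterministic memorization tagger: each
#' training token (lower-cased) votes for its majority label, with a
#' token-shape back-off for unseen tokens (so an unseen catalog-number-shaped
#' token can still inherit the label its shape carried in training) and `O`
#' as the final fallback. Ties break alphabetically, so retraining on the
#' same data always yields identical predictions.
#'
#' @param annotated A tibble with columns `sentence_id`, `token`, `label`
#'   (IOB2: `O`, `B-<TYPE>`, `I-<TYPE>`), e.g. from [read_conll()] or
#'   [generate_tagged_sentences()].
#' @param seed Integer seed, part of the interface contract; the tagger has
#'   no stochastic initialization, so it only fixes the stored metadata.
#' @return A `tagger_model` object.
#' @export
train_tagger <- function(annotated, seed = 1L) {
  if (is.null(annotated) || nrow(annotated) == 0) {
    abort_rtindex("training set is empty", "tagger_empty")
  }
  bad <- setdiff(unique(annotated$label), tagger_taxonomy())
  if (length(bad) > 0) {
    abort_rtindex(paste("labels outside taxonomy:",
                        paste(head(bad, 5), collapse = ", ")), "tagger_label")
  }
  structure(
    list(
      token_map = majority_map(tolower(annotated$token), annotated$label),
      shape_map = majority_map(token_shape(annotated$token), annotated$label),
      seed = as.integer(seed),
      n_sentences = length(unique(annotated$sentence_id))
    ),
    class = "tagger_model"
  )
}

#' @export
print.tagger_model <- function(x, ...) {
  cat(sprintf("<tagger_model> %d token types, %d shapes (trained on %d sentences)\n",
              length(x$token_map), length(x$shape_map), x$n_sentences))
  invisible(x)
}

#' Tag a sentence with a trained model
#'
#' @param model A `tagger_model` from [train_tagger()].
#' @param sentence A string (whitespace-tokenized) or a character vector of
#'   tokens.
#' @return A tibble `token`, `label`; labels are IOB2-consistent (an `I-`
#'   with no preceding tag of the same type is promoted to `B-`).
#' @export
tag_sentence <- function(model, sentence) {
  tokens <- if (length(sentence) == 1L) {
    strsplit(stringr::str_squish(sentence), " ")[[1]]
  } else as.character(sentence)
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0) {
    return(tibble::tibble(token = character(), label = character()))
  }
  labels <- unname(model$token_map[tolower(tokens)])
  miss <- is.na(labels)
  if (any(miss)) {
    labels[miss] <- unname(model$shape_map[token_shape(tokens[miss])])
  }
  labels[is.na(labels)] <- "O"
  # IOB2 repair
  prev_type <- ""
  for (i in seq_along(labels)) {
    lb <- labels[i]
    if (startsWith(lb, "I-")) {
      ty <- substring(lb, 3)
      if (prev_type != ty) labels[i] <- paste0("B-", ty)
    }
    prev_type <- if (lb == "O") "" else substring(labels[i], 3)
  }
  tibble::tibble(token = tokens, label = labels)
}

#' Token-level micro F1 over non-O labels
#'
#' @param predicted,truth Character vectors of equal length.
#' @return A one-row tibble `precision`, `recall`, `f1`.
#' @export
token_f1 <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  tp <- sum(predicted == truth & truth != "O")
  fp <- sum(predicted != "O" & predicted != truth)
  fn <- sum(truth != "O" & predicted != truth)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  tibble::tibble(precision = precision, recall = recall, f1 = f1)
}

#' Generate token-labelled sentences from the synthetic templates
#'
#' Produces resource-mention sentences with IOB2 labels over the resource
#' name tokens, for exercising the trainable-tagger interface without any
#' external annotation.
#'
#' @param n Number of sentences.
#' @param seed Integer seed.
#' @return A tibble `sentence_id`, `token`, `label`.
#' @export
generate_tagged_sentences <- function(n, seed = 1L) {
  with_local_seed(seed, {
    types <- setdiff(RESOURCE_TYPES, "OLIGO")
    purrr::map_dfr(seq_len(n), function(i) {
      ty <- sample(types, 1)
      nm <- sample(resource_name_pool(ty), 1)
      idf <- runif(1) < 0.5
      rs <- resource_sentence(ty, nm, idf)
      tokens <- strsplit(stringr::str_squish(rs$text), " ")[[1]]
      name_tokens <- strsplit(rs$name, " ")[[1]]
      labels <- rep("O", length(tokens))
      # locate the name token run (tokens may carry trailing punctuation)
      for (s in seq_len(length(tokens) - length(name_tokens) + 1L)) {
        span <- s:(s + length(name_tokens) - 1L)
        if (all(startsWith(tokens[span], name_tokens))) {
          labels[span] <- c(paste0("B-", ty),
                            rep(paste0("I-", ty), length(name_tokens) - 1L))
          break
        }
      }
      tibble::tibble(sentence_id = i, token = tokens, label = labels)
    })
  })
}

#' Read and write CoNLL-style annotated sentences
#'
#' Two-column token TAB label text files, sentences separated by blank lines.
#'
#' @param path File path.
#' @return `read_conll()` returns a tibble `sentence_id`, `token`, `label`.
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sid <- cumsum(!nzchar(lines)) + 1L
  keep <- nzchar(lines)
  parts <- stringr::str_split_fixed(lines[keep], "\t", 2)
  tibble::tibble(sentence_id = match(sid[keep], unique(sid[keep])),
                 token = parts[, 1], label = parts[, 2])
}

#' @rdname read_conll
#' @param annotated A tibble `sentence_id`, `token`, `label`.
#' @export
write_conll <- function(annotated, path) {
  chunks <- split(annotated, annotated$sentence_id)
  out <- unlist(lapply(chunks, function(ch) {
    c(paste(ch$token, ch$label, sep = "\t"), "")
  }))
  writeLines(out[-length(out)], path)
  invisible(path)
}
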