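#' Read an annotated corpus from a JSON-lines file
#'
#' One JSON object per line with keys `"pmid"` (string), `"title"` (string),
#' `"abstractText"` (string) and optionally `"meshMajor"` (array of
#' descriptor-id strings), mirroring the citation layout of large-scale
#' biomedical indexing collections. Documents without `meshMajor` are
#' unannotated (empty label set).
#'
#' @param path path to a JSON-lines file.
#' @return a [tibble::tibble] with columns `doc_id`, `title`, `abstract` and
#'   the list-column `labels` (character vectors), one row per input line in
#'   file order.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(doc_id = character(0), title = character(0),
                          abstract = character(0), labels = list()))
  }
  recs <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop("malformed corpus line ", i, ": ", conditionMessage(e),
                           call. = FALSE)
                    })
    for (key in c("pmid", "title", "abstractText")) {
      if (is.null(obj[[key]])) {
        stop("corpus line ", i, ": missing required key \"", key, "\"",
             call. = FALSE)
      }
    }
    labels <- obj[["meshMajor"]]
    labels <- if (is.null(labels)) character(0) else as.character(unlist(labels))
    list(doc_id = as.character(obj$pmid), title = as.character(obj$title),
         abstract = as.character(obj$abstractText), labels = labels)
  })
  ids <- vapply(recs, `[[`, character(1), "doc_id")
  if (anyDuplicated(ids)) {
    stop("duplicate doc_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    doc_id = ids,
    title = vapply(recs, `[[`, character(1), "title"),
    abstract = vapply(recs, `[[`, character(1), "abstract"),
    labels = lapply(recs, `[[`, "labels")
  )
}

#' Write an annotated corpus as JSON-lines
#'
#' Inverse of [read_corpus()]; `read_corpus(write_corpus(x, f))` round-trips
#' exactly.
#'
#' @param corpus corpus data frame (`doc_id`, `title`, `abstract`, `labels`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(
      list(pmid = jsonlite::unbox(corpus$doc_id[i]),
           title = jsonlite::unbox(corpus$title[i]),
           abstractText = jsonlite::unbox(corpus$abstract[i]),
           meshMajor = as.character(corpus$labels[[i]])),
      auto_unbox = FALSE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a descriptor thesaurus from a TSV file
#'
#' Tab-separated with a header row and columns `descriptor_id`,
#' `preferred_term` and `entry_terms` (pipe-separated synonyms; may be
#' empty). The preferred term is implicitly an entry term and is added to
#' the entry-term list on reading. This emulates controlled-vocabulary main
#' headings with their entry terms.
#'
#' @param path path to the TSV file.
#' @return a `thesaurus` object: a tibble with columns `descriptor_id`,
#'   `preferred_term` and list-column `entry_terms` (each including the
#'   preferred term).
#' @export
read_thesaurus <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           stringsAsFactors = FALSE)
  need <- c("descriptor_id", "preferred_term", "entry_terms")
  if (!all(need %in% names(tab))) {
    stop("thesaurus file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$descriptor_id)) {
    stop("duplicate descriptor_id in thesaurus: ",
         paste(unique(tab$descriptor_id[duplicated(tab$descriptor_id)]),
               collapse = ", "), call. = FALSE)
  }
  new_thesaurus(tab$descriptor_id, tab$preferred_term,
                strsplit(tab$entry_terms, "|", fixed = TRUE))
}

#' Construct a thesaurus in memory
#'
#' @param descriptor_id character vector of unique descriptor ids.
#' @param preferred_term character vector of preferred terms.
#' @param entry_terms list of character vectors of synonyms (the preferred
#'   term is added where missing).
#' @return a `thesaurus` tibble.
#' @export
new_thesaurus <- function(descriptor_id, preferred_term, entry_terms) {
  stopifnot(length(descriptor_id) == length(preferred_term),
            length(descriptor_id) == length(entry_terms))
  if (anyDuplicated(descriptor_id)) stop("descriptor ids must be unique")
  entries <- lapply(seq_along(descriptor_id), function(i) {
    e <- entry_terms[[i]]
    e <- e[nzchar(e)]
    unique(c(preferred_term[i], e))
  })
  th <- tibble::tibble(descriptor_id = as.character(descriptor_id),
                       preferred_term = as.character(preferred_term),
                       entry_terms = entries)
  class(th) <- c("thesaurus", class(th))
  th
}

#' Write a thesaurus as TSV
#'
#' @param thesaurus a `thesaurus` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_thesaurus <- function(thesaurus, path) {
  entry <- vapply(seq_len(nrow(thesaurus)), function(i) {
    e <- setdiff(thesaurus$entry_terms[[i]], thesaurus$preferred_term[i])
    paste(e, collapse = "|")
  }, character(1))
  tab <- data.frame(descriptor_id = thesaurus$descriptor_id,
                    preferred_term = thesaurus$preferred_term,
                    entry_terms = entry, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write predictions as JSON-lines
#'
#' One object per document: `pmid`, `ranked` (array of label/score pairs)
#' and `selected` (array of selected label ids).
#'
#' @param predictions tibble as returned by [classify_corpus()], with
#'   columns `doc_id`, `ranked` (list of tibbles with `label_id`, `score`)
#'   and `selected` (list of character vectors).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  lines <- vapply(seq_len(nrow(predictions)), function(i) {
    rk <- predictions$ranked[[i]]
    jsonlite::toJSON(
      list(pmid = jsonlite::unbox(predictions$doc_id[i]),
           ranked = data.frame(label = rk$label_id, score = rk$score),
           selected = as.character(predictions$selected[[i]])),
      auto_unbox = FALSE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read predictions written by [write_predictions()]
#'
#' @param path JSON-lines prediction file.
#' @return tibble with columns `doc_id`, `ranked`, `selected`.
#' @export
read_predictions <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  tibble::tibble(
    doc_id = vapply(recs, function(r) as.character(r$pmid), character(1)),
    ranked = lapply(recs, function(r) {
      rk <- r$ranked
      if (is.null(rk) || length(rk) == 0L) {
        tibble::tibble(label_id = character(0), score = numeric(0))
      } else {
        tibble::tibble(label_id = as.character(rk$label),
                       score = as.numeric(rk$score))
      }
    }),
    selected = lapply(recs, function(r) as.character(unlist(r$selected)))
  )
}
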