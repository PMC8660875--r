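# Reading, normalizing and tabulating verbal-fluency transcripts.

#' Read verbal-fluency transcripts
#'
#' Reads a delimited transcript file with one row per produced response and
#' columns `participant_id,group,rank,response` (UTF-8). Responses are
#' returned in production order as a list of fluency records.
#'
#' @param path path to a CSV (or TSV, with `sep = "\t"`) transcript file.
#' @param sep field separator, `","` by default.
#' @return A list of `fluency_record` objects (see [fluency_record()]).
#' @export
read_fluency <- function(path, sep = ",") {
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8", colClasses = "character")
  need <- c("participant_id", "group", "rank", "response")
  if (!all(need %in% names(df))) {
    stop_stage("fluency_io", "transcript must have columns %s",
               paste(need, collapse = ","))
  }
  df$rank <- as.numeric(df$rank)
  records_from_frame(df)
}

#' Build fluency records from a data frame
#'
#' @param df data frame with columns `participant_id`, `group`, `rank`,
#'   `response`.
#' @return list of `fluency_record` objects, one per participant, responses
#'   ordered by `rank`.
#' @export
records_from_frame <- function(df) {
  ids <- unique(df$participant_id)
  lapply(ids, function(id) {
    sub <- df[df$participant_id == id, , drop = FALSE]
    grp <- unique(sub$group)
    if (length(grp) != 1L) {
      stop_stage("fluency_io", "participant %s has multiple group labels", id)
    }
    sub <- sub[order(sub$rank), , drop = FALSE]
    fluency_record(id, grp, sub$response)
  })
}

#' One participant's ordered fluency responses
#'
#' @param participant_id opaque participant identifier (unique in a cohort).
#' @param group group label (the study design has exactly two).
#' @param responses character vector of raw responses in production order;
#'   may be empty.
#' @return an object of class `fluency_record`.
#' @export
fluency_record <- function(participant_id, group, responses = character()) {
  structure(
    list(participant_id = as.character(participant_id),
         group = as.character(group),
         responses = as.character(responses)),
    class = "fluency_record")
}

#' @export
print.fluency_record <- function(x, ...) {
  cat(sprintf("<fluency_record> %s [group %s]: %d responses\n",
              x$participant_id, x$group, length(x$responses)))
  invisible(x)
}

#' Normalization rules for fluency responses
#'
#' A table-driven canonicalization: a variant-to-canonical map (root/lemma
#' merging, e.g. "cats" -> "cat") plus an optional category lexicon listing
#' admissible canonical exemplars. Canonical forms must be fixed points of
#' the map; a lexicon, when given, may contain only canonical forms.
#'
#' @param variant_map named character vector mapping raw form to canonical
#'   form; names are variants, values canonical forms. Both sides are
#'   case-folded and accent-stripped on construction.
#' @param lexicon optional character vector of admissible canonical forms.
#' @return an object of class `normalization_rules`.
#' @export
normalization_rules <- function(variant_map = character(), lexicon = NULL) {
  if (length(variant_map)) {
    if (is.null(names(variant_map))) {
      stop_stage("fluency_io", "variant_map must be a named character vector")
    }
    variant_map <- setNames(fold_token(as.character(variant_map)),
                            fold_token(names(variant_map)))
    canon <- unname(variant_map)
    moved <- canon %in% names(variant_map) & variant_map[canon] != canon
    moved[is.na(moved)] <- FALSE
    if (any(moved)) {
      stop_stage("fluency_io",
                 "canonical forms must be fixed points of variant_map: %s",
                 paste(unique(canon[moved]), collapse = ", "))
    }
  }
  if (!is.null(lexicon)) {
    lexicon <- fold_token(as.character(lexicon))
    mapped <- lexicon %in% names(variant_map) & variant_map[lexicon] != lexicon
    mapped[is.na(mapped)] <- FALSE
    if (any(mapped)) {
      stop_stage("fluency_io", "lexicon must contain only canonical forms")
    }
    lexicon <- sort(unique(lexicon))
  }
  structure(list(variant_map = variant_map, lexicon = lexicon),
            class = "normalization_rules")
}

#' Read normalization rules from files
#'
#' @param variant_csv path to a CSV with header `variant,canonical`, or NULL.
#' @param lexicon_file path to a plain-text file with one canonical exemplar
#'   per line, or NULL.
#' @return a `normalization_rules` object.
#' @export
read_normalization <- function(variant_csv = NULL, lexicon_file = NULL) {
  vm <- character()
  if (!is.null(variant_csv)) {
    tab <- read.csv(variant_csv, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8", colClasses = "character")
    vm <- setNames(tab$canonical, tab$variant)
  }
  lex <- if (!is.null(lexicon_file)) {
    readLines(lexicon_file, encoding = "UTF-8", warn = FALSE)
  } else NULL
  if (!is.null(lex)) lex <- lex[nzchar(trimws(lex))]
  normalization_rules(vm, lex)
}

# Case-fold and strip accents. The study language is French, so
# orthographic variants such as "léopard"/"leopard" must merge. A chartr
# table covers Latin-1 accents; iconv transliteration catches the rest, and
# residual transliteration marks (quotes, carets) are removed.
fold_token <- function(x) {
  x <- trimws(tolower(x))
  x <- chartr("àáâãäåèéêëìíîïòóôõöùúûüçñýÿ",
              "aaaaaaeeeeiiiiooooouuuucnyy", x)
  x <- gsub("œ", "oe", x)
  x <- gsub("æ", "ae", x)
  y <- suppressWarnings(iconv(x, "UTF-8", "ASCII//TRANSLIT"))
  y[is.na(y)] <- x[is.na(y)]
  y <- gsub("[\"'`^~¨]", "", y)
  gsub("[[:space:]]+", " ", trimws(y))
}

#' Normalize a fluency record
#'
#' Case-folds and accent-strips each raw response, applies the variant map,
#' drops responses outside the lexicon (when one is given), and removes
#' repetitions, keeping first-occurrence order. Dropped tokens are reported
#' as messages, never as errors.
#'
#' @param record a `fluency_record`.
#' @param rules a `normalization_rules` object.
#' @param quiet suppress the per-token drop log.
#' @return the canonicalized, deduplicated `fluency_record`.
#' @export
normalize_responses <- function(record, rules = normalization_rules(),
                                quiet = FALSE) {
  stopifnot(inherits(record, "fluency_record"),
            inherits(rules, "normalization_rules"))
  resp <- fold_token(record$responses)
  resp <- resp[nzchar(resp)]
  hit <- resp %in% names(rules$variant_map)
  resp[hit] <- unname(rules$variant_map[resp[hit]])
  if (!is.null(rules$lexicon)) {
    out_of_cat <- !(resp %in% rules$lexicon)
    if (any(out_of_cat) && !quiet) {
      flunet_log("participant %s: dropped %d non-category response(s): %s",
                 record$participant_id, sum(out_of_cat),
                 paste(unique(resp[out_of_cat]), collapse = ", "))
    }
    resp <- resp[!out_of_cat]
  }
  fluency_record(record$participant_id, record$group, unique(resp))
}

#' Normalize a whole cohort
#'
#' @param records list of `fluency_record` objects.
#' @inheritParams normalize_responses
#' @return list of normalized records.
#' @export
normalize_cohort <- function(records, rules = normalization_rules(),
                             quiet = FALSE) {
  lapply(records, normalize_responses, rules = rules, quiet = quiet)
}

#' Build a binary response matrix for one group
#'
#' Rows are participants, columns the union of canonical exemplars produced
#' by the group (in lexicographic order, for determinism); cell (p, e) is 1
#' iff participant p produced exemplar e. Records must already be
#' normalized and share one group label.
#'
#' @param records list of normalized `fluency_record` objects with a common
#'   group label.
#' @return a binary matrix of class `response_matrix` with participant row
#'   names, exemplar column names, and a `"group"` attribute.
#' @export
build_response_matrix <- function(records) {
  stopifnot(length(records) >= 1L)
  groups <- unique(vapply(records, `[[`, "", "group"))
  if (length(groups) != 1L) {
    stop_stage("fluency_io",
               "records span groups (%s); split groups before tabulating",
               paste(groups, collapse = ", "))
  }
  ids <- vapply(records, `[[`, "", "participant_id")
  if (anyDuplicated(ids)) {
    stop_stage("fluency_io", "duplicate participant ids: %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  exemplars <- sort(unique(unlist(lapply(records, `[[`, "responses"))))
  mat <- matrix(0L, nrow = length(records), ncol = length(exemplars),
                dimnames = list(ids, exemplars))
  for (i in seq_along(records)) {
    mat[i, records[[i]]$responses] <- 1L
  }
  response_matrix(mat, groups)
}

#' Construct a response matrix object
#'
#' @param mat binary integer matrix (participants x exemplars) with
#'   dimnames.
#' @param group group label.
#' @return the matrix with class `response_matrix` and a `group` attribute.
#' @export
response_matrix <- function(mat, group) {
  stopifnot(is.matrix(mat), all(mat %in% c(0L, 1L)),
            !is.null(rownames(mat)), !is.null(colnames(mat)))
  storage.mode(mat) <- "integer"
  structure(mat, group = as.character(group),
            class = c("response_matrix", class(mat)))
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> group %s: %d participants x %d exemplars\n",
              attr(x, "group"), nrow(x), ncol(x)))
  invisible(x)
}

#' Write a response matrix as CSV
#'
#' @param mat a `response_matrix`.
#' @param path output path; first column holds participant ids.
#' @export
write_response_matrix <- function(mat, path) {
  df <- data.frame(participant_id = rownames(mat),
                   as.data.frame(unclass(mat)[, , drop = FALSE]),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Group-level fluency descriptives
#'
#' Per-group mean and SD of the number of distinct responses per
#' participant, the number of distinct exemplars in each group, and the
#' number of exemplars exclusive to each group (set difference of the
#' column sets).
#'
#' @param mat_a,mat_b `response_matrix` objects for the two groups.
#' @return a list with elements `group_a`, `group_b` (each with `group`,
#'   `n`, `mean_responses`, `sd_responses`, `n_distinct`, `n_exclusive`).
#' @export
fluency_descriptives <- function(mat_a, mat_b) {
  one <- function(m, other) {
    present <- colnames(m)[colSums(m) >= 1L]
    other_present <- colnames(other)[colSums(other) >= 1L]
    rs <- rowSums(m)
    list(group = attr(m, "group"),
         n = nrow(m),
         mean_responses = mean(rs),
         sd_responses = sd(rs),
         n_distinct = length(present),
         n_exclusive = length(setdiff(present, other_present)))
  }
  list(group_a = one(mat_a, mat_b), group_b = one(mat_b, mat_a))
}
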