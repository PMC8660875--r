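# From response matrices to cosine association matrices.

#' Drop exemplars produced by too few participants
#'
#' Retains exactly the columns whose column sum is at least `min_count`
#' (default 2: an exemplar must be given by at least two participants in a
#' group to enter that group's network). Rows are unchanged.
#'
#' @param mat a `response_matrix`.
#' @param min_count minimum number of participants producing an exemplar.
#' @return the filtered `response_matrix`.
#' @export
filter_min_occurrence <- function(mat, min_count = 2L) {
  stopifnot(min_count >= 1L)
  keep <- colSums(mat) >= min_count
  if (!any(keep)) {
    stop_stage("estimation",
               "no exemplar reaches min_count = %d; insufficient shared vocabulary",
               min_count)
  }
  response_matrix(unclass(mat)[, keep, drop = FALSE], attr(mat, "group"))
}

#' Equate node sets across two groups
#'
#' Restricts both response matrices to the intersection of their column
#' sets so the two group networks are built over identical nodes. Column
#' order (lexicographic) is shared by both outputs. Apply after
#' [filter_min_occurrence()].
#'
#' @param mat_a,mat_b `response_matrix` objects, already min-occurrence
#'   filtered.
#' @return list with elements `a` and `b`, the equated matrices.
#' @export
equate_nodes <- function(mat_a, mat_b) {
  shared <- sort(intersect(colnames(mat_a), colnames(mat_b)))
  if (length(shared) == 0L) {
    stop_stage("estimation", "groups share no exemplars after filtering")
  }
  list(a = response_matrix(unclass(mat_a)[, shared, drop = FALSE],
                           attr(mat_a, "group")),
       b = response_matrix(unclass(mat_b)[, shared, drop = FALSE],
                           attr(mat_b, "group")))
}

#' Cosine association matrix from a binary response matrix
#'
#' For exemplars i and j, the association is
#' \deqn{A_{ij} = c_{ij} / \sqrt{f_i f_j}}
#' where \eqn{c_{ij}} is the number of participants producing both and
#' \eqn{f_i} the number producing i. Values range from 0 (never co-occur)
#' to 1 (always co-occur). The diagonal is stored as 0 and never used.
#'
#' @param mat a binary `response_matrix` with at least 2 columns and no
#'   zero-frequency column.
#' @return a symmetric numeric matrix of class `association_matrix` with
#'   exemplar dimnames and the group carried in the `"group"` attribute.
#' @export
cosine_association <- function(mat) {
  if (ncol(mat) < 2L) {
    stop_stage("estimation", "need at least 2 exemplars, got %d", ncol(mat))
  }
  f <- colSums(mat)
  if (any(f == 0L)) {
    stop_stage("estimation", "zero-frequency exemplar(s): %s",
               paste(colnames(mat)[f == 0L], collapse = ", "))
  }
  co <- crossprod(unclass(mat))
  assoc <- co / sqrt(tcrossprod(f))
  diag(assoc) <- 0
  structure(assoc, group = attr(mat, "group"),
            class = c("association_matrix", "matrix", "array"))
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("<association_matrix> group %s: %d exemplars, mean off-diagonal %.4f\n",
              attr(x, "group") %||% "?", nrow(x),
              mean(x[upper.tri(x)])))
  invisible(x)
}
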