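# Second-order model terms and the design matrix.
#
# A term set is a data frame (class "rsm_terms") with one row per
# non-intercept term: kind in {linear, square, interaction}, 1-based factor
# indices i (and j for interactions, i < j), and a label in the x-index
# notation used in serialized reports ("x1", "x1^2", "x3*x7").

term_label <- function(kind, i, j = NA_integer_) {
  switch(kind,
    linear      = paste0("x", i),
    square      = paste0("x", i, "^2"),
    interaction = paste0("x", i, "*x", j),
    stop("unknown term kind: ", kind)
  )
}

new_rsm_terms <- function(kind, i, j) {
  tt <- data.frame(kind = kind, i = as.integer(i), j = as.integer(j))
  tt$label <- mapply(term_label, tt$kind, tt$i, tt$j)
  if (anyDuplicated(tt$label)) stop("duplicate terms", call. = FALSE)
  bad <- tt$kind == "interaction" & (is.na(tt$j) | tt$i >= tt$j)
  if (any(bad)) stop("interaction indices must satisfy i < j", call. = FALSE)
  class(tt) <- c("rsm_terms", "data.frame")
  tt
}

#' Candidate terms of the second-order response surface
#'
#' Builds the full second-order candidate set over the seven culture factors:
#' all 7 squared terms and all `choose(7, 2) = 21` pairwise interactions,
#' optionally (default) together with the 7 linear main effects. The
#' intercept is implicit and always fitted.
#'
#' @param include_linear Include the 7 linear terms (default `TRUE`; the
#'   published final model contains linear terms, so the default candidate
#'   pool must offer them).
#' @return An `rsm_terms` data frame (35 rows, or 28 without linear terms).
#' @examples
#' nrow(candidate_terms())        # 35
#' nrow(candidate_terms(FALSE))   # 28
#' @export
candidate_terms <- function(include_linear = TRUE) {
  p <- length(culture_factors())
  pairs <- utils::combn(p, 2)
  kind <- c(if (include_linear) rep("linear", p), rep("square", p),
            rep("interaction", ncol(pairs)))
  i <- c(if (include_linear) seq_len(p), seq_len(p), pairs[1L, ])
  j <- c(rep(NA_integer_, length(kind) - ncol(pairs)), pairs[2L, ])
  new_rsm_terms(kind, i, j)
}

#' Select terms by label
#'
#' @param labels Character labels in x-index notation, e.g.
#'   `c("x1", "x1^2", "x3*x7")`.
#' @return An `rsm_terms` subset of the full candidate set.
#' @export
terms_by_label <- function(labels) {
  full <- candidate_terms(include_linear = TRUE)
  idx <- match(labels, full$label)
  if (anyNA(idx))
    stop("unknown term label(s): ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  out <- full[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the design matrix for a term set
#'
#' Column `j` evaluates term `j` at each record's condition (linear: `x_i`;
#' square: `x_i^2`; interaction: `x_i * x_j`). An intercept column of ones is
#' prepended when `intercept = TRUE`.
#'
#' @param records Data frame with the seven factor columns.
#' @param terms An `rsm_terms` data frame.
#' @param intercept Prepend a column of ones (default `TRUE`).
#' @return Numeric matrix, `nrow(records)` rows, one column per term
#'   (labelled; intercept column `"(Intercept)"`).
#' @export
build_design_matrix <- function(records, terms, intercept = TRUE) {
  if (nrow(records) == 0L) stop("no records to build a design from",
                                call. = FALSE)
  fac <- culture_factors()
  X <- as.matrix(records[fac])
  cols <- lapply(seq_len(nrow(terms)), function(k) {
    i <- terms$i[k]
    switch(terms$kind[k],
      linear      = X[, i],
      square      = X[, i]^2,
      interaction = X[, i] * X[, terms$j[k]]
    )
  })
  M <- do.call(cbind, c(if (intercept) list(`(Intercept)` = rep(1, nrow(X))),
                        cols))
  colnames(M) <- c(if (intercept) "(Intercept)", terms$label)
  M
}

#' @export
print.rsm_terms <- function(x, ...) {
  cat("Response-surface term set: ", nrow(x), " term(s) + intercept\n",
      sep = "")
  cat(" ", paste(x$label, collapse = " "), "\n")
  invisible(x)
}
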