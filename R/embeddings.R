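#' Read word vectors in word2vec text format
#'
#' The text format begins with a header line `"<count> <dim>"` followed by
#' one line per token: the token then `dim` whitespace-separated floats.
#'
#' @param path path to a word2vec text file.
#' @return numeric matrix, one row per token, rownames set to the tokens.
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("word2vec file has no vectors: ", path)
  hdr <- as.integer(strsplit(trimws(lines[[1L]]), "\\s+")[[1L]])
  if (length(hdr) != 2L || any(is.na(hdr)))
    stop("malformed word2vec header in ", path)
  body <- lines[-1L][nzchar(trimws(lines[-1L]))]
  parts <- strsplit(trimws(body), "\\s+")
  tokens <- vapply(parts, `[[`, character(1L), 1L)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(hdr[[2L]])))
  if (nrow(vecs) != hdr[[1L]])
    warning("word2vec header count (", hdr[[1L]], ") does not match ",
            nrow(vecs), " vector lines; using the lines read")
  rownames(vecs) <- tokens
  vecs
}

#' Write word vectors in word2vec text format
#'
#' @param vectors numeric matrix with rownames (tokens).
#' @param path output path.
#' @export
write_word2vec <- function(vectors, path) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(vectors), ncol(vectors)), con)
  body <- vapply(seq_len(nrow(vectors)), function(i) {
    paste(rownames(vectors)[i],
          paste(format(vectors[i, ], scientific = FALSE, trim = TRUE,
                       digits = 17), collapse = " "))
  }, character(1L))
  writeLines(body, con)
  invisible(path)
}

#' Read a JSON embedding dialect: an object mapping label to a float array
#'
#' @param path path to a JSON file `{"label": [floats], ...}`.
#' @return numeric matrix with rownames.
#' @export
read_embeddings_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(obj) || is.null(names(obj)))
    stop("expected a JSON object mapping labels to numeric arrays: ", path)
  u <- length(obj[[1L]])
  vecs <- t(vapply(obj, function(v) as.numeric(v), numeric(u)))
  rownames(vecs) <- names(obj)
  vecs
}

as_embedding_source <- function(source) {
  if (is.matrix(source)) {
    if (is.null(rownames(source))) stop("embedding source matrix needs rownames")
    return(source)
  }
  if (is.list(source) && !is.null(names(source))) {
    u <- length(source[[1L]])
    m <- t(vapply(source, function(v) as.numeric(v), numeric(u)))
    rownames(m) <- names(source)
    return(m)
  }
  stop("embedding source must be a rownamed matrix or a named list of vectors")
}

#' Embed class-label names using a pre-trained vector lookup
#'
#' Labels are lowercased and split on whitespace and underscores; each label
#' maps to the arithmetic mean of its in-vocabulary token vectors. A label
#' whose full (lowercased) name is present in the source is used directly,
#' so phrase vectors (BioWordVec-style) take precedence over token means.
#'
#' @param labels character vector of unique, non-empty class names.
#' @param source token lookup: a matrix with token rownames or a named list
#'   of numeric vectors (see [read_word2vec()], [read_embeddings_json()]).
#' @return a label embedding table: numeric matrix with `labels` as rownames.
#' @examples
#' src <- list(pleural = c(1, 0), effusion = c(0, 1))
#' embed_labels("pleural_effusion", src)   # (0.5, 0.5)
#' @export
embed_labels <- function(labels, source) {
  if (length(labels) == 0L) stop("no labels supplied")
  if (anyDuplicated(labels)) stop("labels must be unique")
  if (any(!nzchar(labels))) stop("labels must be non-empty strings")
  src <- as_embedding_source(source)
  u <- ncol(src)
  vecs <- matrix(NA_real_, length(labels), u, dimnames = list(labels, NULL))
  for (i in seq_along(labels)) {
    key <- tolower(labels[[i]])
    if (key %in% rownames(src)) {
      vecs[i, ] <- src[key, ]
    } else {
      tokens <- strsplit(key, "[ _]+")[[1L]]
      tokens <- tokens[nzchar(tokens)]
      hit <- tokens[tokens %in% rownames(src)]
      if (length(hit) == 0L)
        stop("label '", labels[[i]], "' has no token in the embedding source")
      vecs[i, ] <- colMeans(src[hit, , drop = FALSE])
    }
    if (!all(is.finite(vecs[i, ])))
      stop("non-finite embedding for label '", labels[[i]], "'")
    if (sqrt(sum(vecs[i, ]^2)) == 0)
      stop("zero-norm embedding for label '", labels[[i]], "'")
  }
  validate_embedding_table(vecs)
}

#' Validate a label embedding table
#'
#' Checks uniqueness of labels, finiteness and strictly positive row norms.
#'
#' @param table numeric matrix with label rownames.
#' @return the table, invisibly unchanged, or an error.
#' @export
validate_embedding_table <- function(table) {
  stopifnot(is.matrix(table), is.numeric(table))
  if (is.null(rownames(table))) stop("embedding table must have label rownames")
  if (anyDuplicated(rownames(table))) stop("embedding table labels must be unique")
  if (!all(is.finite(table))) stop("embedding table has non-finite entries")
  if (any(row_norms(table) == 0)) stop("embedding table has zero-norm rows")
  table
}
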