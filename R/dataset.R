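#' Labeled feature dataset
#'
#' Container pairing an n x d feature matrix with structural-class labels
#' and unique protein ids. Produced by [extract_dataset()] or
#' [make_feature_dataset()]; consumed by the selection, classification and
#' evaluation stages.
#'
#' @param x Numeric n x d matrix.
#' @param labels Length-n vector of class labels (coerced to factor).
#' @param ids Length-n unique identifiers; defaults to rownames of `x`.
#' @return An object of class `"pssm_dataset"`: list with elements `x`,
#'   `labels`, `ids`.
#' @export
pssm_dataset <- function(x, labels, ids = rownames(x)) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (is.null(ids)) ids <- sprintf("P%04d", seq_len(n))
  ids <- as.character(ids)
  labels <- factor(labels)
  if (length(labels) != n || length(ids) != n)
    stop("labels (", length(labels), ") and ids (", length(ids),
         ") must both match nrow(x) = ", n)
  if (anyDuplicated(ids))
    stop("duplicate protein ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyNA(x)) stop("feature matrix contains missing values")
  rownames(x) <- ids
  structure(list(x = x, labels = labels, ids = ids), class = "pssm_dataset")
}

#' @export
print.pssm_dataset <- function(x, ...) {
  cat("Labeled PSSM feature dataset:", nrow(x$x), "proteins x",
      ncol(x$x), "features\n")
  print(table(class = x$labels))
  invisible(x)
}

#' @export
dim.pssm_dataset <- function(x) dim(x$x)

# Subset a dataset by row index, preserving factor levels.
subset_dataset <- function(data, rows) {
  out <- structure(list(x = data$x[rows, , drop = FALSE],
                        labels = data$labels[rows],
                        ids = data$ids[rows]),
                   class = "pssm_dataset")
  attr(out, "max_gap") <- attr(data, "max_gap")
  out
}

#' Write / read a labeled feature dataset as TSV
#'
#' Layout: first column `protein_id`, second column `class` (literal "NA"
#' when a label is absent), then one column per feature named
#' `g{g}_{aa_i}{aa_j}`. Values are written at full double precision so a
#' write/read cycle is lossless.
#'
#' @param data A [pssm_dataset()].
#' @param file Path.
#' @return `write_dataset_tsv` returns `file` invisibly; `read_dataset_tsv`
#'   returns a [pssm_dataset()].
#' @export
write_dataset_tsv <- function(data, file) {
  stopifnot(inherits(data, "pssm_dataset"))
  hdr <- c("protein_id", "class", colnames(data$x))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  body <- cbind(data$ids, as.character(data$labels),
                matrix(num_format(data$x), nrow(data$x)))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(file)
}

#' @rdname write_dataset_tsv
#' @export
read_dataset_tsv <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("protein_id", "class") %in% names(df)[1:2]))
    stop("not a feature TSV: first columns must be protein_id, class")
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(x) <- "double"
  pssm_dataset(x, df$class, df$protein_id)
}
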