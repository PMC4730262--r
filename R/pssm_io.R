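#' Construct a PSSM profile object
#'
#' A profile couples an L x 20 score matrix with its query sequence. The 20
#' columns always follow the PSI-BLAST header order ([AA_ORDER]); row k holds
#' the per-amino-acid scores for sequence position k. Profiles are either raw
#' (log-odds scores, any sign) or sigmoid-scaled into (0, 1); downstream
#' feature extraction requires the scaled form.
#'
#' @param matrix Numeric L x 20 matrix of per-position scores.
#' @param sequence Character scalar, the query sequence (length L).
#'   Non-standard residue letters (X, B, Z, U, ...) are accepted: PSI-BLAST
#'   emits score rows for such positions and they carry information.
#' @param scaled Logical; `TRUE` if entries have already been mapped into
#'   (0, 1) by [sigmoid_scale()].
#' @param id Optional identifier string.
#' @return An object of class `"pssm_profile"`.
#' @seealso [parse_pssm()], [sigmoid_scale()]
#' @export
pssm_profile <- function(matrix, sequence, scaled = FALSE, id = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  sequence <- as.character(sequence)
  if (length(sequence) != 1L || nchar(sequence) < 1L)
    stop("'sequence' must be a single non-empty string")
  if (ncol(matrix) != 20L)
    stop("profile matrix must have exactly 20 columns, got ", ncol(matrix))
  if (nrow(matrix) != nchar(sequence))
    stop("matrix has ", nrow(matrix), " rows but sequence has ",
         nchar(sequence), " residues")
  if (anyNA(matrix)) stop("profile matrix contains missing values")
  if (isTRUE(scaled) && (any(matrix <= 0) || any(matrix >= 1)))
    stop("scaled profile entries must lie strictly within (0, 1)")
  colnames(matrix) <- AA_ORDER
  rownames(matrix) <- NULL
  structure(
    list(matrix = matrix, sequence = sequence, scaled = isTRUE(scaled),
         id = if (is.null(id)) NA_character_ else as.character(id)),
    class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("PSSM profile", if (!is.na(x$id)) paste0("'", x$id, "'"), "\n")
  cat("  length:", nrow(x$matrix), "residues;",
      if (x$scaled) "sigmoid-scaled (0,1)" else "raw log-odds scores", "\n")
  seq_show <- x$sequence
  if (nchar(seq_show) > 60) seq_show <- paste0(substr(seq_show, 1, 57), "...")
  cat("  sequence:", seq_show, "\n")
  invisible(x)
}

#' @export
dim.pssm_profile <- function(x) dim(x$matrix)

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the text format produced by `psiblast -out_ascii_pssm`: a title
#' line, a header row of 40 amino-acid letters, then one row per query
#' position carrying the position index, the residue letter, 20 integer
#' log-odds scores, 20 weighted-percentage columns and per-position
#' statistics.
#'
#' By default the first 20-column block (log-odds scores) populates the
#' profile: these are signed values for which the sigmoid mapping into
#' (0, 1) is meaningful. The percentage block can be selected instead with
#' `block = "percent"`.
#'
#' @param file Path to an ASCII PSSM file, or a character vector of lines.
#' @param block Which 20-column block to keep: `"scores"` (log-odds,
#'   default) or `"percent"` (weighted observed percentages).
#' @param id Optional identifier; defaults to the file name without
#'   extension when `file` is a path.
#' @return An unscaled [pssm_profile()].
#' @examples
#' pssm <- system.file("extdata", "example.pssm", package = "pssmclass")
#' prof <- parse_pssm(pssm)
#' prof
#' @export
parse_pssm <- function(file, block = c("scores", "percent"), id = NULL) {
  block <- match.arg(block)
  if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    lines <- readLines(file, warn = FALSE)
    if (is.null(id))
      id <- sub("\\.[A-Za-z0-9]+$", "", basename(file))
  } else {
    lines <- unlist(strsplit(as.character(file), "\n", fixed = TRUE))
  }
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])

  is_header <- vapply(toks, function(tk)
    length(tk) >= 40L && all(tk[seq_len(40L)] %in% AA_ORDER), logical(1))
  hdr <- which(is_header)
  if (length(hdr) == 0L)
    stop("malformed header: no line with the 40 amino-acid column labels found")
  hdr <- hdr[1L]
  hdr_aa <- toks[[hdr]][1:20]

  is_data <- vapply(seq_along(toks), function(i) {
    tk <- toks[[i]]
    i > hdr && length(tk) >= 2L && grepl("^[0-9]+$", tk[1L]) &&
      grepl("^[A-Za-z]$", tk[2L])
  }, logical(1))
  rows <- which(is_data)
  # the data block is contiguous; stop at the first non-data line after it
  if (length(rows)) rows <- rows[seq_len(which.max(diff(c(rows, Inf)) > 1))]
  if (length(rows) == 0L) stop("no positions: PSSM file has an empty data block")

  n <- length(rows)
  mat <- matrix(NA_real_, n, 20L)
  residues <- character(n)
  for (r in seq_len(n)) {
    tk <- toks[[rows[r]]]
    nnum <- length(tk) - 2L
    # psiblast emits 40 numeric columns, plus 2 per-position statistics
    if (!(nnum %in% c(40L, 42L)))
      stop("line ", rows[r], ": expected 20 score and 20 percentage columns, ",
           "found ", nnum, " numeric fields")
    vals <- suppressWarnings(as.numeric(tk[3:42]))
    if (anyNA(vals))
      stop("line ", rows[r], ": non-numeric score field '",
           tk[2L + which(is.na(vals))[1L]], "'")
    sel <- if (block == "scores") vals[1:20] else vals[21:40]
    # map from the file's header order onto the canonical column order
    mat[r, ] <- sel[match(AA_ORDER, hdr_aa)]
    residues[r] <- toupper(tk[2L])
  }
  pssm_profile(mat, paste(residues, collapse = ""), scaled = FALSE, id = id)
}

#' Sigmoid-scale a raw PSSM profile
#'
#' Maps every log-odds entry x into (0, 1) through the logistic function
#' f(x) = 1 / (1 + exp(-x)). Scaling an already-scaled profile is refused:
#' applying the sigmoid twice silently compresses all values into
#' (0.5, 0.73) and corrupts the features.
#'
#' @param profile An unscaled [pssm_profile()].
#' @return The profile with every entry transformed and `scaled = TRUE`.
#' @export
sigmoid_scale <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  if (profile$scaled)
    stop("profile is already sigmoid-scaled; refusing to scale twice")
  pssm_profile(1 / (1 + exp(-profile$matrix)), profile$sequence,
               scaled = TRUE, id = profile$id)
}

#' Write / read a profile as TSV
#'
#' A plain tab-separated dump (position, residue, 20 score columns) for
#' inspection and lossless round trips. Values are written at full double
#' precision.
#'
#' @param profile A [pssm_profile()].
#' @param file Output (or input) path.
#' @return `write_pssm_tsv` returns `file` invisibly; `read_pssm_tsv`
#'   returns a [pssm_profile()].
#' @export
write_pssm_tsv <- function(profile, file) {
  stopifnot(inherits(profile, "pssm_profile"))
  res <- strsplit(profile$sequence, "")[[1]]
  df <- data.frame(position = seq_along(res), residue = res,
                   stringsAsFactors = FALSE)
  for (j in seq_len(20L)) df[[AA_ORDER[j]]] <- num_format(profile$matrix[, j])
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(c("#scaled", profile$scaled, "id", profile$id),
                   collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_pssm_tsv
#' @export
read_pssm_tsv <- function(file) {
  first <- readLines(file, n = 1L)
  meta <- strsplit(first, "\t", fixed = TRUE)[[1]]
  df <- utils::read.delim(file, skip = 1L, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, AA_ORDER, drop = FALSE])
  id <- if (length(meta) >= 4L && !identical(meta[4], "NA")) meta[4] else NULL
  pssm_profile(mat, paste(df$residue, collapse = ""),
               scaled = identical(meta[2], "TRUE"), id = id)
}

#' Run PSI-BLAST to produce an ASCII PSSM (convenience wrapper)
#'
#' Thin, untested wrapper around the `psiblast` executable. The profile
#' protocol used throughout this package is 3 iterations against NR with an
#' E-value cutoff of 0.001; building against a local database or a subject
#' sequence (`-subject`) also works for quick experiments. Requires BLAST+
#' on the PATH and is never invoked by the package itself.
#'
#' @param query Path to a FASTA file with the query sequence.
#' @param db BLAST database name (e.g. `"nr"`), or `NULL` to use `subject`.
#' @param subject Optional FASTA path used with `-subject` instead of a
#'   database.
#' @param out_pssm Output path for the ASCII PSSM.
#' @param iterations,evalue PSI-BLAST search parameters.
#' @return `out_pssm`, invisibly.
#' @export
run_psiblast <- function(query, db = NULL, subject = NULL, out_pssm,
                         iterations = 3, evalue = 0.001) {
  args <- c("-query", query, "-num_iterations", iterations,
            "-evalue", evalue, "-out_ascii_pssm", out_pssm,
            "-save_pssm_after_last_round")
  if (!is.null(db)) args <- c(args, "-db", db)
  else if (!is.null(subject)) args <- c(args, "-subject", subject)
  else stop("provide either 'db' or 'subject'")
  status <- system2("psiblast", args)
  if (status != 0L) stop("psiblast exited with status ", status)
  invisible(out_pssm)
}
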