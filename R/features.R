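#' Dipeptide composition from a scaled PSSM profile
#'
#' For a sigmoid-scaled profile with entries p[k, i], the dipeptide
#' composition (DPC) is the 400-vector
#' \deqn{x_{i,j} = \sum_{k=1}^{L-1} p_{k,i} \, p_{k+1,j}, \quad 1 \le i,j \le 20,}
#' the profile-weighted count of each ordered amino-acid pair at adjacent
#' positions. [gapdpc()] generalises this to pairs separated by a gap of g
#' positions, and [feature_vector()] concatenates the blocks for
#' g = 0, ..., G into the full gapped-dipeptide composition (GapDPC)
#' representation.
#'
#' Element (i, j) sits at flat position (i-1)*20 + j within its block, i.e.
#' the first amino-acid index varies slowest; names follow the pattern
#' `g{g}_{aa_i}{aa_j}`.
#'
#' @param profile A sigmoid-scaled [pssm_profile()].
#' @return Named numeric vector of length 400.
#' @export
dpc <- function(profile) gapdpc(profile, 0L)

#' Gapped-dipeptide composition for one gap size
#'
#' Computes the 400-vector
#' \deqn{y_{i,j,g} = \sum_{k=1}^{L-g-1} p_{k,i} \, p_{k+g+1,j}}
#' for a single gap g (g = 0 recovers [dpc()]). The sum is a raw,
#' unnormalised count: longer sequences yield larger values. Optional
#' division by the number of summands (L - g - 1) is available via
#' `normalize`.
#'
#' @param profile A sigmoid-scaled [pssm_profile()].
#' @param g Nonnegative integer gap; requires L >= g + 2.
#' @param normalize Divide by L - g - 1 so features are length-free.
#'   Off by default: the raw sum is the canonical definition.
#' @return Named numeric vector of length 400, ordering as in [dpc()].
#' @export
gapdpc <- function(profile, g, normalize = FALSE) {
  stopifnot(inherits(profile, "pssm_profile"))
  if (!profile$scaled)
    stop("profile must be sigmoid-scaled before feature extraction; ",
         "see sigmoid_scale()")
  g <- as.integer(g)
  if (length(g) != 1L || is.na(g) || g < 0L) stop("'g' must be a single nonnegative integer")
  L <- nrow(profile$matrix)
  if (L < 2L) stop("sequence too short for dipeptides (L = ", L, ")")
  if (L < g + 2L)
    stop("gap exceeds sequence capacity: g = ", g, " needs L >= ", g + 2L,
         " but L = ", L)
  P <- profile$matrix
  m <- crossprod(P[seq_len(L - g - 1L), , drop = FALSE],
                 P[(g + 2L):L, , drop = FALSE])
  if (normalize) m <- m / (L - g - 1L)
  v <- as.vector(t(m))  # i-major flattening
  names(v) <- feature_names(0L)
  names(v) <- sub("^g0_", paste0("g", g, "_"), names(v))
  v
}

#' Assemble the full GapDPC feature vector
#'
#' Concatenates [gapdpc()] blocks for g = 0, 1, ..., `max_gap` in ascending
#' order, giving 400 * (max_gap + 1) features per protein (3600 for the
#' default G = 8). Requires L >= max_gap + 2 so that even the widest block
#' has at least one summand.
#'
#' @param profile A sigmoid-scaled [pssm_profile()].
#' @param max_gap Largest gap G (default 8).
#' @param normalize Passed to [gapdpc()].
#' @return Named numeric vector of length 400 * (max_gap + 1), with
#'   attribute `max_gap`.
#' @examples
#' prof <- make_pssm(30, seed = 1)
#' length(feature_vector(prof, max_gap = 8))  # 3600
#' @export
feature_vector <- function(profile, max_gap = 8L, normalize = FALSE) {
  stopifnot(inherits(profile, "pssm_profile"))
  max_gap <- as.integer(max_gap)
  if (length(max_gap) != 1L || is.na(max_gap) || max_gap < 0L)
    stop("'max_gap' must be a single nonnegative integer")
  L <- nrow(profile$matrix)
  if (L < max_gap + 2L)
    stop("sequence of length ", L, " is too short for max_gap = ", max_gap,
         "; minimum admissible length is ", max_gap + 2L)
  v <- unlist(lapply(0:max_gap, function(g) gapdpc(profile, g, normalize)),
              use.names = TRUE)
  attr(v, "max_gap") <- max_gap
  v
}

#' Names and decoding of GapDPC feature indices
#'
#' The flat feature order is g-major, then first amino acid i, then second
#' amino acid j: 1-based flat index g*400 + (i-1)*20 + j. `feature_names`
#' lists the names for all gaps up to `max_gap`; `decode_feature_index`
#' maps flat indices back to their (g, aa_i, aa_j) triple.
#'
#' @param max_gap Largest gap G.
#' @param index Integer vector of 1-based flat feature indices.
#' @return `feature_names`: character vector of length 400 * (max_gap + 1).
#'   `decode_feature_index`: data frame with columns `index`, `g`, `aa_i`,
#'   `aa_j`, `name`.
#' @export
feature_names <- function(max_gap = 0L) {
  unlist(lapply(0:max_gap, function(g)
    paste0("g", g, "_", rep(AA_ORDER, each = 20L), rep(AA_ORDER, 20L))))
}

#' @rdname feature_names
#' @export
decode_feature_index <- function(index) {
  index <- as.integer(index)
  if (any(is.na(index) | index < 1L)) stop("feature indices must be positive integers")
  z <- index - 1L
  g <- z %/% 400L
  i <- (z %% 400L) %/% 20L + 1L
  j <- z %% 20L + 1L
  data.frame(index = index, g = g, aa_i = AA_ORDER[i], aa_j = AA_ORDER[j],
             name = paste0("g", g, "_", AA_ORDER[i], AA_ORDER[j]),
             stringsAsFactors = FALSE)
}

#' Build a labeled feature dataset from profiles
#'
#' Extracts the GapDPC [feature_vector()] of every profile and stacks them
#' into an n x 400*(G+1) matrix with aligned class labels. Rows are ordered
#' by protein id (lexicographic) so the result is deterministic regardless
#' of input order.
#'
#' @param profiles List of sigmoid-scaled [pssm_profile()] objects. Ids are
#'   taken from list names, or from each profile's `id` field.
#' @param labels Named character/factor vector mapping protein id to
#'   structural class.
#' @param max_gap Largest gap G (default 8).
#' @param normalize Passed to [gapdpc()].
#' @return A [pssm_dataset()] with attribute `max_gap`.
#' @export
extract_dataset <- function(profiles, labels, max_gap = 8L, normalize = FALSE) {
  if (length(profiles) == 0L) stop("empty profile collection")
  ids <- names(profiles)
  if (is.null(ids))
    ids <- vapply(profiles, function(p) p$id, character(1))
  if (anyNA(ids) || any(ids == ""))
    stop("every profile needs an id (list names or profile$id)")
  if (anyDuplicated(ids))
    stop("duplicate protein ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  missing <- setdiff(ids, names(labels))
  if (length(missing))
    stop("no class label for: ", paste(missing, collapse = ", "))
  ord <- order(ids)
  ids <- ids[ord]
  profiles <- profiles[ord]
  too_short <- vapply(profiles, function(p) nrow(p$matrix) < max_gap + 2L,
                      logical(1))
  if (any(too_short))
    stop("profile too short for max_gap = ", max_gap, ": ",
         paste(ids[too_short], collapse = ", "))
  x <- t(vapply(profiles, feature_vector, numeric(400L * (max_gap + 1L)),
                max_gap = max_gap, normalize = normalize))
  rownames(x) <- ids
  out <- pssm_dataset(x, as.character(labels[ids]), ids)
  attr(out, "max_gap") <- as.integer(max_gap)
  out
}
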