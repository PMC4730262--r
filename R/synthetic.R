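# Internal: one profile row — a renormalized positive random vector.
# sharpness exponentiates the draws, so large values approach one-hot rows.
random_profile_rows <- function(L, sharpness) {
  v <- matrix(stats::runif(L * 20L), L, 20L)^sharpness
  # extreme sharpness underflows the small entries; floor them relative to
  # the row maximum so normalized rows stay strictly inside (0, 1)
  v <- pmax(v, apply(v, 1L, max) * 1e-12)
  v / rowSums(v)
}

#' Generate a synthetic PSSM profile
#'
#' Draws an L x 20 matrix of strictly (0, 1) entries whose rows are
#' renormalized positive random vectors; `sharpness` exponentiates the
#' draws, so high values give near-indicator (one-hot-like) rows. The raw
#' (unscaled) form is obtained through the inverse sigmoid
#' log(p / (1 - p)), so `sigmoid_scale()` recovers the scaled matrix
#' exactly and the raw-to-scaled path can be exercised end to end.
#'
#' @param length Sequence length L >= 1.
#' @param seed Integer seed; the profile is a pure function of it.
#' @param sharpness Positive real controlling row contrast (default 2).
#' @param scaled Return the scaled profile (default) or its raw log-odds
#'   preimage.
#' @param id Optional identifier.
#' @return A [pssm_profile()].
#' @export
make_pssm <- function(length, seed = 1L, sharpness = 2, scaled = TRUE,
                      id = NULL) {
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("'length' must be a positive integer")
  if (sharpness <= 0) stop("'sharpness' must be positive")
  with_seed(seed, {
    p <- random_profile_rows(length, sharpness)
    seq <- paste(AA_ORDER[max.col(p)], collapse = "")
  })
  if (scaled) pssm_profile(p, seq, scaled = TRUE, id = id)
  else pssm_profile(log(p / (1 - p)), seq, scaled = FALSE, id = id)
}

# Structural class names used when up to four classes are generated.
CLASS_NAMES <- c("all-alpha", "all-beta", "alpha/beta", "alpha+beta")

# Decode 1-based flat GapDPC indices to (g, i, j) triples.
flat_to_triple <- function(flat) {
  z <- flat - 1L
  cbind(g = z %/% 400L, i = (z %% 400L) %/% 20L + 1L, j = z %% 20L + 1L)
}

#' Generate labeled synthetic profiles with class-specific dipeptide signal
#'
#' Emulates a structural-class dataset: every protein gets a random scaled
#' profile, and for each class a private set of gapped dipeptide
#' propensities (amino-acid pair (i, j) at gap g) is planted by mixing
#' near-indicator rows into the profile at randomly chosen, non-overlapping
#' position pairs. The GapDPC features at the planted (i, j, g) indices
#' therefore have class-shifted means, while single-residue composition
#' carries essentially no class information — the signal lives at the
#' dipeptide-pair level, which is what the GapDPC representation exploits.
#'
#' `class_signal` sets the per-slot planting probability
#' `min(1, class_signal / 4)`: 0 makes the classes indistinguishable, and
#' around 3 the planted pairs dominate the profile.
#'
#' @param n_per_class Proteins per class.
#' @param n_classes Number of classes, 2..4 (named all-alpha, all-beta,
#'   alpha/beta, alpha+beta).
#' @param length_range Integer (L_min, L_max); L_min must be >= max_gap + 2.
#' @param class_signal Nonnegative effect size (see above).
#' @param n_informative_pairs Planted (i, j, g) propensities per class.
#' @param max_gap Largest gap used for planting and intended for
#'   extraction.
#' @param sharpness Background row contrast, as in [make_pssm()].
#' @param seed Integer seed; output is a pure function of it.
#' @return List with `profiles` (named list of scaled profiles), `labels`
#'   (named factor), `informative` (sorted 1-based flat feature indices in
#'   the 400*(max_gap+1)-dimensional GapDPC space), and `triples` (per-class
#'   planted (g, i, j) tables).
#' @export
make_classed_profiles <- function(n_per_class = 30L, n_classes = 4L,
                                  length_range = c(30L, 60L),
                                  class_signal = 1, n_informative_pairs = 8L,
                                  max_gap = 4L, sharpness = 2, seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L || n_classes > 4L) stop("'n_classes' must be 2..4")
  if (n_per_class < 1L) stop("'n_per_class' must be positive")
  if (class_signal < 0) stop("'class_signal' must be nonnegative")
  max_gap <- as.integer(max_gap)
  d_space <- 400L * (max_gap + 1L)
  if (n_informative_pairs > d_space)
    stop("n_informative_pairs (", n_informative_pairs,
         ") exceeds the feature space size (", d_space, ")")
  if (n_classes * n_informative_pairs > d_space)
    stop("not enough distinct (i, j, g) triples for ", n_classes,
         " disjoint class signatures")
  if (length_range[1] < max_gap + 2L)
    stop("L_min must be at least max_gap + 2 = ", max_gap + 2L)

  classes <- CLASS_NAMES[seq_len(n_classes)]
  p_site <- min(1, class_signal / 4)
  with_seed(seed, {
    pool <- sample.int(d_space, n_classes * n_informative_pairs)
    triples <- lapply(seq_len(n_classes), function(c)
      flat_to_triple(pool[((c - 1L) * n_informative_pairs + 1L):
                          (c * n_informative_pairs)]))
    names(triples) <- classes

    n <- n_per_class * n_classes
    profiles <- vector("list", n)
    labels <- rep(classes, each = n_per_class)
    ids <- sprintf("P%04d", seq_len(n))
    for (s in seq_len(n)) {
      L <- sample(length_range[1]:length_range[2], 1L)
      p <- random_profile_rows(L, sharpness)
      used <- logical(L)
      tri <- triples[[labels[s]]]
      for (t in seq_len(nrow(tri))) {
        g <- tri[t, "g"]; i <- tri[t, "i"]; j <- tri[t, "j"]
        n_slots <- max(0L, (L - g - 1L) %/% (g + 2L))
        if (n_slots == 0L || p_site == 0) next
        n_plant <- stats::rbinom(1L, n_slots, p_site)
        if (n_plant == 0L) next
        cand <- seq_len(L - g - 1L)
        cand <- if (length(cand) > 1L) sample(cand) else cand
        planted <- 0L
        for (k in cand) {
          if (planted >= n_plant) break
          if (used[k] || used[k + g + 1L]) next
          p[k, ] <- 0.1 * p[k, ] + 0.9 * (seq_len(20L) == i)
          p[k + g + 1L, ] <- 0.1 * p[k + g + 1L, ] + 0.9 * (seq_len(20L) == j)
          used[c(k, k + g + 1L)] <- TRUE
          planted <- planted + 1L
        }
      }
      profiles[[s]] <- pssm_profile(p, paste(AA_ORDER[max.col(p)],
                                             collapse = ""),
                                    scaled = TRUE, id = ids[s])
    }
  })
  names(profiles) <- ids
  labels <- factor(labels, levels = classes)
  names(labels) <- ids
  list(profiles = profiles, labels = labels,
       informative = sort(pool), triples = triples)
}

#' Generate a labeled Gaussian feature dataset with informative columns
#'
#' Direct test bed for the selection and classification stages: an
#' n x d standard-normal feature table in which `n_informative` columns
#' receive class-dependent mean offsets of +/- effect/2, with the signs
#' balanced across classes so every informative column separates some pair
#' of classes by `effect` standard deviations.
#'
#' @param n_per_class Samples per class.
#' @param d Total feature count.
#' @param n_informative Number of class-informative columns.
#' @param effect Between-class mean separation in SD units (0 = null).
#' @param n_classes Number of classes, 2..4.
#' @param seed Integer seed; output is a pure function of it.
#' @return List with `data` (a [pssm_dataset()]) and `informative`
#'   (sorted column indices carrying signal).
#' @export
make_feature_dataset <- function(n_per_class = 40L, d = 200L,
                                 n_informative = 10L, effect = 2,
                                 n_classes = 4L, seed = 1L) {
  if (n_informative > d)
    stop("n_informative (", n_informative, ") exceeds d (", d, ")")
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L || n_classes > 4L) stop("'n_classes' must be 2..4")
  classes <- CLASS_NAMES[seq_len(n_classes)]
  n <- n_per_class * n_classes
  labels <- rep(classes, each = n_per_class)
  with_seed(seed, {
    informative <- sort(sample.int(d, n_informative))
    x <- matrix(stats::rnorm(n * d), n, d)
    for (col in informative) {
      signs <- sample(rep_len(c(1, -1), n_classes))
      x[, col] <- x[, col] + (effect / 2) * signs[match(labels, classes)]
    }
  })
  colnames(x) <- sprintf("f%04d", seq_len(d))
  data <- pssm_dataset(x, factor(labels, levels = classes),
                       sprintf("P%04d", seq_len(n)))
  list(data = data, informative = informative)
}

#' Write a profile as a PSI-BLAST-style ASCII PSSM file
#'
#' Emits the `-out_ascii_pssm` layout (title, 40-letter header, one data
#' row per position with rounded integer scores, a weighted-percentage
#' block and per-position statistics, trailing Lambda/K lines) so the
#' [parse_pssm()] path can be exercised without running PSI-BLAST. Scores
#' are rounded to integers, as in real files; pass an integer-valued raw
#' profile for lossless round trips.
#'
#' @param profile An unscaled [pssm_profile()].
#' @param file Path.
#' @return `file`, invisibly.
#' @export
write_pssm_ascii <- function(profile, file) {
  stopifnot(inherits(profile, "pssm_profile"))
  if (profile$scaled)
    stop("ASCII PSSM files carry raw log-odds scores; got a scaled profile")
  m <- round(profile$matrix)
  sig <- 1 / (1 + exp(-profile$matrix))
  pct <- round(100 * sig / rowSums(sig))
  res <- strsplit(profile$sequence, "")[[1]]
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapless real matches to pseudocounts"),
    paste0("         ", paste(sprintf("%3s", c(AA_ORDER, AA_ORDER)),
                              collapse = " "))), con)
  for (k in seq_len(nrow(m))) {
    writeLines(paste0(sprintf("%5d %s ", k, res[k]),
                      paste(sprintf("%3d", m[k, ]), collapse = " "), "  ",
                      paste(sprintf("%3d", pct[k, ]), collapse = " "),
                      sprintf("  %4.2f %8.2f", 0, 0)), con)
  }
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1340     0.3172",
               "Standard Gapped      0.0410     0.2670",
               "PSI Ungapped         0.1340     0.3172",
               "PSI Gapped           0.0410     0.2670"), con)
  invisible(file)
}
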