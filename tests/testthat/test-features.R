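test_that("dpc of near-indicator rows is the corresponding unit pair", {
  i0 <- 3; j0 <- 17
  m <- rbind(indicator_row(i0), indicator_row(j0))
  v <- dpc(profile_from_matrix(m))
  expect_equal(unname(v[(i0 - 1) * 20 + j0]), 1, tolerance = 1e-6)
  expect_lt(max(v[-((i0 - 1) * 20 + j0)]), 1e-6)
  expect_length(v, 400)
})

test_that("dpc of a constant profile has the closed-form value (L-1)c^2", {
  for (L in c(2, 5, 11)) {
    for (cc in c(0.1, 0.5, 0.9)) {
      v <- dpc(constant_profile(L, cc))
      expect_equal(unname(v), rep((L - 1) * cc^2, 400))
    }
  }
})

test_that("dpc and gapdpc agree with the naive triple-loop oracle", {
  set.seed(101)
  for (rep in 1:20) {
    L <- sample(3:20, 1)
    prof <- make_pssm(L, seed = rep)
    for (g in sample(0:(L - 2), min(3, L - 1))) {
      expect_equal(unname(gapdpc(prof, g)), naive_gapdpc(prof$matrix, g),
                   tolerance = 1e-12)
    }
    expect_equal(unname(dpc(prof)), naive_gapdpc(prof$matrix, 0),
                 tolerance = 1e-12)
  }
})

test_that("gapdpc with g = 0 equals dpc exactly", {
  for (s in 1:5) {
    prof <- make_pssm(sample(5:25, 1), seed = s)
    expect_identical(unname(gapdpc(prof, 0)), unname(dpc(prof)))
  }
})

test_that("unit-row-sum profiles give block sums of L - g - 1", {
  # make_pssm rows are renormalized, so each row sums to 1
  for (s in 1:5) {
    L <- 10 + s
    prof <- make_pssm(L, seed = s)
    for (g in c(0, 1, 4, L - 2)) {
      expect_equal(sum(gapdpc(prof, g)), L - g - 1, tolerance = 1e-10)
    }
  }
})

test_that("gapdpc values from scaled profiles are bounded in [0, L-g-1]", {
  set.seed(33)
  for (rep in 1:10) {
    L <- sample(4:30, 1)
    g <- sample(0:(L - 2), 1)
    v <- gapdpc(make_pssm(L, seed = rep * 7), g)
    expect_true(all(v >= 0))
    expect_true(all(v <= L - g - 1))
  }
})

test_that("feature_vector concatenates gapdpc blocks in ascending g", {
  prof <- make_pssm(20, seed = 4)
  G <- 5
  v <- feature_vector(prof, G)
  expect_length(v, 400 * (G + 1))
  for (g in 0:G) {
    expect_equal(unname(v[(g * 400 + 1):((g + 1) * 400)]),
                 unname(gapdpc(prof, g)))
  }
  # G-monotone nesting: feature_vector(P, G) is a prefix of (P, G+1)
  v6 <- feature_vector(prof, G + 1)
  expect_identical(as.numeric(v6[seq_along(v)]), as.numeric(v))
  # canonical dimensions
  expect_length(feature_vector(prof, 8), 3600)
  expect_length(feature_vector(prof, 0), 400)
})

test_that("feature extraction rejects invalid inputs", {
  raw <- make_pssm(10, seed = 2, scaled = FALSE)
  expect_error(dpc(raw), "scaled")
  expect_error(gapdpc(make_pssm(5, seed = 1), 4), "gap exceeds")
  expect_error(feature_vector(make_pssm(5, seed = 1), 8),
               "minimum admissible length is 10")
  one <- constant_profile(2, 0.5)
  expect_error(gapdpc(one, 1), "gap exceeds")
})

test_that("permuting profile columns permutes feature blocks consistently", {
  prof <- make_pssm(12, seed = 8)
  set.seed(8)
  perm <- sample(20)
  prof_p <- pssm_profile(prof$matrix[, perm], prof$sequence, scaled = TRUE)
  for (g in c(0, 2)) {
    v <- matrix(gapdpc(prof, g), 20, 20, byrow = TRUE)    # v[i, j]
    vp <- matrix(gapdpc(prof_p, g), 20, 20, byrow = TRUE)
    # relabeling i, j by the permutation leaves values unchanged
    expect_equal(unname(vp), unname(v[perm, perm]))
  }
})

test_that("flat index convention decodes to (g, aa_i, aa_j)", {
  # 1-based flat index g*400 + (i-1)*20 + j
  dec <- decode_feature_index(c(1, 400, 401, 2 * 400 + 20 * 3 + 5))
  expect_equal(dec$g, c(0, 0, 1, 2))
  expect_equal(dec$aa_i, c("A", "V", "A", AA_ORDER[4]))
  expect_equal(dec$aa_j, c("A", "V", "A", AA_ORDER[5]))
  expect_identical(feature_names(1)[401], "g1_AA")
  # names produced by feature_vector follow the same convention
  prof <- make_pssm(10, seed = 1)
  v <- feature_vector(prof, 2)
  expect_identical(names(v), feature_names(2))
})

test_that("extract_dataset stacks per-protein feature vectors sorted by id", {
  gen <- make_classed_profiles(n_per_class = 1, n_classes = 4,
                               length_range = c(12, 20), class_signal = 2,
                               max_gap = 2, seed = 21)
  ds <- extract_dataset(gen$profiles, gen$labels, max_gap = 2)
  expect_s3_class(ds, "pssm_dataset")
  expect_equal(dim(ds$x), c(4, 1200))
  expect_identical(ds$ids, sort(names(gen$profiles)))
  for (id in ds$ids) {
    expect_equal(as.numeric(ds$x[id, ]),
                 as.numeric(feature_vector(gen$profiles[[id]], 2)))
  }
  # shuffling the input order changes nothing
  ds2 <- extract_dataset(rev(gen$profiles), gen$labels, max_gap = 2)
  expect_identical(ds2$x, ds$x)
  expect_identical(as.character(ds2$labels), as.character(ds$labels))
})

test_that("extract_dataset validates labels, ids and lengths", {
  gen <- make_classed_profiles(n_per_class = 2, n_classes = 2,
                               length_range = c(8, 10), max_gap = 2, seed = 3)
  expect_error(extract_dataset(list(), gen$labels), "empty")
  labs <- gen$labels[-1]
  expect_error(extract_dataset(gen$profiles, labs, max_gap = 2),
               names(gen$labels)[1])
  dup <- gen$profiles[c(1, 1, 2)]
  expect_error(extract_dataset(dup, gen$labels, max_gap = 2), "duplicate")
  expect_error(extract_dataset(gen$profiles, gen$labels, max_gap = 30),
               "too short")
})

test_that("feature TSV write/read round-trips a labeled dataset", {
  syn <- make_feature_dataset(n_per_class = 3, d = 12, n_informative = 4,
                              effect = 1, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dataset_tsv(syn$data, path)
  back <- read_dataset_tsv(path)
  expect_equal(unname(back$x), unname(syn$data$x))
  expect_identical(as.character(back$labels), as.character(syn$data$labels))
  expect_identical(back$ids, syn$data$ids)
})
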