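#' Standard amino-acid column order
#'
#' The 20 amino acids in the column order used by PSI-BLAST ASCII PSSM
#' headers. Every profile matrix and every feature index in this package is
#' defined against this ordering.
#'
#' @format Character vector of length 20.
#' @export
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Full-precision numeric formatting for lossless TSV round trips.
num_format <- function(x) formatC(x, digits = 17, format = "g")
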