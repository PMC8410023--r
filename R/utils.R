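#' @keywords internal
"_PACKAGE"

# 20 standard amino acids, one-letter code
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. Mersenne-Twister + Rejection sampling are pinned so results
# are stable across R's default RNG-kind changes.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  expr
}

#' Derive a per-sample seed from a master seed and a sample identifier
#'
#' Hashes `(master_seed, sample_id)` into a 31-bit integer so that each
#' sample's downsampling (or simulation) stream is independent of which
#' other samples are present in the cohort: adding or removing a sample
#' never perturbs the draws of the others.
#'
#' @param master_seed Integer master seed for the whole run.
#' @param sample_id Character scalar identifying the sample.
#' @return A positive integer seed below 2^31.
#' @examples
#' derive_seed(42, "HC_001")
#' @export
derive_seed <- function(master_seed, sample_id) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1,
            is.character(sample_id), length(sample_id) == 1)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(master_seed) %% m
  for (code in utf8ToInt(sample_id)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 1L) + 1L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 1 && x == floor(x)
}
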