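#' @useDynLib ptmx, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dhyper pbinom runif
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# The 21-letter encoding alphabet: the 20 standard amino acids in
# alphabetical order, then '*' for terminus padding / non-standard letters.
AA_ALPHABET21 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "*")

AA20 <- AA_ALPHABET21[1:20]

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() that never falls into the scalar-x trap (sample(5, 1) != 5)
sample_from <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
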