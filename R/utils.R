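#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#' @importFrom stats rbinom rnorm runif
#' @importFrom utils read.delim write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib junctionscan, .registration = TRUE
NULL

# reverse-complement for plain character vectors over A/C/G/T/N (any other
# character becomes N)
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(.revcomp_cpp(x))
}

.BASES <- c("A", "C", "G", "T")
.BASE_INTS <- utf8ToInt(paste(.BASES, collapse = ""))

# integer codes + "not a plain base" mask; N (or any ambiguity code) never
# matches anything, including itself
.seq_ints <- function(seq) {
  v <- utf8ToInt(seq)
  list(ints = v, bad = !(v %in% .BASE_INTS))
}

.is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == as.integer(x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# evaluate `expr` with the RNG seeded to `seed`, restoring global RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}
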