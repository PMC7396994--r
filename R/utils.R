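#' Reverse complement of DNA strings
#'
#' @param seq character vector of ACGT strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  vapply(seq, cpp_revcomp, character(1), USE.NAMES = FALSE)
}

# run expr with a private RNG state seeded at `seed`, restoring the caller's
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string")
  if (nchar(seq) == 0L) stop(what, " must be non-empty")
  if (grepl("[^ACGT]", seq)) stop(what, " contains characters outside ACGT")
  invisible(seq)
}

.substr1 <- function(seq, i) substr(seq, i, i)
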