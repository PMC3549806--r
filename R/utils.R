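# Shared constants and small helpers.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes, in the conventional
#' ARNDCQEGHILKMFPSTWYV order used for all 20 x 20 tables in this package.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() AA_CODES

AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
              Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
              L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
              S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

GAP_CHARS <- c("-", ".")

## classed conditions so callers can test on error class
ppStop <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "pairPSSMError")))
}

ppWarn <- function(class, msg) {
  warning(warningCondition(msg, class = c(class, "pairPSSMWarning")))
}

## population (divide-by-N) standard deviation
popSd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

## evaluate `code` under `seed` without disturbing the caller's RNG stream
withSeed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

isStandardAA <- function(x) x %in% AA_CODES

## split sequences into character matrices etc.
seqToChars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
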