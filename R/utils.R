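## internal helpers shared across modules

#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the R random number generator seeded at
#' \code{seed}, then restores the caller's RNG state, so seeded package
#' functions do not disturb the session stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## DNA as integer codes 1:4 = A,C,G,T (transitions: 1<->3, 2<->4)
DNA_BASES <- c("A", "C", "G", "T")

dnaToInt <- function(x) {
  v <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], DNA_BASES)
  if (anyNA(v)) stop("sequence contains characters outside A/C/G/T")
  v
}

intToDna <- function(v) paste(DNA_BASES[v], collapse = "")

#' Reverse complement of a nucleotide string
#' @param x character scalar over A/C/G/T/N.
#' @return character scalar.
#' @keywords internal
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## random sequence from base probabilities p = c(A,C,G,T)
randomSeq <- function(n, p = rep(0.25, 4)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

## i.i.d. point mutations with a transition bias (ti:tv = kappa:1 per
## alternative; kappa = 2 gives P(transition) = 1/2)
mutateSeq <- function(x, rate, kappa = 2) {
  if (rate <= 0) return(x)
  v <- dnaToInt(x)
  hit <- which(runif(length(v)) < rate)
  if (length(hit)) {
    ti <- c(3L, 4L, 1L, 2L)         # A<->G, C<->T
    tv <- cbind(c(2L, 1L, 2L, 1L), c(4L, 3L, 4L, 3L))
    p_ti <- kappa / (kappa + 2)
    u <- runif(length(hit))
    new <- integer(length(hit))
    is_ti <- u < p_ti
    new[is_ti] <- ti[v[hit[is_ti]]]
    pick <- 1L + (u[!is_ti] > (p_ti + (1 - p_ti) / 2))
    new[!is_ti] <- tv[cbind(v[hit[!is_ti]], pick)]
    v[hit] <- new
  }
  intToDna(v)
}

## base probabilities c(A,C,G,T) realizing an AT content and both skews
baseProbs <- function(at_content, at_skew = 0, gc_skew = 0) {
  stopifnot(at_content >= 0, at_content <= 1)
  gc <- 1 - at_content
  c(A = at_content / 2 * (1 + at_skew),
    C = gc / 2 * (1 - gc_skew),
    G = gc / 2 * (1 + gc_skew),
    T = at_content / 2 * (1 - at_skew))[c(1, 2, 3, 4)]
}

## circular span length for 0-based half-open [start, end) with wrap
spanLength <- function(start, end, L) {
  ifelse(end >= start, end - start, L - start + end)
}
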