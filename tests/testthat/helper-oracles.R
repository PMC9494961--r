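# independent oracles and small fixture builders used across tests

# every order reachable from `order` in one TDRL step is a concatenation
# of two complementary subsequences of its anchored linearization; the
# oracle enumerates all 2^n subsets directly (independent of applyTDRL)
tdrlMergeOracle <- function(order) {
  labs <- orderLabels(order)
  n <- length(labs)
  res <- character(0)
  for (mask in 0:(2^n - 1L)) {
    inS <- bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0
    m <- c(labs[inS], labs[!inS])
    i <- match(orderAnchor(order), m)
    m <- m[c(seq(i, n), if (i > 1L) seq_len(i - 1L))]
    res <- c(res, paste(m, collapse = "|"))
  }
  sort(unique(res))
}

# reachable set produced by the implementation: all blocks x retentions
tdrlImplReachable <- function(order) {
  n <- length(orderLabels(order))
  res <- character(0)
  for (i in seq_len(n)) for (j in seq(i, n)) {
    k <- j - i + 1L
    for (mask in 0:(2^k - 1L)) {
      ret <- ifelse(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0,
                    "second", "first")
      out <- applyTDRL(order, TDRLEvent(i, j, ret))
      res <- c(res, paste(orderLabels(out), collapse = "|"))
    }
  }
  sort(unique(res))
}

# hand p-distance over gap-free sites (oracle for pDistanceMatrix)
handPDistance <- function(x, y) {
  a <- strsplit(x, "")[[1]]
  b <- strsplit(y, "")[[1]]
  ok <- a != "-" & b != "-"
  sum(a[ok] != b[ok]) / sum(ok)
}

# a tiny hand-checkable annotated genome: three abutting H-strand PCGs
# of 9 bases "ATGAAATAA" each on a 27-base genome
toyCodingGenome <- function() {
  unit <- "ATGAAATAA"
  MitoGenome("toy-coding", strrep(unit, 3L),
             data.frame(label = c("ND1", "ND2", "ND3"), kind = "PCG",
                        strand = "H",
                        start = c(0L, 9L, 18L), end = c(9L, 18L, 27L)))
}

spanLen <- function(s, e, L) ifelse(e >= s, e - s, L - s + e)

combinat_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in combinat_perms(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

randomDna <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}
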