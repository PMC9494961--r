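## control-region dissection: tandem repeats, motifs, paralog identity

#' Detect tandem repeats by deterministic period scan
#'
#' For every candidate period the sequence is compared against itself
#' shifted by that period; runs where adjacent copies agree well enough
#' become candidate arrays, which are then validated against a
#' per-column majority consensus. A candidate is accepted when its
#' consensus match fraction exceeds \code{match_threshold} and it spans
#' at least \code{min_copies} copies. Overlapping calls are resolved
#' longest-span-first, then highest consensus match; period ties (an
#' array explained at period p and 2p) go to the smallest period.
#'
#' Positions are 1-based inclusive on the input sequence. Copy numbers
#' are reported both raw and rounded (to 0.1 and to the nearest integer).
#'
#' @param seq character scalar.
#' @param min_period,max_period period search range in bases;
#'   \code{max_period} is clamped to half the sequence length with a
#'   warning.
#' @param min_copies minimum copy number before rounding.
#' @param match_threshold minimum consensus match fraction (default 0.90,
#'   exclusive).
#' @return data.frame: \code{start}, \code{end}, \code{period},
#'   \code{copy_number}, \code{copies_rounded}, \code{consensus},
#'   \code{match_fraction}; zero rows when nothing passes.
#' @export
findTandemRepeats <- function(seq, min_period = 10L, max_period = 2000L,
                              min_copies = 2, match_threshold = 0.90) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(v)
  if (max_period > n %/% 2L) {
    warning("max_period clamped to half the sequence length",
            call. = FALSE)
    max_period <- n %/% 2L
  }
  if (max_period < min_period) return(emptyRepeatTable())
  ## adjacent mutated copies agree ~ (1-mu)^2 when the consensus match is
  ## ~ (1-mu): screen candidates at the implied looser level, validate at
  ## the consensus threshold afterwards
  cand_thr <- max(0, 2 * match_threshold - 1)
  cands <- list()
  for (p in seq(min_period, max_period)) {
    m <- v[seq_len(n - p)] == v[seq(p + 1L, n)]
    nw <- n - 2L * p + 1L
    if (nw < 1L) break
    cs <- cumsum(m)
    winsum <- cs[seq(p, p + nw - 1L)] -
      c(0, cs[seq_len(nw - 1L)])
    good <- winsum / p >= cand_thr
    r <- rle(good)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values)) {
      a <- starts[ri]
      span_end <- ends[ri] + 2L * p - 1L
      rec <- evaluateRepeat(v, a, span_end, p, match_threshold)
      if (!is.null(rec) && rec$copy_number >= min_copies &&
          rec$match_fraction > match_threshold)
        cands[[length(cands) + 1L]] <- rec
    }
  }
  if (!length(cands)) return(emptyRepeatTable())
  tab <- do.call(rbind, lapply(cands, as.data.frame))
  ## smallest-period dedup of same-locus calls (p vs 2p), then greedy
  ## longest-span / highest-match selection among distinct loci
  tab <- tab[order(tab$period, -tab$match_fraction), , drop = FALSE]
  keep <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!keep[i]) next
    if (i < nrow(tab)) for (j in seq(i + 1L, nrow(tab))) {
      if (!keep[j]) next
      ov <- min(tab$end[i], tab$end[j]) - max(tab$start[i], tab$start[j]) + 1
      longer <- max(tab$end[i] - tab$start[i], tab$end[j] - tab$start[j]) + 1
      if (ov >= 0.8 * longer) keep[j] <- FALSE
    }
  }
  tab <- tab[keep, , drop = FALSE]
  tab <- tab[order(-(tab$end - tab$start), -tab$match_fraction,
                   tab$period), , drop = FALSE]
  keep <- rep(TRUE, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!keep[i]) next
    if (i < nrow(tab)) for (j in seq(i + 1L, nrow(tab))) {
      if (keep[j] && tab$start[j] <= tab$end[i] &&
          tab$end[j] >= tab$start[i]) keep[j] <- FALSE
    }
  }
  tab <- tab[keep, , drop = FALSE]
  tab <- tab[order(tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

emptyRepeatTable <- function() {
  data.frame(start = integer(), end = integer(), period = integer(),
             copy_number = numeric(), copies_rounded = integer(),
             consensus = character(), match_fraction = numeric(),
             stringsAsFactors = FALSE)
}

## consensus-validate a candidate array; extend partial copies at both
## edges while they agree with the consensus
evaluateRepeat <- function(v, start, end, p, threshold) {
  n <- length(v)
  k <- (end - start + 1L) %/% p
  if (k < 2L) return(NULL)
  cols <- matrix(v[seq(start, start + k * p - 1L)], nrow = p)
  cons <- apply(cols, 1L, function(x) names(which.max(table(x))))
  ## extend forward/backward over bases matching the consensus in phase
  e <- start + k * p - 1L
  while (e < n && v[e + 1L] == cons[((e + 1L - start) %% p) + 1L])
    e <- e + 1L
  s <- start
  while (s > 1L && v[s - 1L] == cons[((s - 1L - start) %% p) + 1L])
    s <- s - 1L
  k2 <- (e - s + 1L) %/% p
  phase <- ((s - start) %% p)
  full <- seq(s, s + k2 * p - 1L)
  match_frac <- mean(v[full] == cons[((full - start) %% p) + 1L])
  list(start = s, end = e, period = p,
       copy_number = (e - s + 1L) / p,
       copies_rounded = as.integer(round((e - s + 1L) / p)),
       consensus = paste(cons[((seq(phase, phase + p - 1L)) %% p) + 1L],
                         collapse = ""),
       match_fraction = match_frac)
}

#' Excise detected tandem repeats from a sequence
#'
#' Removes (not N-masks) the repeat spans, merging overlapping spans
#' first, and reports the removed length. The remainder is the
#' "conserved" sequence used for cross-species comparison.
#'
#' @param seq character scalar.
#' @param repeats data.frame from [findTandemRepeats()] on \code{seq}.
#' @return list: \code{sequence} (repeat-free), \code{removed_bases},
#'   \code{removed_spans} data.frame.
#' @export
maskRepeats <- function(seq, repeats) {
  if (!nrow(repeats))
    return(list(sequence = seq, removed_bases = 0L,
                removed_spans = data.frame(start = integer(),
                                           end = integer())))
  sp <- repeats[order(repeats$start), c("start", "end")]
  merged <- sp[1, ]
  for (i in seq_len(nrow(sp))[-1]) {
    last <- nrow(merged)
    if (sp$start[i] <= merged$end[last] + 1L)
      merged$end[last] <- max(merged$end[last], sp$end[i])
    else merged <- rbind(merged, sp[i, ])
  }
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  drop <- unlist(mapply(function(a, b) a:b, merged$start, merged$end,
                        SIMPLIFY = FALSE))
  list(sequence = paste(v[-drop], collapse = ""),
       removed_bases = length(drop),
       removed_spans = merged)
}

#' The default O_L motif library
#'
#' The two stem motifs of the vertebrate light-strand replication origin:
#' motif 1 (CTTCT, strictly conserved) and motif 2 (GCCGG, 5' base of the
#' stem; one mismatch tolerated to catch variants such as GCCAG).
#' Termination-associated sequences (TAS) and conserved sequence blocks
#' (CSB) are lineage-specific and must be supplied by the user from
#' reference taxa.
#'
#' @return named list: each element \code{list(pattern, max_mismatches)}.
#' @export
defaultMotifLibrary <- function() {
  list(OL_motif1 = list(pattern = "CTTCT", max_mismatches = 0L),
       OL_motif2 = list(pattern = "GCCGG", max_mismatches = 1L))
}

#' Read a motif library from YAML
#'
#' YAML maps motif name to \code{pattern} (IUPAC allowed) and optional
#' \code{max_mismatches} (default 0).
#'
#' @param path YAML file.
#' @return named list as [defaultMotifLibrary()].
#' @export
readMotifLibrary <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, function(m)
    list(pattern = m$pattern,
         max_mismatches = if (is.null(m$max_mismatches)) 0L
                          else as.integer(m$max_mismatches)))
}

#' Search a sequence for short conserved motifs
#'
#' Hamming-style search (mismatches allowed per motif, no indels) on the
#' given strand and optionally the reverse complement.
#'
#' @param seq character scalar.
#' @param motifs motif library (see [defaultMotifLibrary()]); a plain
#'   named character vector is accepted (0 mismatches).
#' @param max_mismatches optional override applied to every motif.
#' @param both_strands also search the reverse complement.
#' @return data.frame: \code{motif}, \code{strand}, \code{start},
#'   \code{end} (1-based on \code{seq}), \code{match},
#'   \code{mismatches}.
#' @export
findMotifs <- function(seq, motifs = defaultMotifLibrary(),
                       max_mismatches = NULL, both_strands = FALSE) {
  if (is.character(motifs))
    motifs <- lapply(motifs, function(p)
      list(pattern = p, max_mismatches = 0L))
  subj <- Biostrings::DNAString(seq)
  out <- data.frame(motif = character(), strand = character(),
                    start = integer(), end = integer(),
                    match = character(), mismatches = integer(),
                    stringsAsFactors = FALSE)
  strands <- if (both_strands) c("+", "-") else "+"
  for (nm in names(motifs)) {
    mm <- if (is.null(max_mismatches)) motifs[[nm]]$max_mismatches
          else max_mismatches
    pat <- motifs[[nm]]$pattern
    if (nchar(pat) > length(subj)) next
    for (strand in strands) {
      s <- if (strand == "+") subj
           else Biostrings::reverseComplement(subj)
      hits <- Biostrings::matchPattern(pat, s, max.mismatch = mm,
                                       fixed = FALSE)
      if (!length(hits)) next
      st <- Biostrings::start(hits); en <- Biostrings::end(hits)
      if (strand == "-") {
        L <- length(subj)
        tmp <- st
        st <- L - en + 1L
        en <- L - tmp + 1L
      }
      mseq <- vapply(seq_along(hits), function(i)
        as.character(hits[[i]]), "")
      nmis <- vapply(mseq, function(x)
        sum(strsplit(x, "")[[1]] !=
              strsplit(pat, "")[[1]]), 0L, USE.NAMES = FALSE)
      out <- rbind(out, data.frame(
        motif = nm, strand = strand, start = st, end = en,
        match = mseq, mismatches = nmis, stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Pairwise identity of paralogous control regions
#'
#' Globally aligns two control-region sequences (match +1, mismatch -1,
#' gap open -5, gap extend -1 by default) and reports identity over
#' "alignable sites": gap-free columns only, so gaps are neither matches
#' nor substitutions. Pre-aligned input (equal-length strings with "-")
#' bypasses alignment, which is the exact-reproduction path for published
#' substitution counts.
#'
#' @param seq1,seq2 character scalars; with \code{aligned = TRUE}, equal
#'   length including gap characters.
#' @param aligned inputs are already aligned.
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @return list of class \code{CRAlignment}: \code{alignable_sites},
#'   \code{substitutions}, \code{identity} (percent).
#' @examples
#' crPairwiseIdentity("ACGTACGT", "ACGTACGT")$identity  # 100
#' @export
crPairwiseIdentity <- function(seq1, seq2, aligned = FALSE, match = 1,
                               mismatch = -1, gap_open = -5,
                               gap_extend = -1) {
  if (!nchar(seq1) || !nchar(seq2)) stop("empty input sequence")
  if (aligned) {
    if (nchar(seq1) != nchar(seq2))
      stop("pre-aligned sequences must have equal length")
    a <- strsplit(toupper(seq1), "")[[1]]
    b <- strsplit(toupper(seq2), "")[[1]]
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(seq1), Biostrings::DNAString(seq2),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = match, mismatch = mismatch),
      gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
    a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  }
  free <- a != "-" & b != "-"
  alignable <- sum(free)
  if (!alignable) stop("no gap-free aligned columns")
  subs <- sum(a[free] != b[free])
  structure(list(alignable_sites = alignable, substitutions = subs,
                 identity = (alignable - subs) / alignable * 100),
            class = "CRAlignment")
}

#' @export
print.CRAlignment <- function(x, ...) {
  cat(sprintf("CR identity: %.1f%% (%d substitutions in %d alignable sites)\n",
              x$identity, x$substitutions, x$alignable_sites))
  invisible(x)
}
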