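## gene remnants inside non-coding regions and ATP8-loss pathway calls

#' Best local alignment of a reference gene against a query region
#'
#' Smith-Waterman local alignment (match +2, mismatch -1, gap -2 by
#' default). A hit is reported only when its score reaches
#' \code{threshold}, which defaults to half of the maximum attainable
#' score (a perfect full-length match, \code{2 * nchar(ref)}). Under
#' this scoring, spurious local alignments between unrelated sequences
#' plateau below half-maximal score even for tRNA-sized references,
#' while remnants decayed at up to ~30% per site still score above it.
#'
#' @param query nucleotide string searched for remnants (e.g. an NCR).
#' @param ref reference gene sequence.
#' @param match,mismatch,gap alignment scores.
#' @param threshold minimum score for a reported hit.
#' @return \code{NULL} when nothing reaches the threshold, else a list:
#'   \code{score}, \code{identity} (percent over the aligned span),
#'   \code{query_span}, \code{ref_span} (1-based), \code{ref_coverage}
#'   (fraction of the reference inside the hit).
#' @export
localAlign <- function(query, ref, match = 2, mismatch = -1, gap = -2,
                       threshold = 0.5 * 2 * nchar(ref)) {
  if (!nchar(query) || !nchar(ref)) stop("empty input sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(ref),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch),
    gapOpening = 0, gapExtension = abs(gap))
  if (Biostrings::score(aln) < threshold) return(NULL)
  p <- Biostrings::pattern(aln)
  s <- Biostrings::subject(aln)
  list(score = Biostrings::score(aln),
       identity = Biostrings::pid(aln),
       query_span = c(Biostrings::start(p), Biostrings::end(p)),
       ref_span = c(Biostrings::start(s), Biostrings::end(s)),
       ref_coverage = (Biostrings::end(s) - Biostrings::start(s) + 1) /
         nchar(ref))
}

#' Classify how a non-coding region at the ATP8 locus was formed
#'
#' Scans an NCR for degraded remnants of reference genes by local
#' alignment and applies positional logic for the two formation
#' pathways: a duplication-degeneration NCR (the COII--tRNA-Lys region
#' duplicated in tandem, then the supernumerary COII, tRNA-Lys and ATP8
#' copies degraded) carries remnants of genes besides ATP8, whereas a
#' direct-mutation NCR (ATP8 alone decayed in place) aligns only to
#' ATP8. No remnant at all leaves the region unclassified.
#'
#' @param ncr NCR nucleotide string.
#' @param refs named list/character of reference gene sequences from a
#'   close relative; must include \code{ATP8}, normally also \code{K}
#'   (tRNA-Lys) and \code{COII}.
#' @param ... scoring arguments passed to [localAlign()].
#' @return list of class \code{NCRClassification}: \code{pathway} in
#'   \{"duplication-degeneration", "direct-mutation", "unclassified"\},
#'   \code{hits} data.frame.
#' @export
classifyNCR <- function(ncr, refs, ...) {
  if (!"ATP8" %in% names(refs))
    stop("refs must include an ATP8 reference")
  hits <- data.frame(ref = character(), score = numeric(),
                     identity = numeric(), ref_coverage = numeric(),
                     q_start = integer(), q_end = integer(),
                     stringsAsFactors = FALSE)
  for (nm in names(refs)) {
    h <- localAlign(ncr, as.character(refs[[nm]]), ...)
    if (!is.null(h))
      hits <- rbind(hits, data.frame(
        ref = nm, score = h$score, identity = h$identity,
        ref_coverage = h$ref_coverage,
        q_start = h$query_span[1], q_end = h$query_span[2],
        stringsAsFactors = FALSE))
  }
  non_atp8 <- setdiff(hits$ref, "ATP8")
  pathway <- if (nrow(hits) >= 2L || length(non_atp8))
    "duplication-degeneration"
  else if (nrow(hits) == 1L && hits$ref == "ATP8") "direct-mutation"
  else "unclassified"
  structure(list(pathway = pathway, hits = hits),
            class = "NCRClassification")
}

#' @export
print.NCRClassification <- function(x, ...) {
  cat("NCR formation pathway:", x$pathway, "\n")
  if (nrow(x$hits))
    cat("remnants:", paste(sprintf("%s (%.0f%% id)", x$hits$ref,
                                   x$hits$identity), collapse = ", "),
        "\n")
  invisible(x)
}

#' Sanity-check the anticodon loop of a putative tRNA pseudogene
#'
#' Given an externally predicted secondary structure in dot-bracket
#' notation and the annotated anticodon-loop span, reports whether the
#' loop is the canonical 7 unpaired bases. A shorter loop ("lacking a
#' nucleotide") cannot present a proper anticodon and marks the gene as
#' a likely pseudogene.
#'
#' @param structure dot-bracket string (balanced brackets required).
#' @param loop_span integer c(start, end), 1-based inclusive span of the
#'   anticodon loop within \code{structure}.
#' @return list: \code{status} "normal"/"abnormal", \code{reason}.
#' @export
anticodonLoopCheck <- function(structure, loop_span) {
  chars <- strsplit(structure, "")[[1]]
  if (!all(chars %in% c(".", "(", ")")))
    stop("malformed dot-bracket string")
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0) || depth[length(depth)] != 0)
    stop("unbalanced brackets in dot-bracket string")
  if (length(loop_span) != 2L || loop_span[1] < 1L ||
      loop_span[2] > length(chars) || loop_span[1] > loop_span[2])
    stop("invalid anticodon loop span")
  loop <- chars[loop_span[1]:loop_span[2]]
  n_unpaired <- sum(loop == ".")
  if (any(loop != "."))
    list(status = "abnormal",
         reason = "anticodon loop contains paired bases")
  else if (n_unpaired == 7L)
    list(status = "normal", reason = "canonical 7-base anticodon loop")
  else if (n_unpaired < 7L)
    list(status = "abnormal",
         reason = sprintf("anticodon loop lacking %d nucleotide(s)",
                          7L - n_unpaired))
  else
    list(status = "abnormal",
         reason = sprintf("anticodon loop with %d extra nucleotide(s)",
                          n_unpaired - 7L))
}
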