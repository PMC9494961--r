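## S4 classes for annotated circular mitogenomes and gene-order models

#' @title Controlled label vocabulary
#' @description Labels recognised for mitogenome features. Protein-coding
#'   genes use conventional symbols; tRNAs use one-letter amino-acid codes
#'   with the two leucine/serine isoacceptors disambiguated as
#'   \code{"L(UUR)"}/\code{"L(CUN)"} and \code{"S(UCN)"}/\code{"S(AGY)"}.
#' @format A named list with elements \code{PCG}, \code{tRNA}, \code{rRNA},
#'   \code{CR}, \code{NCR}, \code{OL}, each a character vector of labels.
#' @export
featureVocabulary <- function() {
  list(
    PCG  = c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
             "COI", "COII", "COIII", "ATP6", "ATP8", "CYTB"),
    tRNA = c("F", "V", "L(UUR)", "I", "Q", "M", "W", "A", "N", "C", "Y",
             "S(UCN)", "D", "K", "G", "R", "H", "S(AGY)", "L(CUN)",
             "E", "T", "P"),
    rRNA = c("12S", "16S"),
    CR   = c("CR", "CR1", "CR2"),
    NCR  = "NCR",
    OL   = "OL"
  )
}

FEATURE_KINDS <- c("PCG", "tRNA", "rRNA", "CR", "NCR", "OL")
STRANDS <- c("H", "L")

emptyFeatures <- function() {
  data.frame(label = character(), kind = character(), strand = character(),
             start = integer(), end = integer(), anticodon = character(),
             stringsAsFactors = FALSE)
}

#' MitoGenome: an annotated circular mitochondrial genome
#'
#' Holds the heavy-strand (H) sequence of a circular mitogenome together
#' with an ordered, strand-aware feature table. Internal coordinates are
#' 0-based half-open; a feature with \code{end < start} wraps across the
#' origin (at most one feature may wrap).
#'
#' @slot id single character identifier.
#' @slot sequence a \link[Biostrings]{DNAString} over A/C/G/T/N (H-strand).
#' @slot circular logical flag.
#' @slot features data.frame with columns \code{label}, \code{kind}
#'   (PCG/tRNA/rRNA/CR/NCR/OL), \code{strand} (H/L), \code{start},
#'   \code{end}, \code{anticodon}, sorted by \code{start}.
#' @seealso [readFeatureTable()], [readGenBank()], [geneOrder()]
#' @export
setClass("MitoGenome",
  representation(id = "character", sequence = "ANY",
                 circular = "logical", features = "data.frame"))

setValidity("MitoGenome", function(object) {
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "'id' must be length 1")
  if (!is(object@sequence, "DNAString"))
    msg <- c(msg, "'sequence' must be a DNAString")
  L <- length(object@sequence)
  if (L < 1L) msg <- c(msg, "sequence must be non-empty")
  bad <- setdiff(unique(strsplit(as.character(object@sequence), "")[[1]]),
                 c("A", "C", "G", "T", "N"))
  if (length(bad)) msg <- c(msg, paste("alphabet outside A/C/G/T/N:",
                                       paste(bad, collapse = ",")))
  ft <- object@features
  need <- c("label", "kind", "strand", "start", "end", "anticodon")
  if (!all(need %in% names(ft))) {
    msg <- c(msg, paste("features must have columns",
                        paste(need, collapse = ", ")))
  } else if (nrow(ft)) {
    if (!all(ft$kind %in% FEATURE_KINDS))
      msg <- c(msg, "unknown feature kind")
    if (!all(ft$strand %in% STRANDS))
      msg <- c(msg, "strand must be 'H' or 'L'")
    if (any(ft$start < 0L) || any(ft$start >= L) ||
        any(ft$end < 0L) || any(ft$end > L))
      msg <- c(msg, "feature span outside [0, genome length)")
    if (sum(ft$end < ft$start) > 1L)
      msg <- c(msg, "at most one feature may wrap across the origin")
    if (is.unsorted(ft$start))
      msg <- c(msg, "features must be sorted by start")
    if (any(spanLength(ft$start, ft$end, L) < 1L))
      msg <- c(msg, "zero-length feature span")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MitoGenome
#'
#' @param id character identifier.
#' @param sequence character scalar or \code{DNAString} (H-strand).
#' @param features feature data.frame (see \linkS4class{MitoGenome});
#'   missing \code{anticodon} column is filled with \code{NA}. Rows are
#'   sorted by start.
#' @param circular logical; circular genome (default \code{TRUE}).
#' @return a validated \linkS4class{MitoGenome}.
#' @examples
#' g <- MitoGenome("toy", "ATGAAATAAGGGCCC",
#'   data.frame(label = "ND1", kind = "PCG", strand = "H",
#'              start = 0L, end = 9L))
#' genomeLength(g)
#' @export
MitoGenome <- function(id, sequence, features = emptyFeatures(),
                       circular = TRUE) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  if (!"anticodon" %in% names(features))
    features$anticodon <- rep(NA_character_, nrow(features))
  features <- features[, c("label", "kind", "strand", "start", "end",
                           "anticodon")]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (nrow(features))
    features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  new("MitoGenome", id = id, sequence = sequence,
      circular = circular, features = features)
}

#' GeneOrder: an anchored circular gene order
#'
#' The circular sequence of feature labels with strand signs, linearized
#' so that the anchor label comes first. Two circular orders are equal iff
#' their anchored linearizations are equal.
#'
#' @slot labels character vector of unique labels.
#' @slot strands character vector ("H"/"L"), parallel to labels.
#' @slot anchor the anchor label (equals \code{labels[1]}).
#' @export
setClass("GeneOrder",
  representation(labels = "character", strands = "character",
                 anchor = "character"))

setValidity("GeneOrder", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@strands))
    msg <- c(msg, "labels and strands must have equal length")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "duplicate labels in gene order")
  if (length(object@labels) &&
      (length(object@anchor) != 1L || object@labels[1] != object@anchor))
    msg <- c(msg, "anchor must be the first label")
  if (length(object@strands) && !all(object@strands %in% STRANDS))
    msg <- c(msg, "strands must be 'H' or 'L'")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneOrder
#'
#' @param labels character labels in circular order.
#' @param strands strand signs ("H"/"L"); default all "H".
#' @param anchor label to rotate to front (default: first label).
#' @return a \linkS4class{GeneOrder}.
#' @export
GeneOrder <- function(labels, strands = rep("H", length(labels)),
                      anchor = labels[1]) {
  i <- match(anchor, labels)
  if (is.na(i)) stop("anchor '", anchor, "' not present in labels")
  rot <- c(seq_along(labels), seq_along(labels))[i:(i + length(labels) - 1L)]
  new("GeneOrder", labels = labels[rot], strands = strands[rot],
      anchor = anchor)
}

#' TDRLEvent: one tandem duplication-random loss step
#'
#' A contiguous block of an anchored gene order is duplicated in tandem;
#' for every gene in the block exactly one copy (the first or the second)
#' is retained. Strands are untouched: TDRL rearranges within a strand
#' context.
#'
#' @slot block integer c(from, to): 1-based inclusive positions in the
#'   anchored linearization.
#' @slot retention character vector of "first"/"second", one per block
#'   position.
#' @export
setClass("TDRLEvent",
  representation(block = "integer", retention = "character"))

setValidity("TDRLEvent", function(object) {
  msg <- character()
  if (length(object@block) != 2L || object@block[1] > object@block[2] ||
      object@block[1] < 1L)
    msg <- c(msg, "block must be c(from, to) with 1 <= from <= to")
  if (length(object@retention) != object@block[2] - object@block[1] + 1L)
    msg <- c(msg, "retention length must equal block size")
  if (length(object@retention) &&
      !all(object@retention %in% c("first", "second")))
    msg <- c(msg, "retention entries must be 'first' or 'second'")
  if (length(msg)) msg else TRUE
})

#' Construct a TDRLEvent
#' @param from,to 1-based inclusive block bounds in the anchored order.
#' @param retention character vector of "first"/"second" per block gene.
#' @return a \linkS4class{TDRLEvent}.
#' @export
TDRLEvent <- function(from, to, retention) {
  new("TDRLEvent", block = as.integer(c(from, to)), retention = retention)
}

#' PathwayScript: a replayable gene-rearrangement scenario
#'
#' An ordered list of steps taking a start order to an expected end order.
#' Steps are either TDRL events (\code{type = "tdrl"}) or annotated
#' non-TDRL transformations (\code{type = "replace"}: a contiguous run of
#' labels is substituted, e.g. duplication of a control region or
#' degeneration of a gene into a non-coding region).
#'
#' @slot start,end \linkS4class{GeneOrder}s.
#' @slot steps list; each element a list with \code{type} and either
#'   \code{event} (a \linkS4class{TDRLEvent}) or \code{from}/\code{to}/
#'   \code{to_strands}, plus an optional \code{note}.
#' @slot description free-text description.
#' @export
setClass("PathwayScript",
  representation(start = "GeneOrder", end = "GeneOrder",
                 steps = "list", description = "character"))

#' Construct a PathwayScript
#' @param start,end \linkS4class{GeneOrder}s.
#' @param steps list of step descriptions (see \linkS4class{PathwayScript}).
#' @param description free text.
#' @return a \linkS4class{PathwayScript}.
#' @export
PathwayScript <- function(start, end, steps = list(),
                          description = NA_character_) {
  new("PathwayScript", start = start, end = end, steps = steps,
      description = description)
}
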