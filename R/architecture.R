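## gene order extraction, circular junction accounting, cluster detection

#' Extract the anchored gene order of a genome
#'
#' Features in circular genomic order, linearized at the anchor label.
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @param anchor label to anchor at (default "12S").
#' @return a \linkS4class{GeneOrder}.
#' @export
geneOrder <- function(genome, anchor = "12S") {
  ft <- featureTable(genome)
  if (anyDuplicated(ft$label))
    stop("duplicate feature labels: ",
         paste(unique(ft$label[duplicated(ft$label)]), collapse = ", "))
  GeneOrder(ft$label, ft$strand, anchor = anchor)
}

#' Spacer and overlap accounting around the circle
#'
#' For every pair of circularly consecutive features of the included
#' kinds, the signed gap is \code{next start - previous end} under
#' circular arithmetic: a positive gap is an intergenic spacer, a
#' negative one an overlap of that many shared bases, and abutting
#' features (gap 0) are reported in neither list. Control regions and
#' non-coding regions are excluded by default: published junction totals
#' count only gene-to-gene junctions, and the gap holding an NCR is the
#' NCR, not a spacer; the light-strand replication origin is included
#' because its overlap with tRNA-Cys is part of those totals.
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @param include_kinds feature kinds entering the accounting.
#' @return list of class \code{JunctionReport}: \code{spacers} and
#'   \code{overlaps} data.frames (\code{upstream}, \code{downstream},
#'   \code{bases}) and \code{totals} (spacer count/bases, overlap
#'   count/bases, max overlap).
#' @export
junctionScan <- function(genome,
                         include_kinds = c("PCG", "tRNA", "rRNA", "OL")) {
  all_ft <- featureTable(genome)
  ft <- all_ft[all_ft$kind %in% include_kinds, , drop = FALSE]
  excl <- all_ft[!all_ft$kind %in% include_kinds, , drop = FALSE]
  L <- genomeLength(genome)
  n <- nrow(ft)
  sp <- ov <- data.frame(upstream = character(), downstream = character(),
                         bases = integer(), stringsAsFactors = FALSE)
  if (n >= 2L) {
    for (k in seq_len(n)) {
      a <- ft[k, ]
      b <- ft[if (k == n) 1L else k + 1L, ]
      gap <- (b$start - a$end) %% L
      if (gap > L / 2) gap <- gap - L
      ## a gap that hosts an excluded feature (CR/NCR) is that region,
      ## not an intergenic spacer: drop the junction
      if (gap > 0 && nrow(excl)) {
        inside <- ((excl$start - a$end) %% L) < gap
        if (any(inside)) next
      }
      if (gap < 0) {
        shorter <- min(spanLength(a$start, a$end, L),
                       spanLength(b$start, b$end, L))
        if (-gap > shorter)
          stop("features ", a$label, " and ", b$label,
               " overlap by more than the shorter feature")
        ov <- rbind(ov, data.frame(upstream = a$label,
                                   downstream = b$label,
                                   bases = -gap))
      } else if (gap > 0) {
        sp <- rbind(sp, data.frame(upstream = a$label,
                                   downstream = b$label,
                                   bases = gap))
      }
    }
  }
  structure(list(
    spacers = sp, overlaps = ov,
    totals = list(spacer_count = nrow(sp), spacer_bases = sum(sp$bases),
                  overlap_count = nrow(ov), overlap_bases = sum(ov$bases),
                  max_overlap = if (nrow(ov)) max(ov$bases) else 0L)),
    class = "JunctionReport")
}

#' @export
print.JunctionReport <- function(x, ...) {
  t <- x$totals
  cat(sprintf("Junctions: %d spacers (%d bp), %d overlaps (%d bp, max %d)\n",
              t$spacer_count, t$spacer_bases, t$overlap_count,
              t$overlap_bases, t$max_overlap))
  invisible(x)
}

#' Named tRNA cluster dictionaries
#'
#' The clusters screened by [namedClusters()]: the vertebrate "WANCY"
#' block (which hosts the light-strand replication origin between Asn and
#' Cys), the ancestral "LTPF" block and its derived rhacophorid swap
#' "TLPF". Extensible without code changes.
#'
#' @return named list of label vectors.
#' @export
clusterDictionaries <- function() {
  list(WANCY = c("W", "A", "N", "C", "Y"),
       TLPF = c("T", "L(CUN)", "P", "F"),
       LTPF = c("L(CUN)", "T", "P", "F"))
}

#' Detect named tRNA gene clusters in a gene order
#'
#' Finds contiguous circular runs matching each dictionary entry. An
#' embedded light-strand origin (OL) inside a run is tolerated and
#' reported (the WANCY cluster normally carries it between Asn and Cys).
#'
#' @param order a \linkS4class{GeneOrder}.
#' @param dictionaries named list of label vectors
#'   (default [clusterDictionaries()]).
#' @return data.frame: \code{cluster}, \code{position} (1-based index of
#'   the first member in the anchored order), \code{ol_inside}.
#' @export
namedClusters <- function(order, dictionaries = clusterDictionaries()) {
  labs <- orderLabels(order)
  n <- length(labs)
  out <- data.frame(cluster = character(), position = integer(),
                    ol_inside = logical(), stringsAsFactors = FALSE)
  for (nm in names(dictionaries)) {
    dict <- dictionaries[[nm]]
    for (s in seq_len(n)) {
      i <- s; ok <- TRUE; ol <- FALSE
      for (d in dict) {
        while (labs[(i - 1L) %% n + 1L] == "OL") {
          ol <- TRUE
          i <- i + 1L
        }
        if (labs[(i - 1L) %% n + 1L] != d) { ok <- FALSE; break }
        i <- i + 1L
      }
      if (ok) {
        out <- rbind(out, data.frame(cluster = nm, position = s,
                                     ol_inside = ol))
        break
      }
    }
  }
  out
}

#' Feature counts per strand and kind
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @return data.frame: \code{kind}, \code{H}, \code{L}.
#' @export
strandDistribution <- function(genome) {
  ft <- featureTable(genome)
  kinds <- FEATURE_KINDS[FEATURE_KINDS %in% ft$kind]
  out <- data.frame(
    kind = kinds,
    H = vapply(kinds, function(k)
      sum(ft$kind == k & ft$strand == "H"), 0L),
    L = vapply(kinds, function(k)
      sum(ft$kind == k & ft$strand == "L"), 0L))
  rownames(out) <- NULL
  out
}
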