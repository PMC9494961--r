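## MitoGenome accessors, coordinate arithmetic, readers and writers

#' Accessors for MitoGenome objects
#'
#' @param x a \linkS4class{MitoGenome}.
#' @return \code{genomeID}: character; \code{genomeSeq}: DNAString;
#'   \code{genomeLength}: integer; \code{featureTable}: data.frame with
#'   0-based half-open coordinates.
#' @name MitoGenome-accessors
NULL

#' @rdname MitoGenome-accessors
#' @export
setMethod("genomeID", "MitoGenome", function(x) x@id)

#' @rdname MitoGenome-accessors
#' @export
setMethod("genomeSeq", "MitoGenome", function(x) x@sequence)

#' @rdname MitoGenome-accessors
#' @export
setMethod("genomeLength", "MitoGenome", function(x) length(x@sequence))

#' @rdname MitoGenome-accessors
#' @export
setMethod("featureTable", "MitoGenome", function(x) x@features)

setMethod("show", "MitoGenome", function(object) {
  ft <- object@features
  cat("MitoGenome '", object@id, "': ", length(object@sequence), " bp, ",
      if (object@circular) "circular" else "linear", ", ",
      nrow(ft), " features", sep = "")
  if (nrow(ft)) {
    tab <- table(ft$kind)
    cat(" (", paste(names(tab), tab, sep = ":", collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
})

#' Accessors for GeneOrder objects
#' @param x a \linkS4class{GeneOrder}.
#' @return character vectors.
#' @name GeneOrder-accessors
NULL

#' @rdname GeneOrder-accessors
#' @export
setMethod("orderLabels", "GeneOrder", function(x) x@labels)

#' @rdname GeneOrder-accessors
#' @export
setMethod("orderStrands", "GeneOrder", function(x) x@strands)

#' @rdname GeneOrder-accessors
#' @export
setMethod("orderAnchor", "GeneOrder", function(x) x@anchor)

setMethod("show", "GeneOrder", function(object) {
  sgn <- ifelse(object@strands == "L", "-", "")
  cat("GeneOrder (anchor ", object@anchor, "): ",
      paste0(sgn, object@labels, collapse = ", "), "\n", sep = "")
})

## ---------------------------------------------------------------------
## feature table I/O (file coordinates are 1-based inclusive; a file span
## with start > end wraps across the origin)

#' Read a genome from a feature TSV plus FASTA
#'
#' The TSV has columns \code{label}, \code{kind}, \code{strand},
#' \code{start}, \code{end} and optionally \code{anticodon}, with 1-based
#' inclusive coordinates (a row with \code{start > end} wraps across the
#' origin). The companion FASTA supplies the H-strand sequence.
#'
#' @param tsv path to the feature table.
#' @param fasta path to a single-record FASTA file.
#' @param id genome identifier; default: FASTA record name.
#' @return a validated \linkS4class{MitoGenome} (internal coordinates
#'   0-based half-open).
#' @seealso [writeFeatureTable()]
#' @export
readFeatureTable <- function(tsv, fasta, id = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) stop("FASTA must contain exactly one record")
  if (is.null(id)) id <- sub("\\s.*$", "", names(seqs)[1])
  ft <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  need <- c("label", "kind", "strand", "start", "end")
  if (!all(need %in% names(ft)))
    stop("feature table must have columns ", paste(need, collapse = ", "))
  vocab <- unlist(featureVocabulary(), use.names = FALSE)
  L <- length(seqs[[1]])
  for (i in seq_len(nrow(ft))) {
    if (!ft$kind[i] %in% FEATURE_KINDS)
      stop("row ", i, ": unknown kind '", ft$kind[i], "'")
    if (!ft$strand[i] %in% STRANDS)
      stop("row ", i, ": unknown strand '", ft$strand[i], "'")
    if (!ft$label[i] %in% vocab)
      stop("row ", i, ": unknown label '", ft$label[i], "'")
    if (ft$start[i] < 1L || ft$start[i] > L ||
        ft$end[i] < 1L || ft$end[i] > L)
      stop("row ", i, ": span outside sequence of length ", L)
  }
  if (!"anticodon" %in% names(ft))
    ft$anticodon <- rep(NA_character_, nrow(ft))
  ## 1-based inclusive [s, e] -> 0-based half-open [s-1, e); a wrapped file
  ## span (s > e) keeps the same end, still encoding wrap as end < start
  feats <- data.frame(label = ft$label, kind = ft$kind, strand = ft$strand,
                      start = as.integer(ft$start) - 1L,
                      end = as.integer(ft$end),
                      anticodon = as.character(ft$anticodon),
                      stringsAsFactors = FALSE)
  MitoGenome(id, seqs[[1]], feats)
}

#' Write the feature table (and optionally FASTA) of a genome
#'
#' Inverse of [readFeatureTable()]: coordinates are written 1-based
#' inclusive, wrap encoded as start > end.
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @param tsv output path for the feature table.
#' @param fasta optional output path for the sequence FASTA.
#' @return invisibly, the data.frame written.
#' @export
writeFeatureTable <- function(genome, tsv, fasta = NULL) {
  ft <- featureTable(genome)
  out <- data.frame(label = ft$label, kind = ft$kind, strand = ft$strand,
                    start = ft$start + 1L, end = ft$end,
                    anticodon = ft$anticodon, stringsAsFactors = FALSE)
  utils::write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(genomeSeq(genome))
    names(ss) <- genomeID(genome)
    Biostrings::writeXStringSet(ss, fasta)
  }
  invisible(out)
}

## ---------------------------------------------------------------------

#' Extract the sequence of one feature
#'
#' Returns the H-strand substring for strand-H features and the reverse
#' complement for strand-L features (i.e. the coding/gene sequence).
#' Wrapped spans concatenate the suffix and prefix of the genome.
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @param feature a feature label present exactly once, or a single row of
#'   \code{featureTable(genome)}.
#' @return character scalar.
#' @examples
#' g <- MitoGenome("toy", "ATGCC",
#'   data.frame(label = "F", kind = "tRNA", strand = "L",
#'              start = 0L, end = 4L))
#' extractFeatureSequence(g, "F")  # "GCAT"
#' @export
extractFeatureSequence <- function(genome, feature) {
  if (is.character(feature)) {
    ft <- featureTable(genome)
    i <- which(ft$label == feature)
    if (length(i) != 1L)
      stop("label '", feature, "' matches ", length(i), " features")
    feature <- ft[i, ]
  }
  s <- as.character(genomeSeq(genome))
  L <- nchar(s)
  seq <- if (feature$end >= feature$start) {
    substr(s, feature$start + 1L, feature$end)
  } else {
    paste0(substr(s, feature$start + 1L, L),
           substr(s, 1L, feature$end))
  }
  if (feature$strand == "L") revComp(seq) else seq
}

#' Rotate a circular genome so an anchor feature starts at the origin
#'
#' The sequence and all feature coordinates are rotated so the anchor
#' feature starts at position 0. Feature content and all inter-feature
#' distances are preserved.
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @param anchor a label present exactly once.
#' @return a rotated \linkS4class{MitoGenome}.
#' @export
rotateToAnchor <- function(genome, anchor) {
  ft <- featureTable(genome)
  i <- which(ft$label == anchor)
  if (length(i) != 1L)
    stop("anchor '", anchor, "' matches ", length(i), " features")
  off <- ft$start[i]
  if (off == 0L) return(genome)
  s <- as.character(genomeSeq(genome))
  L <- nchar(s)
  s2 <- paste0(substr(s, off + 1L, L), substr(s, 1L, off))
  ft$start <- (ft$start - off) %% L
  ft$end <- (ft$end - off) %% L
  ## a non-wrapping feature ending exactly at the rotation point gets end 0
  ft$end[ft$end == 0L & ft$start > 0L] <- L
  ## re-encode: end == L stays L only when start < L means no wrap; keep
  ## half-open invariant end <= L
  MitoGenome(genomeID(genome), s2, ft, circular = genome@circular)
}

#' Validate a genome and report soft issues
#'
#' Runs the class validity checks plus advisory checks: unknown labels,
#' tRNA spans outside the realistic 60-80 bp window (warn, don't fail),
#' and N content above 5%.
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @return data.frame with columns \code{check}, \code{status},
#'   \code{detail}.
#' @export
validateGenome <- function(genome) {
  validObject(genome)
  ft <- featureTable(genome)
  L <- genomeLength(genome)
  out <- data.frame(check = "class validity", status = "ok",
                    detail = "", stringsAsFactors = FALSE)
  vocab <- unlist(featureVocabulary(), use.names = FALSE)
  unk <- setdiff(ft$label, vocab)
  out <- rbind(out, data.frame(
    check = "labels in vocabulary",
    status = if (length(unk)) "warn" else "ok",
    detail = paste(unk, collapse = ", ")))
  tr <- ft[ft$kind == "tRNA", , drop = FALSE]
  if (nrow(tr)) {
    len <- spanLength(tr$start, tr$end, L)
    bad <- tr$label[len < 60 | len > 80]
    out <- rbind(out, data.frame(
      check = "tRNA spans 60-80 bp",
      status = if (length(bad)) "warn" else "ok",
      detail = paste(bad, collapse = ", ")))
  }
  nfrac <- Biostrings::alphabetFrequency(genomeSeq(genome))[["N"]] / L
  out <- rbind(out, data.frame(
    check = "N content <= 5%",
    status = if (nfrac > 0.05) "warn" else "ok",
    detail = sprintf("%.2f%% N", 100 * nfrac)))
  for (i in which(out$status == "warn"))
    warning(out$check[i], ": ", out$detail[i], call. = FALSE)
  out
}
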