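## nucleotide composition, strand skews, codon usage (RSCU), codon endpoints

#' AT and GC skew
#'
#' Strand-asymmetry statistics \eqn{(A-T)/(A+T)} and \eqn{(G-C)/(G+C)}.
#' Arguments may be counts or percentages (the ratio is scale-free).
#'
#' @param a,t,g,c base counts or percentages.
#' @return dimensionless skew in [-1, 1]; \code{NA} when the denominator
#'   is zero.
#' @examples
#' atSkew(30.2, 30.8)   # -0.00984 -> prints as -0.010 at 3 d.p.
#' @export
atSkew <- function(a, t) ifelse(a + t == 0, NA_real_, (a - t) / (a + t))

#' @rdname atSkew
#' @export
gcSkew <- function(g, c) ifelse(g + c == 0, NA_real_, (g - c) / (g + c))

#' Base composition and skews of a sequence
#'
#' Counts A/C/G/T (N excluded from all denominators; more than 5% N
#' raises a warning), AT and GC content as percent of non-N bases, and
#' both skews computed from raw counts (not pre-rounded percentages).
#'
#' @param seq character scalar or \code{DNAString}.
#' @return one-row data.frame: \code{A,C,G,T,N}, \code{at_content},
#'   \code{gc_content} (percent), \code{at_skew}, \code{gc_skew}.
#' @export
baseComposition <- function(seq) {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  if (length(seq) == 0L) stop("empty sequence")
  f <- Biostrings::alphabetFrequency(seq)
  n <- sum(f[c("A", "C", "G", "T")])
  if (n == 0L) stop("sequence contains no unambiguous bases")
  if (f[["N"]] / length(seq) > 0.05)
    warning("more than 5% N bases", call. = FALSE)
  data.frame(A = f[["A"]], C = f[["C"]], G = f[["G"]], T = f[["T"]],
             N = f[["N"]],
             at_content = 100 * (f[["A"]] + f[["T"]]) / n,
             gc_content = 100 * (f[["G"]] + f[["C"]]) / n,
             at_skew = atSkew(f[["A"]], f[["T"]]),
             gc_skew = gcSkew(f[["G"]], f[["C"]]))
}

## concatenate the coding-strand sequences of all features of given kinds
concatKind <- function(genome, kinds, labels = NULL) {
  ft <- featureTable(genome)
  sel <- ft$kind %in% kinds
  if (!is.null(labels)) sel <- sel & ft$label %in% labels
  rows <- which(sel)
  if (!length(rows)) return("")
  paste(vapply(rows, function(i)
    extractFeatureSequence(genome, ft[i, ]), ""), collapse = "")
}

## in-frame codons of one PCG, truncated tail dropped
pcgCodons <- function(cds) {
  k <- nchar(cds) %/% 3L
  if (k == 0L) return(character())
  substring(cds, 3L * seq_len(k) - 2L, 3L * seq_len(k))
}

#' Per-region composition report
#'
#' One composition row each for the whole genome, all PCGs concatenated,
#' pooled codon positions 1/2/3 (strand-aware reading frame, truncated
#' tails dropped), all tRNAs, all rRNAs, CR1 and CR2. Region classes
#' absent from the annotation yield a row flagged absent (e.g. CR2 in a
#' single-control-region genome). A lone "CR" label is reported as CR1.
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @return data.frame with a \code{region} column, \code{present} flag and
#'   the [baseComposition()] columns.
#' @export
regionCompositionReport <- function(genome) {
  ft <- featureTable(genome)
  pcg <- which(ft$kind == "PCG")
  codon_pool <- c("", "", "")
  for (i in pcg) {
    cod <- pcgCodons(extractFeatureSequence(genome, ft[i, ]))
    if (length(cod)) {
      for (p in 1:3)
        codon_pool[p] <- paste0(codon_pool[p],
                                paste(substr(cod, p, p), collapse = ""))
    }
  }
  cr1 <- concatKind(genome, "CR", c("CR", "CR1"))
  regions <- list(
    genome = as.character(genomeSeq(genome)),
    PCGs = concatKind(genome, "PCG"),
    codon1 = codon_pool[1], codon2 = codon_pool[2], codon3 = codon_pool[3],
    tRNAs = concatKind(genome, "tRNA"),
    rRNAs = concatKind(genome, "rRNA"),
    CR1 = cr1,
    CR2 = concatKind(genome, "CR", "CR2"))
  out <- do.call(rbind, lapply(names(regions), function(r) {
    s <- regions[[r]]
    if (!nchar(s)) {
      cbind(data.frame(region = r, present = FALSE),
            data.frame(A = NA_integer_, C = NA_integer_, G = NA_integer_,
                       T = NA_integer_, N = NA_integer_,
                       at_content = NA_real_, gc_content = NA_real_,
                       at_skew = NA_real_, gc_skew = NA_real_))
    } else {
      cbind(data.frame(region = r, present = TRUE), baseComposition(s))
    }
  }))
  rownames(out) <- NULL
  out
}

#' Codon usage and RSCU under the vertebrate mitochondrial code
#'
#' Counts complete in-frame codons across all protein-coding genes
#' (truncated terminal codons are skipped; an internal stop raises a
#' warning but the codon is still counted). RSCU is
#' \eqn{count \times family\_size / family\_total} within each synonymous
#' family; Leu and Ser are single 6-codon families (the vertebrate
#' mitochondrial translation merges their subfamilies). Stop codons (TAA,
#' TAG, AGA, AGG) are counted but carry no RSCU.
#'
#' @param genome a \linkS4class{MitoGenome} with at least one PCG.
#' @return list of class \code{CodonUsageTable}: \code{codons} data.frame
#'   (\code{codon}, \code{aa}, \code{count}, \code{family_size},
#'   \code{rscu}), \code{aa_freq} data.frame (\code{aa}, \code{count},
#'   \code{percent}), \code{total} codons counted.
#' @export
codonUsage <- function(genome) {
  ft <- featureTable(genome)
  pcg <- which(ft$kind == "PCG")
  if (!length(pcg)) stop("genome has no protein-coding genes")
  code <- Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
  counts <- stats::setNames(integer(length(code)), names(code))
  for (i in pcg) {
    cod <- pcgCodons(extractFeatureSequence(genome, ft[i, ]))
    if (!length(cod)) next
    aa <- code[cod]
    if (any(aa[-length(aa)] == "*"))
      warning("internal stop codon in ", ft$label[i], call. = FALSE)
    tab <- table(cod)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  aa <- unname(code[names(counts)])
  fam_size <- ave(counts, aa, FUN = length)
  fam_tot <- ave(counts, aa, FUN = sum)
  rscu <- ifelse(aa == "*" | fam_tot == 0, NA_real_,
                 counts * fam_size / fam_tot)
  codons <- data.frame(codon = names(counts), aa = aa,
                       count = as.integer(counts),
                       family_size = as.integer(fam_size),
                       rscu = as.numeric(rscu), stringsAsFactors = FALSE)
  sense <- codons[codons$aa != "*", ]
  aa_counts <- tapply(sense$count, sense$aa, sum)
  aa_freq <- data.frame(aa = names(aa_counts),
                        count = as.integer(aa_counts),
                        percent = 100 * as.integer(aa_counts) /
                          sum(aa_counts))
  rownames(aa_freq) <- NULL
  structure(list(codons = codons, aa_freq = aa_freq,
                 total = sum(counts)),
            class = "CodonUsageTable")
}

#' @export
print.CodonUsageTable <- function(x, ...) {
  cat("Codon usage over", x$total, "codons;",
      sum(!is.na(x$codons$rscu)), "codons carry RSCU\n")
  top <- x$codons[order(-x$codons$rscu), ]
  top <- top[!is.na(top$rscu), ][1:5, ]
  cat("highest RSCU:",
      paste(sprintf("%s(%s)=%.2f", top$codon, top$aa, top$rscu),
            collapse = ", "), "\n")
  invisible(x)
}

#' Start and stop codons of every protein-coding gene
#'
#' The start codon is the first coding-strand triplet, recorded verbatim
#' and flagged when it is not ATN. The stop is the final complete triplet
#' when the CDS length is a multiple of 3; otherwise the truncated forms
#' "T--" (length = 3n+1, last base T) or "TA-" (length = 3n+2, last two
#' TA), completed in vivo by post-transcriptional polyadenylation.
#' Truncated tails that do not conform are flagged.
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @return data.frame: \code{gene}, \code{start_codon}, \code{stop_codon},
#'   \code{start_ATN}, \code{truncated}, \code{flag}.
#' @export
startStopCodons <- function(genome) {
  ft <- featureTable(genome)
  pcg <- which(ft$kind == "PCG")
  if (!length(pcg)) stop("genome has no protein-coding genes")
  rows <- lapply(pcg, function(i) {
    cds <- extractFeatureSequence(genome, ft[i, ])
    n <- nchar(cds)
    if (n < 6L) stop("CDS of ", ft$label[i], " shorter than 6 bases")
    start <- substr(cds, 1L, 3L)
    rem <- n %% 3L
    flag <- ""
    if (rem == 0L) {
      stop_c <- substr(cds, n - 2L, n)
      trunc <- FALSE
    } else if (rem == 1L) {
      trunc <- TRUE
      stop_c <- "T--"
      if (substr(cds, n, n) != "T") {
        flag <- "non-conforming truncated tail"
        stop_c <- paste0(substr(cds, n, n), "--")
      }
    } else {
      trunc <- TRUE
      stop_c <- "TA-"
      if (substr(cds, n - 1L, n) != "TA") {
        flag <- "non-conforming truncated tail"
        stop_c <- paste0(substr(cds, n - 1L, n), "-")
      }
    }
    start_atn <- grepl("^AT[ACGT]$", start)
    if (!start_atn)
      flag <- trimws(paste(flag, "non-ATN start"))
    data.frame(gene = ft$label[i], start_codon = start,
               stop_codon = stop_c, start_ATN = start_atn,
               truncated = trunc, flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of the genome occupied by protein-coding genes
#'
#' @param genome a \linkS4class{MitoGenome}.
#' @return percent of genome length covered by PCG spans, rounded to
#'   2 decimals.
#' @examples
#' # 11,124 coding bases on a 19,720 bp genome -> 56.41
#' @export
pcgFraction <- function(genome) {
  ft <- featureTable(genome)
  pcg <- ft[ft$kind == "PCG", , drop = FALSE]
  if (!nrow(pcg)) return(0)
  L <- genomeLength(genome)
  round(sum(spanLength(pcg$start, pcg$end, L)) / L * 100, 2)
}
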