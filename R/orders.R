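## shipped gene-order templates and typical feature lengths

#' Gene-order templates
#'
#' The three architecture states used throughout the package, anchored
#' at 12S:
#' \describe{
#'   \item{"canonical"}{the typical vertebrate order (as in *Xenopus
#'     laevis*): ... H, S(AGY), L(CUN), ND5, ND6, E, CYTB, T, P, CR, F,
#'     12S; ATP8 present.}
#'   \item{"LTPF-single-CR"}{the ancestral rhacophorid state (as in
#'     *Buergeria buergeri*): ND5 shifted downstream of the control
#'     region, the LTPF tRNA cluster upstream of 12S, one CR; ATP8
#'     present.}
#'   \item{"TLPF-dual-CR"}{the derived *Polypedates* state: duplicated
#'     control regions flanking ND5 (CYTB, CR1, ND5, CR2), the TLPF
#'     cluster, and a non-coding region at the ancestral ATP8 locus.}
#' }
#'
#' @param template template name.
#' @return data.frame: \code{label}, \code{kind}, \code{strand} in
#'   circular order starting at 12S.
#' @export
geneOrderTemplate <- function(template = c("canonical", "LTPF-single-CR",
                                           "TLPF-dual-CR")) {
  template <- match.arg(template)
  ## shared head: 12S .. tRNA-Lys (L-strand genes carry "-")
  head <- c("12S", "V", "16S", "L(UUR)", "ND1", "I", "-Q", "M", "ND2",
            "W", "-A", "-N", "OL", "-C", "-Y", "COI", "-S(UCN)", "D",
            "COII", "K")
  mid <- c("ATP6", "COIII", "G", "ND3", "R", "ND4L", "ND4", "H",
           "S(AGY)")
  tail <- switch(template,
    "canonical" = c("L(CUN)", "ND5", "-ND6", "-E", "CYTB", "T", "-P",
                    "CR", "F"),
    "LTPF-single-CR" = c("-ND6", "-E", "CYTB", "CR", "ND5", "L(CUN)",
                         "T", "-P", "F"),
    "TLPF-dual-CR" = c("-ND6", "-E", "CYTB", "CR1", "ND5", "CR2", "T",
                       "L(CUN)", "-P", "F"))
  atp8 <- if (template == "TLPF-dual-CR") "NCR" else "ATP8"
  labels <- c(head, atp8, mid, tail)
  strand <- ifelse(startsWith(labels, "-"), "L", "H")
  labels <- sub("^-", "", labels)
  vocab <- featureVocabulary()
  kind <- vapply(labels, function(l) {
    for (k in names(vocab)) if (l %in% vocab[[k]]) return(k)
    stop("label ", l, " not in vocabulary")
  }, "", USE.NAMES = FALSE)
  data.frame(label = labels, kind = kind, strand = strand,
             stringsAsFactors = FALSE)
}

#' Typical mitochondrial feature lengths (bp)
#'
#' Round figures for an anuran mitogenome, used by the synthetic
#' generator and fixtures; tRNAs default to 70 bp (real ones span
#' 65-74).
#'
#' @return named integer vector.
#' @export
typicalFeatureLengths <- function() {
  c(ND1 = 960, ND2 = 1038, COI = 1551, COII = 688, ATP8 = 165,
    ATP6 = 684, COIII = 784, ND3 = 340, ND4L = 297, ND4 = 1378,
    ND5 = 1812, ND6 = 501, CYTB = 1141,
    `12S` = 930, `16S` = 1537,
    CR = 1400, CR1 = 1401, CR2 = 2264, NCR = 869, OL = 30,
    tRNA = 70)
}

featureLengthFor <- function(label, kind,
                             lengths = typicalFeatureLengths()) {
  if (label %in% names(lengths)) unname(lengths[label])
  else if (kind == "tRNA") unname(lengths["tRNA"])
  else stop("no length for ", label)
}
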