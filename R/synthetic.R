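## seeded synthetic mitogenome and control-region generators with
## ground-truth records

#' Specification for a synthetic mitogenome
#'
#' Bundles the planted parameters of [generateGenome()]. Defaults
#' emulate a *Polypedates*-like genome: the TLPF-dual-CR architecture,
#' whole-genome AT content 61% with a slightly negative AT skew and a
#' strongly negative GC skew, AT-rich control regions carrying a planted
#' 38-bp tandem repeat at the 5' end, closely similar CR paralogs, and a
#' non-coding region at the ATP8 locus built by one of the two loss
#' pathways.
#'
#' @param template gene-order template (see [geneOrderTemplate()]).
#' @param at_content,at_skew,gc_skew whole-genome base composition
#'   targets (fractions / dimensionless).
#' @param cr_at_content AT-content target inside control regions.
#' @param cr_repeat list: \code{unit_length}, \code{copies},
#'   \code{mutation_rate} for the planted 5' tandem repeat.
#' @param cr_divergence per-site divergence planted between CR paralogs.
#' @param ncr_pathway "duplication-degeneration" or "direct-mutation"
#'   (only used by dual-CR templates, whose ATP8 locus is an NCR).
#' @param ncr_mutation_rate per-site decay of the NCR remnants.
#' @param truncated_stop_genes PCGs given a truncated "T--" stop.
#' @return list of class \code{SyntheticSpec}.
#' @export
syntheticSpec <- function(template = "TLPF-dual-CR",
                          at_content = 0.61, at_skew = -0.010,
                          gc_skew = -0.246, cr_at_content = 0.66,
                          cr_repeat = list(unit_length = 38L,
                                           copies = 3L,
                                           mutation_rate = 0.02),
                          cr_divergence = 0.02,
                          ncr_pathway = "duplication-degeneration",
                          ncr_mutation_rate = 0.2,
                          truncated_stop_genes = c("ND3", "CYTB")) {
  rates <- c(cr_repeat$mutation_rate, cr_divergence, ncr_mutation_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (at_content < 0 || at_content > 1) stop("at_content in [0, 1]")
  structure(list(template = template, at_content = at_content,
                 at_skew = at_skew, gc_skew = gc_skew,
                 cr_at_content = cr_at_content, cr_repeat = cr_repeat,
                 cr_divergence = cr_divergence,
                 ncr_pathway = ncr_pathway,
                 ncr_mutation_rate = ncr_mutation_rate,
                 truncated_stop_genes = truncated_stop_genes),
            class = "SyntheticSpec")
}

MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")

randomCodingSeq <- function(n_codons, probs, stops = MITO_STOPS) {
  cods <- vapply(seq_len(n_codons), function(i) randomSeq(3L, probs), "")
  bad <- which(cods %in% stops)
  while (length(bad)) {
    cods[bad] <- vapply(bad, function(i) randomSeq(3L, probs), "")
    bad <- which(cods %in% stops)
  }
  paste(cods, collapse = "")
}

## one control region: planted 5' tandem repeat + conserved remainder
buildCR <- function(target_len, probs, repeat_plan) {
  unit <- randomSeq(repeat_plan$unit_length, probs)
  copies <- vapply(seq_len(repeat_plan$copies), function(i)
    mutateSeq(unit, repeat_plan$mutation_rate), "")
  rep_seq <- paste(copies, collapse = "")
  rest <- target_len - nchar(rep_seq)
  if (rest < 0) stop("repeat array exceeds the control-region length")
  list(seq = paste0(rep_seq, randomSeq(rest, probs)),
       unit = unit, period = repeat_plan$unit_length,
       copies = repeat_plan$copies,
       repeat_span = c(1L, nchar(rep_seq)))
}

#' Generate a synthetic annotated mitogenome with ground truth
#'
#' Builds a circular genome realizing a [syntheticSpec()]: the gene
#' order equals the template; per-region base frequencies are drawn
#' i.i.d. to match the planted content and skews in expectation; PCGs
#' get valid start codons, in-frame-stop-free bodies and complete or
#' planted truncated stop codons; control regions carry the planted
#' tandem repeat and paralog divergence; dual-CR templates receive an
#' NCR built by the requested ATP8-loss pathway. Deterministic given the
#' seed.
#'
#' @param spec a [syntheticSpec()].
#' @param seed integer seed (mandatory).
#' @return list: \code{genome} (a \linkS4class{MitoGenome}),
#'   \code{truth} (planted values as realized).
#' @export
generateGenome <- function(spec = syntheticSpec(), seed) {
  withSeed(seed, {
    tmpl <- geneOrderTemplate(spec$template)
    probs <- baseProbs(spec$at_content, spec$at_skew, spec$gc_skew)
    cr_probs <- baseProbs(spec$cr_at_content, 0, spec$gc_skew)
    lengths <- typicalFeatureLengths()
    seqs <- character(nrow(tmpl))
    truth <- list(template = spec$template, seed = seed,
                  at_content = spec$at_content,
                  at_skew = spec$at_skew, gc_skew = spec$gc_skew)
    cr1_seq <- NULL
    for (i in seq_len(nrow(tmpl))) {
      lab <- tmpl$label[i]; kind <- tmpl$kind[i]
      if (kind == "PCG") {
        len <- featureLengthFor(lab, kind, lengths)
        trunc <- lab %in% spec$truncated_stop_genes
        n_cod <- if (trunc) (len - 1L) %/% 3L - 1L else len %/% 3L - 2L
        body <- randomCodingSeq(n_cod, probs)
        seqs[i] <- if (trunc) paste0("ATG", body, "T")
                   else paste0("ATG", body, "TAA")
      } else if (kind == "tRNA") {
        seqs[i] <- randomSeq(sample(65:74, 1L), probs)
      } else if (kind == "CR") {
        if (is.null(cr1_seq)) {
          cr <- buildCR(featureLengthFor(lab, kind, lengths), cr_probs,
                        spec$cr_repeat)
          seqs[i] <- cr$seq
          cr1_seq <- cr$seq
          truth$cr_repeat <- cr[c("unit", "period", "copies",
                                  "repeat_span")]
        } else {
          seqs[i] <- mutateSeq(cr1_seq, spec$cr_divergence)
          nmis <- sum(strsplit(seqs[i], "")[[1]] !=
                        strsplit(cr1_seq, "")[[1]])
          truth$cr_divergence <- spec$cr_divergence
          truth$cr_identity <- 100 * (1 - nmis / nchar(cr1_seq))
        }
      } else if (kind == "NCR") {
        seqs[i] <- ""  # filled below, needs COII/K/ATP8 refs
      } else {
        seqs[i] <- randomSeq(featureLengthFor(lab, kind, lengths), probs)
      }
    }
    ncr_i <- which(tmpl$kind == "NCR")
    if (length(ncr_i)) {
      refs <- list(
        COII = seqs[tmpl$label == "COII"],
        K = seqs[tmpl$label == "K"],
        ATP8 = {  # reference ATP8 from the ancestral, pre-loss state
          len <- featureLengthFor("ATP8", "PCG", lengths)
          paste0("ATG", randomCodingSeq(len %/% 3L - 2L, probs), "TAA")
        })
      planted <- plantNCRImpl(spec$ncr_pathway, refs,
                              spec$ncr_mutation_rate)
      seqs[ncr_i] <- planted$sequence
      truth$ncr <- planted$truth
      truth$ncr_refs <- refs
    }
    ## assemble: abutting features on the H strand, L-strand features
    ## stored as reverse complement
    genome_parts <- ifelse(tmpl$strand == "L",
                           vapply(seqs, revComp, ""), seqs)
    lens <- nchar(seqs)
    ends <- cumsum(lens)
    starts <- ends - lens
    feats <- data.frame(label = tmpl$label, kind = tmpl$kind,
                        strand = tmpl$strand,
                        start = as.integer(starts),
                        end = as.integer(ends),
                        anticodon = NA_character_,
                        stringsAsFactors = FALSE)
    truth$feature_lengths <- stats::setNames(lens, tmpl$label)
    truth$genome_length <- sum(lens)
    genome <- MitoGenome(paste0("synthetic-", spec$template),
                         paste(genome_parts, collapse = ""), feats)
    list(genome = genome, truth = truth)
  })
}

#' Default species tree for control-region simulations
#'
#' A fixed ultrametric 7-taxon tree of depth 1 with terminal branches of
#' at least 0.3 (time units are arbitrary; rates are per unit branch
#' length). Terminal branches this long give homogenization time to act
#' within every tip lineage, the regime the concerted-evolution test is
#' designed for.
#'
#' @return a \code{phylo} tree.
#' @export
defaultCRTree <- function() {
  ape::read.tree(text = paste0(
    "((sp1:0.4,sp2:0.4):0.6,((sp3:0.35,sp4:0.35):0.3,",
    "(sp5:0.4,(sp6:0.3,sp7:0.3):0.1):0.25):0.35);"))
}

#' Simulate duplicated control regions under concerted or independent
#' evolution
#'
#' Both CR copies arise by a duplication on a stem of length
#' \code{dup_stem} above the species-tree root and then evolve by
#' i.i.d. per-site substitutions (transition bias 2:1) along the tree.
#' In concerted mode, gene-conversion events (Poisson with rate
#' \code{homogenization_rate} per unit branch length) overwrite one
#' paralog with the other, in a random direction, within a lineage; in
#' independent mode the copies never exchange. An outgroup with a single
#' CR is simulated from the pre-duplication ancestor.
#'
#' @param tree species tree with branch lengths
#'   (default [defaultCRTree()]).
#' @param mode "concerted" or "independent".
#' @param subst_rate substitutions per site per unit branch length.
#' @param homogenization_rate gene-conversion events per unit branch
#'   length (concerted mode).
#' @param seq_length CR length in bases (no indels, so the output is
#'   already aligned).
#' @param dup_stem branch length between the duplication and the root.
#' @param outgroup_depth branch length from the pre-duplication ancestor
#'   to the outgroup tip.
#' @param seed integer seed (mandatory).
#' @return list: \code{sequences} named character vector
#'   ("species|CR1", "species|CR2", ..., "outgroup"), \code{truth}
#'   (mode, rates, per-tip homogenization on the terminal branch).
#' @export
simulateCREvolution <- function(tree = defaultCRTree(),
                                mode = c("concerted", "independent"),
                                subst_rate = 0.2,
                                homogenization_rate = 20,
                                seq_length = 800L, dup_stem = 0.5,
                                outgroup_depth = 1.6, seed) {
  mode <- match.arg(mode)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (all(tree$edge.length == 0) &&
      (subst_rate > 0 || homogenization_rate > 0))
    warning("zero-length tree with nonzero rates", call. = FALSE)
  withSeed(seed, {
    psub <- function(t) 1 - exp(-subst_rate * t)
    anc <- randomSeq(seq_length, baseProbs(0.62))
    out_seq <- mutateSeq(anc, psub(outgroup_depth))
    c1 <- mutateSeq(anc, psub(dup_stem))
    c2 <- mutateSeq(anc, psub(dup_stem))
    ntip <- length(tree$tip.label)
    rootn <- ntip + 1L
    res <- character(0)
    terminal_homog <- stats::setNames(logical(ntip), tree$tip.label)
    recurse <- function(node, s1, s2) {
      kids <- tree$edge[tree$edge[, 1] == node, , drop = FALSE]
      for (r in seq_len(nrow(kids))) {
        child <- kids[r, 2]
        t <- tree$edge.length[which(tree$edge[, 1] == node &
                                      tree$edge[, 2] == child)[1]]
        k <- if (mode == "concerted") stats::rpois(1L,
                                                  homogenization_rate * t)
             else 0L
        if (k > 0L) {
          u <- max(stats::runif(k))  # time of the last conversion event
          a <- mutateSeq(s1, psub(u * t))
          b <- mutateSeq(s2, psub(u * t))
          if (stats::runif(1) < 0.5) b <- a else a <- b
          a <- mutateSeq(a, psub((1 - u) * t))
          b <- mutateSeq(b, psub((1 - u) * t))
        } else {
          a <- mutateSeq(s1, psub(t))
          b <- mutateSeq(s2, psub(t))
        }
        if (child <= ntip) {
          sp <- tree$tip.label[child]
          res[paste0(sp, "|CR1")] <<- a
          res[paste0(sp, "|CR2")] <<- b
          terminal_homog[sp] <<- k > 0L
        } else {
          recurse(child, a, b)
        }
      }
    }
    recurse(rootn, c1, c2)
    res["outgroup"] <- out_seq
    list(sequences = res,
         truth = list(mode = mode, subst_rate = subst_rate,
                      homogenization_rate = homogenization_rate,
                      dup_stem = dup_stem, seed = seed,
                      terminal_homogenization = terminal_homog))
  })
}

plantNCRImpl <- function(pathway, refs, mutation_rate,
                         coii_tail = 100L) {
  need <- c("ATP8", "K", "COII")
  if (!all(need %in% names(refs)))
    stop("refs must include ", paste(need, collapse = ", "))
  if (mutation_rate > 0.5)
    warning("mutation rate above 0.5: classification is not expected ",
            "to succeed", call. = FALSE)
  template <- switch(pathway,
    "duplication-degeneration" = {
      co <- refs$COII
      tail_seq <- substr(co, max(1L, nchar(co) - coii_tail + 1L),
                         nchar(co))
      paste0(tail_seq, refs$K, refs$ATP8)
    },
    "direct-mutation" = refs$ATP8,
    stop("unknown pathway '", pathway, "'"))
  seq <- mutateSeq(template, mutation_rate)
  list(sequence = seq,
       truth = list(pathway = pathway, mutation_rate = mutation_rate,
                    template_length = nchar(template)))
}

#' Build a non-coding region by a planted ATP8-loss pathway
#'
#' Constructs an NCR either as the decayed tandem duplication of the
#' COII-tail + tRNA-Lys + ATP8 block (duplication-degeneration, the
#' large-NCR pathway) or as ATP8 decayed in place (direct-mutation, the
#' small-NCR pathway), mutating the template at the given per-site
#' rate. Deterministic given the seed.
#'
#' @param pathway "duplication-degeneration" or "direct-mutation".
#' @param refs named sequences: \code{ATP8}, \code{K} (tRNA-Lys),
#'   \code{COII}.
#' @param mutation_rate per-site decay rate (warning above 0.5).
#' @param seed integer seed (mandatory).
#' @param coii_tail how much of the COII 3' end enters the duplicated
#'   block (bases).
#' @return list: \code{sequence}, \code{truth}.
#' @export
plantNCR <- function(pathway, refs, mutation_rate = 0.2, seed,
                     coii_tail = 100L) {
  withSeed(seed, plantNCRImpl(pathway, refs, mutation_rate, coii_tail))
}
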