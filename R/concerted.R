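## paralog-vs-ortholog clustering test for duplicated control regions:
## distances -> neighbor joining -> bootstrap -> verdict

alignedToMatrix <- function(aligned) {
  if (is(aligned, "DNAStringSet")) {
    nms <- names(aligned)
    aligned <- as.character(aligned)
    names(aligned) <- nms
  }
  if (is.character(aligned) && !is.matrix(aligned)) {
    if (length(unique(nchar(aligned))) != 1L)
      stop("aligned sequences must have equal length")
    m <- do.call(rbind, strsplit(tolower(aligned), ""))
    rownames(m) <- names(aligned)
    aligned <- m
  }
  if (is.null(rownames(aligned)) || anyDuplicated(rownames(aligned)))
    stop("aligned input needs unique names")
  aligned
}

#' Pairwise distances from an alignment
#'
#' Proportion of differing sites over gap-free positions per pair
#' (p-distance), optionally transformed with the Kimura two-parameter
#' correction. p-distances need not satisfy the triangle inequality
#' exactly; neighbor joining does not require it.
#'
#' @param aligned named character vector, character matrix or
#'   \code{DNAStringSet} of equal-length aligned sequences.
#' @param model "p" (raw proportion) or "K2P".
#' @return a \code{dist} object.
#' @export
pDistanceMatrix <- function(aligned, model = c("p", "K2P")) {
  model <- match.arg(model)
  m <- alignedToMatrix(aligned)
  db <- ape::as.DNAbin(m)
  d <- ape::dist.dna(db, model = if (model == "p") "raw" else "K80",
                     pairwise.deletion = TRUE)
  if (any(!is.finite(d)))
    stop("a sequence pair has no gap-free overlap (or is saturated)")
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor joining. Ties in the Q criterion are
#' broken by the lowest-index pair, making the reconstruction
#' deterministic for a given label order.
#'
#' @param d a \code{dist} or symmetric matrix over >= 4 taxa.
#' @return an unrooted \code{phylo} tree.
#' @export
njTree <- function(d) {
  if (inherits(d, "dist")) n <- attr(d, "Size") else n <- nrow(d)
  if (n < 4L) stop("neighbor joining needs at least 4 taxa")
  ape::nj(d)
}

#' Neighbor-joining tree with column-resampling bootstrap supports
#'
#' Builds the point-estimate tree from the full alignment, then
#' resamples alignment columns with replacement \code{n_replicates}
#' times, rebuilds the tree per replicate, and writes the percentage of
#' replicates containing each internal bipartition of the point tree
#' into \code{node.label}.
#'
#' @param aligned as for [pDistanceMatrix()].
#' @param n_replicates bootstrap replicates (>= 1).
#' @param seed mandatory integer seed.
#' @param model distance model passed on.
#' @return a \code{phylo} tree with \code{node.label} supports in
#'   [0, 100] (root label \code{NA}).
#' @export
bootstrapSupport <- function(aligned, n_replicates = 100L, seed,
                             model = c("p", "K2P")) {
  model <- match.arg(model)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  m <- alignedToMatrix(aligned)
  point <- njTree(pDistanceMatrix(m, model))
  reps <- withSeed(seed, {
    lapply(seq_len(n_replicates), function(i) {
      cols <- sample.int(ncol(m), replace = TRUE)
      njTree(pDistanceMatrix(m[, cols, drop = FALSE], model))
    })
  })
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  point$node.label <- round(100 * counts / n_replicates, 1)
  point$node.label[1] <- NA  # root of the unrooted representation
  point
}

parseCRLabels <- function(labels, outgroup) {
  m <- regmatches(labels, regexec("^(.*)[|_]CR([12])$", labels))
  data.frame(
    label = labels,
    species = vapply(m, function(x) if (length(x)) x[2] else NA_character_,
                     ""),
    copy = vapply(m, function(x) if (length(x)) x[3] else NA_character_,
                  ""),
    is_outgroup = labels == outgroup,
    stringsAsFactors = FALSE)
}

#' Do paralogous control regions cluster within individuals?
#'
#' Roots the tree at the designated outgroup and checks, for every
#' species carrying two control-region leaves ("species|CR1",
#' "species|CR2"; an underscore separator is also accepted), whether the
#' two form a two-leaf clade (a paralog cherry). Concerted evolution
#' predicts paralog cherries for every species; independent evolution
#' predicts separate CR1 and CR2 clusters.
#'
#' @param tree a \code{phylo} tree, e.g. from [bootstrapSupport()].
#' @param outgroup leaf label used to root the tree.
#' @return list of class \code{ConcertedVerdict}: \code{per_species}
#'   data.frame (\code{species}, \code{paralogs_sister},
#'   \code{support}), \code{mode} one of "concerted", "independent",
#'   "mixed".
#' @export
paralogClusteringVerdict <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a leaf of the tree")
  info <- parseCRLabels(tree$tip.label, outgroup)
  rooted <- ape::root(tree, outgroup, resolve.root = TRUE)
  species <- unique(info$species[!is.na(info$species) & !info$is_outgroup])
  rows <- lapply(species, function(sp) {
    leaves <- info$label[!is.na(info$species) & info$species == sp]
    if (length(leaves) != 2L) {
      warning("species '", sp, "' has ", length(leaves),
              " CR leaves; skipped", call. = FALSE)
      return(NULL)
    }
    mrca <- ape::getMRCA(rooted, leaves)
    ndesc <- length(descendantTips(rooted, mrca))
    supp <- NA_real_
    if (!is.null(rooted$node.label)) {
      lab <- rooted$node.label[mrca - ape::Ntip(rooted)]
      supp <- suppressWarnings(as.numeric(lab))
    }
    data.frame(species = sp, paralogs_sister = ndesc == 2L,
               support = supp, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  mode <- if (is.null(per) || !nrow(per)) "mixed"
          else if (all(per$paralogs_sister)) "concerted"
          else if (!any(per$paralogs_sister)) "independent"
          else "mixed"
  structure(list(per_species = per, mode = mode),
            class = "ConcertedVerdict")
}

descendantTips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descendantTips, tree = tree))
}

#' @export
print.ConcertedVerdict <- function(x, ...) {
  cat("Concerted-evolution verdict:", x$mode, "\n")
  if (!is.null(x$per_species) && nrow(x$per_species)) {
    ok <- sum(x$per_species$paralogs_sister)
    cat(ok, "of", nrow(x$per_species),
        "species have their CR paralogs as sisters\n")
  }
  invisible(x)
}

#' End-to-end concerted-evolution test
#'
#' Convenience wrapper: distances, neighbor joining, bootstrap, verdict.
#'
#' @param aligned aligned CR sequences with "species|CR1"-style names
#'   plus the outgroup.
#' @param outgroup outgroup leaf name.
#' @param n_replicates bootstrap replicates.
#' @param seed integer seed.
#' @param model distance model.
#' @return list: \code{tree} (with supports), \code{verdict}.
#' @export
concertedEvolutionTest <- function(aligned, outgroup,
                                   n_replicates = 100L, seed,
                                   model = c("p", "K2P")) {
  tree <- bootstrapSupport(aligned, n_replicates, seed, model)
  list(tree = tree, verdict = paralogClusteringVerdict(tree, outgroup))
}
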