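## tandem duplication-random loss (TDRL) model on anchored gene orders

setMethod("show", "TDRLEvent", function(object) {
  cat("TDRLEvent: duplicate block [", object@block[1], "..",
      object@block[2], "], retain ",
      paste(substr(object@retention, 1, 1), collapse = ""),
      " (f=first copy, s=second copy)\n", sep = "")
})

setMethod("show", "PathwayScript", function(object) {
  cat("PathwayScript (", length(object@steps), " steps): ",
      if (!is.na(object@description)) object@description else "", "\n",
      sep = "")
})

#' Apply one TDRL event to a gene order
#'
#' The block is duplicated in tandem and, for every gene, the copy named
#' in the retention vector survives. The result is the permutation
#' prefix + (block genes retained in the first copy, in block order) +
#' (block genes retained in the second copy, in block order) + suffix,
#' re-anchored at the input anchor. Strands are unchanged.
#'
#' @param order a \linkS4class{GeneOrder}.
#' @param event a \linkS4class{TDRLEvent}; block indices refer to the
#'   anchored linearization of \code{order}.
#' @return a \linkS4class{GeneOrder}.
#' @examples
#' o <- GeneOrder(c("L(CUN)", "T", "P", "F"))
#' e <- TDRLEvent(1, 2, c("second", "first"))
#' orderLabels(applyTDRL(o, e))   # TLPF: the derived rhacophorid swap
#' @export
applyTDRL <- function(order, event) {
  validObject(event)
  labs <- orderLabels(order)
  str <- orderStrands(order)
  n <- length(labs)
  if (event@block[2] > n)
    stop("block exceeds order length ", n)
  idx <- seq(event@block[1], event@block[2])
  first <- idx[event@retention == "first"]
  second <- idx[event@retention == "second"]
  perm <- c(seq_len(event@block[1] - 1L), first, second,
            if (event@block[2] < n) seq(event@block[2] + 1L, n))
  GeneOrder(labs[perm], str[perm], anchor = orderAnchor(order))
}

## canonical form of an event: leading 'first' and trailing 'second'
## retentions leave those genes in place, so trim them; an all-identity
## event canonicalizes to NULL
canonicalTDRL <- function(event) {
  r <- event@retention
  from <- event@block[1]
  while (length(r) && r[1] == "first") { r <- r[-1]; from <- from + 1L }
  while (length(r) && r[length(r)] == "second") r <- r[-length(r)]
  if (!length(r)) return(NULL)
  TDRLEvent(from, from + length(r) - 1L, r)
}

eventKey <- function(event) {
  paste(event@block[1], event@block[2],
        paste(substr(event@retention, 1, 1), collapse = ""), sep = ":")
}

#' Enumerate single TDRL events transforming one order into another
#'
#' Exhaustively enumerates all duplication blocks and copy-retention
#' vectors and returns every event whose application to \code{a} yields
#' \code{b}, in canonical form (uninvolved block edges trimmed) and
#' deduplicated. An empty list means \code{b} is not reachable from
#' \code{a} in one TDRL step; if \code{a} equals \code{b} the single
#' canonical no-change event is reported as an attribute
#' \code{zero_rearrangements = TRUE} with an empty event list.
#'
#' @param a,b \linkS4class{GeneOrder}s over the same label multiset, the
#'   same strands and the same anchor.
#' @param max_labels enumeration cutoff; orders longer than this are
#'   rejected (combinatorial explosion).
#' @return list of \linkS4class{TDRLEvent}s (possibly empty), with
#'   attribute \code{zero_rearrangements}.
#' @export
inferSingleTDRL <- function(a, b, max_labels = 14L) {
  la <- orderLabels(a); lb <- orderLabels(b)
  if (!setequal(la, lb) || length(la) != length(lb))
    stop("orders are over different label sets")
  if (orderAnchor(a) != orderAnchor(b))
    stop("orders have different anchors")
  sa <- orderStrands(a)[order(la)]
  sb <- orderStrands(b)[order(lb)]
  if (!identical(sa, sb))
    stop("orders assign different strands (TDRL preserves strands)")
  n <- length(la)
  if (n > max_labels)
    stop("order longer than ", max_labels,
         " labels; exhaustive enumeration refused")
  if (identical(la, lb)) {
    out <- list()
    attr(out, "zero_rearrangements") <- TRUE
    return(out)
  }
  found <- list()
  seen <- character()
  for (i in seq_len(n)) {
    for (j in seq(i, n)) {
      k <- j - i + 1L
      for (mask in 0:(2^k - 1L)) {
        ret <- ifelse(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0,
                      "second", "first")
        ev <- TDRLEvent(i, j, ret)
        if (identical(orderLabels(applyTDRL(a, ev)), lb)) {
          cev <- canonicalTDRL(ev)
          if (is.null(cev)) next
          key <- eventKey(cev)
          if (!key %in% seen) {
            seen <- c(seen, key)
            found <- c(found, cev)
          }
        }
      }
    }
  }
  attr(found, "zero_rearrangements") <- FALSE
  found
}

## apply one annotated non-TDRL step: substitute a contiguous label run
applyReplaceStep <- function(order, step) {
  labs <- orderLabels(order)
  str <- orderStrands(order)
  n <- length(labs)
  m <- length(step$from)
  hit <- which(vapply(seq_len(n), function(i)
    all(labs[((i + seq_len(m) - 2L) %% n) + 1L] == step$from), TRUE))
  if (length(hit) != 1L)
    stop("replace step: segment (", paste(step$from, collapse = ","),
         ") matches ", length(hit), " positions")
  ## rotate so the matched segment is contiguous at the front, substitute,
  ## then re-anchor
  rot <- ((hit + seq_len(n) - 2L) %% n) + 1L
  labs <- labs[rot]; str <- str[rot]
  to_strands <- if (!is.null(step$to_strands)) step$to_strands
                else rep("H", length(step$to))
  GeneOrder(c(step$to, labs[-seq_len(m)]),
            c(to_strands, str[-seq_len(m)]),
            anchor = orderAnchor(order))
}

#' Replay a rearrangement pathway script and verify its endpoint
#'
#' Applies each step of the script in turn (TDRL events via
#' [applyTDRL()], annotated duplication/degeneration steps by segment
#' replacement) and compares the final order with the expected end.
#'
#' @param script a \linkS4class{PathwayScript}.
#' @return list: \code{pass} logical, \code{intermediates} list of
#'   \linkS4class{GeneOrder}s after each step, \code{failed_step} index of
#'   the first failing step or \code{NA}.
#' @export
verifyPathway <- function(script) {
  cur <- script@start
  inter <- list()
  for (s in seq_along(script@steps)) {
    step <- script@steps[[s]]
    res <- tryCatch({
      if (step$type == "tdrl") applyTDRL(cur, step$event)
      else if (step$type == "replace") applyReplaceStep(cur, step)
      else stop("unknown step type '", step$type, "'")
    }, error = function(e) e)
    if (inherits(res, "error"))
      return(list(pass = FALSE, intermediates = inter, failed_step = s,
                  error = conditionMessage(res)))
    cur <- res
    inter[[s]] <- cur
  }
  pass <- identical(orderLabels(cur), orderLabels(script@end)) &&
    identical(orderStrands(cur), orderStrands(script@end))
  list(pass = pass, intermediates = inter,
       failed_step = if (pass) NA_integer_ else length(script@steps) + 1L)
}

## ---------------------------------------------------------------------
## YAML serialization of pathway scripts

orderToList <- function(o)
  list(labels = as.list(orderLabels(o)), strands = as.list(orderStrands(o)),
       anchor = orderAnchor(o))

orderFromList <- function(x)
  GeneOrder(unlist(x$labels), unlist(x$strands), anchor = x$anchor)

#' Read or write a pathway script as YAML
#'
#' @param path YAML file.
#' @return [readPathwayScript()]: a \linkS4class{PathwayScript}.
#' @export
readPathwayScript <- function(path) {
  y <- yaml::read_yaml(path)
  steps <- lapply(y$steps, function(s) {
    if (s$type == "tdrl")
      list(type = "tdrl",
           event = TDRLEvent(s$block[[1]], s$block[[2]],
                             unlist(s$retention)),
           note = s$note)
    else
      list(type = "replace", from = unlist(s$from), to = unlist(s$to),
           to_strands = if (!is.null(s$to_strands)) unlist(s$to_strands),
           note = s$note)
  })
  PathwayScript(orderFromList(y$start), orderFromList(y$end), steps,
                description = if (!is.null(y$description)) y$description
                              else NA_character_)
}

#' @rdname readPathwayScript
#' @param script a \linkS4class{PathwayScript}.
#' @export
writePathwayScript <- function(script, path) {
  steps <- lapply(script@steps, function(s) {
    if (s$type == "tdrl")
      list(type = "tdrl",
           block = as.list(s$event@block),
           retention = as.list(s$event@retention),
           note = s$note)
    else
      list(type = "replace", from = as.list(s$from), to = as.list(s$to),
           to_strands = as.list(s$to_strands), note = s$note)
  })
  yaml::write_yaml(list(description = script@description,
                        start = orderToList(script@start),
                        end = orderToList(script@end),
                        steps = steps), path)
  invisible(path)
}
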