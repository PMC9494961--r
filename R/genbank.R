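## minimal single-record GenBank flat-file reader
##
## Covers the subset of the format that annotated mitogenome submissions
## use: LOCUS, a FEATURES table with CDS/tRNA/rRNA/D-loop/rep_origin/
## misc_feature entries (plain, complement() and two-segment join() that
## wraps the origin), and an ORIGIN sequence block.

#' Load the label synonym table
#'
#' Maps depositor-side gene/product names (e.g. "COX1", "D-loop",
#' "tRNA-Lys") onto the package's controlled vocabulary. The table ships
#' as an editable TSV; pass your own to extend it.
#'
#' @param path TSV with columns \code{synonym}, \code{label}; default the
#'   shipped table.
#' @return named character vector: normalized synonym -> label.
#' @export
labelSynonyms <- function(path = system.file("extdata",
                                             "label_synonyms.tsv",
                                             package = "mitoarch")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$label, toupper(gsub("[ _]", "", tab$synonym)))
}

normalizeLabel <- function(raw, synonyms) {
  key <- toupper(gsub("[ _]", "", raw))
  unname(synonyms[key])
}

parseGbLocation <- function(loc) {
  loc <- gsub("[<>]", "", loc)
  strand <- "H"
  if (grepl("^complement\\(", loc)) {
    strand <- "L"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    parts <- strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",")[[1]]
    if (length(parts) != 2L)
      stop("only two-segment join() locations (origin wrap) are supported")
    a <- as.integer(strsplit(parts[1], "\\.\\.")[[1]])
    b <- as.integer(strsplit(parts[2], "\\.\\.")[[1]])
    if (b[1] != 1L)
      stop("join() does not wrap the origin: ", loc)
    return(list(start = a[1], end = b[2], strand = strand))
  }
  xs <- as.integer(strsplit(loc, "\\.\\.")[[1]])
  if (length(xs) == 1L) xs <- c(xs, xs)
  list(start = xs[1], end = xs[2], strand = strand)
}

#' Read a single-record GenBank flat file
#'
#' Parses the feature table and ORIGIN sequence of one GenBank record and
#' maps feature names onto the controlled vocabulary via [labelSynonyms()].
#' Unmapped features are kept with their file kind and raw name, with a
#' warning; an undisambiguated "tRNA-Leu"/"tRNA-Ser" is flagged rather
#' than silently assigned to one isoacceptor.
#'
#' @param path GenBank flat file with exactly one record.
#' @param synonyms synonym map from [labelSynonyms()].
#' @return a \linkS4class{MitoGenome}.
#' @export
readGenBank <- function(path, synonyms = labelSynonyms()) {
  lines <- readLines(path, warn = FALSE)
  if (sum(grepl("^LOCUS", lines)) != 1L)
    stop("expected exactly one LOCUS record")
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("record has no ORIGIN sequence")
  if (!length(fstart)) stop("record has no FEATURES table")
  oend <- grep("^//", lines)
  oend <- oend[oend > ostart][1]
  if (is.na(oend)) oend <- length(lines) + 1L
  seq <- toupper(gsub("[^A-Za-z]", "",
                      paste(lines[(ostart + 1L):(oend - 1L)],
                            collapse = "")))

  flines <- lines[(fstart + 1L):(ostart - 1L)]
  ## feature rows start with a key at column 6; continuation lines are
  ## further indented
  keyrows <- grep("^ {5}\\S", flines)
  kind_map <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                "D-loop" = "CR", rep_origin = "OL",
                misc_feature = "NCR")
  feats <- emptyFeatures()
  for (k in seq_along(keyrows)) {
    from <- keyrows[k]
    to <- if (k < length(keyrows)) keyrows[k + 1L] - 1L else length(flines)
    key <- sub("^ {5}(\\S+).*$", "\\1", flines[from])
    if (key == "source" || !key %in% names(kind_map)) next
    body <- paste(sub("^ {5}\\S+\\s*", "", flines[from]),
                  paste(trimws(flines[seq(from + 1L, length.out =
                                            max(0L, to - from))]),
                        collapse = " "))
    loc_txt <- sub("^(\\S+).*$", "\\1", trimws(body))
    ## location may continue before the first qualifier
    loc_txt <- strsplit(trimws(body), "/")[[1]][1]
    loc <- parseGbLocation(gsub("\\s", "", loc_txt))
    qual <- function(name) {
      m <- regmatches(body, regexpr(paste0("/", name,
                                           "=\"[^\"]*\""), body))
      if (!length(m)) return(NA_character_)
      sub("\"$", "", sub(paste0("^/", name, "=\""), "", m))
    }
    raw <- qual("gene")
    if (is.na(raw)) raw <- qual("product")
    if (is.na(raw)) raw <- key
    label <- normalizeLabel(raw, synonyms)
    if (is.na(label)) {
      if (grepl("^tRNA-(Leu|Ser)$", raw))
        warning("ambiguous label '", raw,
                "': isoacceptor not disambiguated", call. = FALSE)
      else
        warning("feature name '", raw,
                "' not in synonym table; kept verbatim", call. = FALSE)
      label <- raw
    }
    anticodon <- qual("anticodon")
    feats <- rbind(feats, data.frame(
      label = label, kind = unname(kind_map[key]), strand = loc$strand,
      start = loc$start - 1L, end = loc$end,
      anticodon = if (is.na(anticodon)) NA_character_ else anticodon,
      stringsAsFactors = FALSE))
  }
  id <- sub("^LOCUS\\s+(\\S+).*$", "\\1", lines[grep("^LOCUS", lines)])
  MitoGenome(id, seq, feats)
}
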