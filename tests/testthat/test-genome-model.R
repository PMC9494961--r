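# container, coordinate conventions, readers/writers

test_that("feature TSV coordinates convert 1-based inclusive to 0-based half-open", {
  tsv <- tempfile(fileext = ".tsv")
  fa <- tempfile(fileext = ".fa")
  L <- 19720L
  seq <- randomDna(L, seed = 11)
  writeLines(c(">fixt", seq), fa)
  write.table(
    data.frame(label = c("CYTB", "CR1"), kind = c("PCG", "CR"),
               strand = "H", start = c(1L, 19000L), end = c(1141L, 500L)),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- readFeatureTable(tsv, fa)
  ft <- featureTable(g)
  cytb <- ft[ft$label == "CYTB", ]
  expect_equal(c(cytb$start, cytb$end), c(0L, 1141L))
  wrapped <- ft[ft$label == "CR1", ]
  expect_lt(wrapped$end, wrapped$start)
  # hand count: (19720 - 18999) + 500 = 1221 bases for file span 19000..500
  expect_equal(nchar(extractFeatureSequence(g, wrapped)),
               (L - 19000L + 1L) + 500L)
})

test_that("an empty feature table yields a valid featureless genome", {
  tsv <- tempfile(fileext = ".tsv")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGTACGT"), fa)
  write.table(
    data.frame(label = character(), kind = character(),
               strand = character(), start = integer(), end = integer()),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- readFeatureTable(tsv, fa)
  expect_s4_class(g, "MitoGenome")
  expect_equal(nrow(featureTable(g)), 0L)
})

test_that("unknown labels, kinds, strands and out-of-range spans are rejected by row", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGTACGTAC"), fa)
  mk <- function(df) {
    tsv <- tempfile(fileext = ".tsv")
    write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    tsv
  }
  expect_error(readFeatureTable(mk(data.frame(
    label = "BOGUS", kind = "PCG", strand = "H", start = 1, end = 4)),
    fa), "unknown label")
  expect_error(readFeatureTable(mk(data.frame(
    label = "ND1", kind = "gene", strand = "H", start = 1, end = 4)),
    fa), "unknown kind")
  expect_error(readFeatureTable(mk(data.frame(
    label = "ND1", kind = "PCG", strand = "+", start = 1, end = 4)),
    fa), "unknown strand")
  expect_error(readFeatureTable(mk(data.frame(
    label = "ND1", kind = "PCG", strand = "H", start = 1, end = 99)),
    fa), "outside sequence")
})

test_that("feature table write/read round trip is field-for-field exact", {
  g <- impresusJunctionGenome(seed = 5)
  tsv <- tempfile(fileext = ".tsv")
  fa <- tempfile(fileext = ".fa")
  writeFeatureTable(g, tsv, fa)
  g2 <- readFeatureTable(tsv, fa, id = genomeID(g))
  expect_identical(featureTable(g2), featureTable(g))
  expect_identical(as.character(genomeSeq(g2)), as.character(genomeSeq(g)))
})

test_that("extractFeatureSequence honours strand and origin wrap", {
  g <- MitoGenome("t", "ATGCCTTT", data.frame(
    label = c("F", "V", "P"), kind = "tRNA",
    strand = c("H", "L", "H"),
    start = c(0L, 0L, 6L), end = c(4L, 4L, 2L)))
  expect_identical(extractFeatureSequence(g, featureTable(g)[1, ]), "ATGC")
  expect_identical(extractFeatureSequence(g, featureTable(g)[2, ]), "GCAT")
  # wrapped span [6, 2): suffix "TT" + prefix "AT", length (8-6)+2
  wrapped <- featureTable(g)[featureTable(g)$label == "P", ]
  expect_identical(extractFeatureSequence(g, wrapped), "TTAT")
  expect_equal(nchar(extractFeatureSequence(g, wrapped)), (8 - 6) + 2)
})

test_that("rotation preserves features, distances and junction totals", {
  g <- impresusJunctionGenome(seed = 3)
  sig <- function(x) {
    ft <- featureTable(x)
    sort(paste(ft$label, ft$strand,
               spanLen(ft$start, ft$end, genomeLength(x))))
  }
  r <- rotateToAnchor(g, "COI")
  expect_equal(featureTable(r)$start[featureTable(r)$label == "COI"], 0L)
  expect_identical(sig(r), sig(g))
  # rotating back is the identity
  r2 <- rotateToAnchor(r, "12S")
  expect_identical(featureTable(r2), featureTable(g))
  expect_identical(as.character(genomeSeq(r2)), as.character(genomeSeq(g)))
  # junction accounting is rotation-invariant
  expect_identical(junctionScan(r)$totals, junctionScan(g)$totals)
  expect_error(rotateToAnchor(g, "nope"), "matches 0 features")
})

test_that("the GenBank reader maps names, strands and wrapped joins", {
  gb <- system.file("extdata", "synthetic_mitogenome.gb",
                    package = "mitoarch")
  expect_warning(g <- readGenBank(gb), "ambiguous label")
  expect_equal(genomeLength(g), 2000L)
  ft <- featureTable(g)
  # COX1 synonym resolves to the vocabulary label
  expect_true("COI" %in% ft$label)
  # complement() becomes strand L with inclusive span length 70
  q <- ft[ft$label == "Q", ]
  expect_identical(q$strand, "L")
  expect_equal(q$end - q$start, 70L)
  # D-loop maps to the CR kind; rep_origin to OL
  expect_identical(ft$kind[ft$label == "CR"], "CR")
  expect_identical(ft$kind[ft$label == "OL"], "OL")
  # join(1900..2000,1..60) is the single wrapped feature
  nd1 <- ft[ft$label == "ND1", ]
  expect_lt(nd1$end, nd1$start)
  expect_equal(nchar(extractFeatureSequence(g, nd1)), 101L + 60L)
  # the undisambiguated tRNA-Leu is kept verbatim, not silently assigned
  expect_true("tRNA-Leu" %in% ft$label)
})

test_that("the GenBank reader rejects multi-record and sequence-less files", {
  gb <- system.file("extdata", "synthetic_mitogenome.gb",
                    package = "mitoarch")
  lines <- readLines(gb)
  two <- tempfile(fileext = ".gb")
  writeLines(c(lines, lines), two)
  expect_error(readGenBank(two), "exactly one LOCUS")
  noseq <- tempfile(fileext = ".gb")
  writeLines(lines[seq_len(grep("^ORIGIN", lines) - 1L)], noseq)
  expect_error(readGenBank(noseq), "no ORIGIN")
})

test_that("validateGenome flags out-of-range tRNA spans without failing", {
  g <- MitoGenome("t", randomDna(300, seed = 2), data.frame(
    label = c("F", "V"), kind = "tRNA", strand = "H",
    start = c(0L, 100L), end = c(70L, 220L)))  # V is 120 bp
  expect_warning(rep <- validateGenome(g), "tRNA spans")
  expect_true("warn" %in% rep$status)
})
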