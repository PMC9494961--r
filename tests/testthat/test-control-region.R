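# tandem repeats, motif search, paralog identity

# the 38-mer repeat unit shared by the 5' control-region ends of
# Polypedates mitogenomes
REPEAT38 <- "ATTTACCCCATCATACTATGTATAATAAGCATTAATTT"

test_that("exact concatenated copies are found with the exact period and count", {
  seq <- strrep(REPEAT38, 3)
  hits <- findTandemRepeats(seq, max_period = nchar(seq) %/% 2)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$period, 38L)
  expect_equal(hits$copies_rounded, 3L)
  expect_equal(hits$match_fraction, 1)
  expect_equal(hits$consensus, REPEAT38)
  expect_equal(c(hits$start, hits$end), c(1L, nchar(seq)))
})

test_that("mutated planted repeats are recovered above the consensus threshold", {
  for (seed in 1:10) {
    plant <- withr::with_seed(seed, {
      unit <- paste(sample(c("A", "C", "G", "T"), 50, TRUE),
                    collapse = "")
      copies <- vapply(1:4, function(i) {
        v <- strsplit(unit, "")[[1]]
        hit <- runif(50) < 0.02
        v[hit] <- sample(c("A", "C", "G", "T"), sum(hit), TRUE)
        paste(v, collapse = "")
      }, "")
      list(arr = paste(copies, collapse = ""))
    })
    seq <- paste0(randomDna(300, seed + 100), plant$arr,
                  randomDna(300, seed + 200))
    hits <- findTandemRepeats(seq, min_period = 10, max_period = 200)
    expect_gte(nrow(hits), 1L)
    best <- hits[which.max(hits$end - hits$start), ]
    expect_equal(best$period, 50L)
    expect_equal(best$copies_rounded, 4L)
    expect_gt(best$match_fraction, 0.9)
  }
})

test_that("i.i.d. random sequence yields no repeat call", {
  seq <- randomDna(2000, seed = 123)
  hits <- findTandemRepeats(seq, max_period = 1000)
  expect_equal(nrow(hits), 0L)
})

test_that("max_period beyond half the length is clamped with a warning", {
  expect_warning(findTandemRepeats(strrep(REPEAT38, 3), max_period = 5000),
                 "clamped")
})

test_that("repeat excision removes the spans and leaves no further calls", {
  cr <- paste0(strrep(REPEAT38, 3), randomDna(600, seed = 31))
  hits <- findTandemRepeats(cr, max_period = 300)
  masked <- maskRepeats(cr, hits)
  expect_equal(nchar(masked$sequence),
               nchar(cr) - masked$removed_bases)
  expect_equal(masked$removed_bases,
               sum(hits$end - hits$start + 1L))
  rescan <- findTandemRepeats(masked$sequence,
                              max_period = nchar(masked$sequence) %/% 2)
  expect_equal(nrow(rescan), 0L)
  # no repeats -> identity
  none <- maskRepeats(cr, findTandemRepeats(randomDna(50, 1),
                                            max_period = 20))
  expect_identical(none$sequence, cr)
  # arithmetic: one span [100, 479] on a 2000-base region leaves 1620
  fake <- data.frame(start = 100L, end = 479L)
  expect_equal(nchar(maskRepeats(randomDna(2000, 7), fake)$sequence), 1620L)
})

test_that("motif search finds the replication-origin stem motifs", {
  # the conserved stem carries motif 1 at its 5' end
  hits <- findMotifs("CTTCTCCCGT")
  expect_true(any(hits$motif == "OL_motif1" & hits$start == 1L))
  # the GCCAG variant is caught with one mismatch
  hits2 <- findMotifs("AAAGCCAGAAA")
  m2 <- hits2[hits2$motif == "OL_motif2", ]
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$mismatches, 1L)
  # a poly-A sequence has no hits
  expect_equal(nrow(findMotifs(strrep("A", 50))), 0L)
})

test_that("zero-mismatch search equals exact substring search", {
  for (seed in 1:5) {
    s <- randomDna(500, seed)
    pat <- substr(s, 201, 208)
    hits <- findMotifs(s, c(m = pat))
    exact <- gregexpr(pat, s, fixed = TRUE)[[1]]
    exact <- exact[exact > 0]
    # gregexpr misses overlapping matches; every exact hit must be found
    expect_true(all(exact %in% hits$start))
    expect_true(all(vapply(hits$start, function(i)
      substr(s, i, i + 7) == pat, TRUE)))
  }
})

test_that("motif library YAML round-trips and longer-than-sequence motifs miss", {
  lib <- readMotifLibrary(system.file("extdata", "ol_motifs.yaml",
                                      package = "mitoarch"))
  expect_identical(lib$OL_motif1$pattern, "CTTCT")
  expect_equal(lib$OL_motif2$max_mismatches, 1L)
  expect_equal(nrow(findMotifs("ACG", lib)), 0L)
})

test_that("CR identity counts substitutions over gap-free columns only", {
  expect_equal(crPairwiseIdentity("ACGTACGT", "ACGTACGT")$identity, 100)
  # published substitution counts as pre-aligned fixtures
  a <- strrep("A", 1496)
  b <- paste0(strrep("A", 1496 - 133), strrep("G", 133))
  r <- crPairwiseIdentity(a, b, aligned = TRUE)
  expect_equal(round(r$identity, 1), 91.1)
  expect_equal(r$alignable_sites, 1496L)
  a2 <- strrep("A", 1690)
  b2 <- paste0(strrep("A", 1685), strrep("C", 5))
  expect_equal(round(crPairwiseIdentity(a2, b2, aligned = TRUE)$identity, 1),
               99.7)
  # gapped columns are neither matches nor substitutions
  r3 <- crPairwiseIdentity("AC-GT", "ACCGA", aligned = TRUE)
  expect_equal(r3$alignable_sites, 4L)
  expect_equal(r3$substitutions, 1L)
})

test_that("CR identity is symmetric and aligns unaligned input", {
  x <- randomDna(400, seed = 51)
  y <- withr::with_seed(52, mitoarch:::mutateSeq(x, 0.05))
  r1 <- crPairwiseIdentity(x, y)
  r2 <- crPairwiseIdentity(y, x)
  expect_equal(r1$identity, r2$identity)
  expect_gt(r1$identity, 90)
  expect_error(crPairwiseIdentity("", "ACGT"), "empty")
})
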