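# composition, skews, RSCU, codon endpoints

test_that("skews follow the count formula and reproduce published compositions", {
  # printed whole-genome compositions of the two Polypedates mitogenomes
  expect_equal(round(atSkew(30.2, 30.8), 3), -0.010)
  expect_equal(round(atSkew(30.5, 30.4), 3), 0.002)
  expect_equal(round(gcSkew(24.3, 14.7), 3), 0.246)  # formula applied literally
  expect_true(is.na(atSkew(0, 0)))
})

test_that("baseComposition counts, contents and skews are exact on hand cases", {
  b <- baseComposition("ACGT")
  expect_equal(unlist(b[c("A", "C", "G", "T")]),
               c(A = 1L, C = 1L, G = 1L, T = 1L))
  expect_equal(b$at_content, 50)
  expect_equal(b$at_skew, 0)
  expect_equal(b$gc_skew, 0)
  expect_error(baseComposition("NNNN"), "no unambiguous")
  expect_error(baseComposition(""), "empty")
})

test_that("skews are antisymmetric under reverse complement and contents sum to 100", {
  for (seed in 1:5) {
    s <- randomDna(400, seed)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    a <- baseComposition(s); b <- baseComposition(rc)
    expect_equal(a$at_skew, -b$at_skew)
    expect_equal(a$gc_skew, -b$gc_skew)
    expect_equal(a$at_content + a$gc_content, 100)
  }
})

test_that("region report covers genome, PCGs, codon positions, RNAs and CRs", {
  g <- toyCodingGenome()   # three copies of ATG AAA TAA on the H strand
  rep <- regionCompositionReport(g)
  # codon positions computable by hand: pos1 = A,A,T per gene
  p1 <- rep[rep$region == "codon1", ]
  expect_equal(c(p1$A, p1$T, p1$G), c(6L, 3L, 0L))
  p3 <- rep[rep$region == "codon3", ]
  expect_equal(c(p3$G, p3$A), c(3L, 6L))
  # codon position rows partition the pooled PCG bases
  pcg <- rep[rep$region == "PCGs", ]
  pos_total <- sum(rep[rep$region %in% c("codon1", "codon2", "codon3"),
                       c("A", "C", "G", "T")])
  expect_equal(pos_total, sum(pcg[, c("A", "C", "G", "T")]))
  # no CRs annotated: both CR rows absent
  expect_false(any(rep$present[rep$region %in% c("CR1", "CR2")]))
})

test_that("a single-CR genome reports CR2 as absent", {
  gg <- generateGenome(syntheticSpec(template = "LTPF-single-CR",
                                     ncr_pathway = "direct-mutation"),
                       seed = 8)
  rep <- regionCompositionReport(gg$genome)
  expect_true(rep$present[rep$region == "CR1"])
  expect_false(rep$present[rep$region == "CR2"])
})

test_that("RSCU satisfies its defining identities on hand-built families", {
  # uniform six-codon leucine family -> RSCU 1 for each member
  leu <- c("CTA", "CTC", "CTG", "CTT", "TTA", "TTG")
  cds <- paste0("ATG", paste(leu, collapse = ""), "TAA")
  g <- MitoGenome("leu", cds, data.frame(
    label = "ND1", kind = "PCG", strand = "H",
    start = 0L, end = nchar(cds)))
  cu <- codonUsage(g)
  expect_equal(cu$codons$rscu[cu$codons$codon %in% leu], rep(1, 6))

  # serine family counts 10/2/2/2/2/2 -> RSCU(TCA) = 10/(20/6) = 3
  ser <- c(rep("TCA", 10), rep(c("TCC", "TCT", "TCG", "AGT", "AGC"), 2))
  cds2 <- paste0("ATG", paste(ser, collapse = ""), "TAA")
  g2 <- MitoGenome("ser", cds2, data.frame(
    label = "ND1", kind = "PCG", strand = "H",
    start = 0L, end = nchar(cds2)))
  cu2 <- codonUsage(g2)
  expect_equal(cu2$codons$rscu[cu2$codons$codon == "TCA"], 3)
  # within each family with nonzero total, RSCU sums to the family size
  tab <- cu2$codons[!is.na(cu2$codons$rscu), ]
  sums <- tapply(tab$rscu, tab$aa, sum)
  sizes <- tapply(tab$family_size, tab$aa, unique)
  expect_equal(as.numeric(sums), as.numeric(sizes))
})

test_that("stop codons are counted but carry no RSCU; Met/Lys hand case", {
  g <- MitoGenome("mk", "ATGAAATAA", data.frame(
    label = "ND1", kind = "PCG", strand = "H", start = 0L, end = 9L))
  cu <- codonUsage(g)
  expect_equal(cu$codons$count[cu$codons$codon == "ATG"], 1L)
  expect_equal(cu$codons$count[cu$codons$codon == "AAA"], 1L)
  expect_equal(cu$codons$count[cu$codons$codon == "TAA"], 1L)
  expect_true(is.na(cu$codons$rscu[cu$codons$codon == "TAA"]))
  expect_equal(cu$total, 3L)
  # AGA/AGG are stops, not arginine, under the vertebrate mito code
  expect_identical(cu$codons$aa[cu$codons$codon == "AGA"], "*")
})

test_that("an internal stop raises a warning but the codon is still counted", {
  g <- MitoGenome("is", "ATGTAAAAATAA", data.frame(
    label = "ND1", kind = "PCG", strand = "H", start = 0L, end = 12L))
  expect_warning(cu <- codonUsage(g), "internal stop")
  expect_equal(cu$codons$count[cu$codons$codon == "TAA"], 2L)
})

test_that("codon endpoints report complete, truncated and non-ATN cases", {
  mk <- function(cds) MitoGenome("e", cds, data.frame(
    label = "ND1", kind = "PCG", strand = "H",
    start = 0L, end = nchar(cds)))
  # complete AGG stop (vertebrate mitochondrial)
  r <- startStopCodons(mk("ATGAAAAGG"))
  expect_identical(r$stop_codon, "AGG")
  expect_false(r$truncated)
  # length 3n+1 ending T -> "T--"
  r <- startStopCodons(mk("ATGAAAT"))
  expect_identical(r$stop_codon, "T--")
  expect_true(r$truncated)
  # length 3n+2 ending TA -> "TA-"
  r <- startStopCodons(mk("ATGAAATA"))
  expect_identical(r$stop_codon, "TA-")
  # GTG start is recorded verbatim and flagged non-ATN
  r <- startStopCodons(mk("GTGAAATAA"))
  expect_identical(r$start_codon, "GTG")
  expect_false(r$start_ATN)
  expect_match(r$flag, "non-ATN")
  # non-conforming truncated tail flagged
  r <- startStopCodons(mk("ATGAAAG"))
  expect_match(r$flag, "non-conforming")
  expect_error(startStopCodons(mk("ATGA")), "shorter than 6")
})

test_that("pcgFraction reproduces the published percentages from the printed totals", {
  mk <- function(pcg_total, L, seed) {
    MitoGenome("f", randomDna(L, seed), data.frame(
      label = "ND5", kind = "PCG", strand = "H",
      start = 0L, end = pcg_total))
  }
  expect_equal(pcgFraction(mk(11124L, 19720L, 21)), 56.41)
  expect_equal(pcgFraction(mk(11118L, 20056L, 22)), 55.43)
  expect_equal(pcgFraction(MitoGenome("none", "ACGT")), 0)
})
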