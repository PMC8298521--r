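test_that("codon-change classification reproduces the known lesions", {
  expect_equal(classify_codon_change("CAG", "TAG")$effect, "stop_gained")
  expect_equal(classify_codon_change("CAG", "TAA")$effect, "stop_gained")
  expect_equal(classify_codon_change("CAG", "CAA")$effect, "synonymous")
  expect_equal(classify_codon_change("AGT", "TCA")$effect, "synonymous")
  cc <- classify_codon_change("CAG", "TAA")
  expect_equal(cc$aa_ref, "Q")
  expect_equal(cc$aa_alt, "*")
  expect_error(classify_codon_change("CAN", "CAA"), "invalid codon")
  expect_error(classify_codon_change("CA", "CAA"), "invalid codon")
})

test_that("codon-change classification equals the exhaustive translate-and-compare oracle", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  aa <- vapply(codons, function(cd) as.character(Biostrings::translate(
    Biostrings::DNAString(cd), no.init.codon = TRUE)), "")
  for (ref in codons) {
    got <- vapply(codons, function(alt)
      classify_codon_change(ref, alt)$effect, "")
    expected <- ifelse(aa[ref] == aa, "synonymous",
                       ifelse(aa == "*", "stop_gained",
                              ifelse(aa[ref] == "*", "stop_lost", "missense")))
    expect_identical(got, expected)
  }
})

test_that("a C>T at the first base of a CAG codon 598 gives Q598X", {
  fx <- make_gene_fixture()
  v <- classify_variant(fx$genome, list(fx$gene), fx$chrom, fx$q598_pos,
                        "C", "T")
  expect_equal(v$effect, "stop_gained")
  expect_equal(v$protein_change, "Q598X")
  expect_equal(v$gene_id, "geneT")
})

test_that("positions map to splice, intron, UTR and intergenic classes", {
  fx <- make_gene_fixture()
  # intron positions +1/+2 from the donor are splice sites, deeper is intronic
  don <- classify_variant(fx$genome, list(fx$gene), fx$chrom,
                          fx$exon1_end + 1, "G", "A")
  expect_equal(don$effect, "splice_site")
  acc <- classify_variant(fx$genome, list(fx$gene), fx$chrom,
                          fx$exon2_start - 1, "G", "C")
  expect_equal(acc$effect, "splice_site")
  base3 <- bulkmapr::genome_base(fx$genome, fx$chrom, fx$exon1_end + 3)
  deep <- classify_variant(fx$genome, list(fx$gene), fx$chrom,
                           fx$exon1_end + 3, base3,
                           setdiff(c("A", "C", "G", "T"), base3)[1])
  expect_equal(deep$effect, "intronic")
  expect_true(is.na(deep$protein_change))

  # far from the gene: intergenic, no gene, no protein change
  far <- fx$exon1_start - 1000
  bf <- bulkmapr::genome_base(fx$genome, fx$chrom, far)
  ig <- classify_variant(fx$genome, list(fx$gene), fx$chrom, far, bf,
                         setdiff(c("A", "C", "G", "T"), bf)[1])
  expect_equal(ig$effect, "intergenic")
  expect_true(is.na(ig$gene_id))

  # transcript bounds beyond the CDS mark UTRs
  g_utr <- gene_model("geneT", fx$chrom, "+", fx$gene$cds_exons,
                      tx_start = fx$exon1_start - 100,
                      tx_end = fx$exon2_end + 100)
  pu <- fx$exon1_start - 50
  bu <- bulkmapr::genome_base(fx$genome, fx$chrom, pu)
  utr <- classify_variant(fx$genome, list(g_utr), fx$chrom, pu, bu,
                          setdiff(c("A", "C", "G", "T"), bu)[1])
  expect_equal(utr$effect, "utr")
})

test_that("reference mismatches and N bases are rejected with coordinates", {
  fx <- make_gene_fixture()
  wrong <- setdiff(c("A", "C", "G", "T"),
                   bulkmapr::genome_base(fx$genome, fx$chrom, 100))
  expect_error(classify_variant(fx$genome, list(fx$gene), fx$chrom, 100,
                                wrong[1], wrong[2]),
               "reference mismatch.*100")
  seqN <- fx$seq
  substr(seqN, 100, 100) <- "N"
  genN <- toy_genome(fx$chrom, nchar(seqN),
                     stats::setNames(seqN, fx$chrom))
  expect_error(classify_variant(genN, list(fx$gene), fx$chrom, 100, "A", "G"),
               "N reference base")
})

test_that("random coding SNVs agree with the full-translation oracle", {
  fx <- make_gene_fixture()
  set.seed(41)
  ex <- fx$gene$cds_exons
  cds_positions <- c(seq(ex$start[1], ex$end[1]), seq(ex$start[2], ex$end[2]))
  for (i in 1:200) {
    pos <- sample(cds_positions, 1)
    ref <- bulkmapr::genome_base(fx$genome, fx$chrom, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- classify_variant(fx$genome, list(fx$gene), fx$chrom, pos, ref, alt)
    want <- oracle_classify_coding(fx, pos, alt)
    expect_equal(got$effect, want$effect,
                 info = sprintf("pos=%d %s>%s", pos, ref, alt))
    if (want$effect != "synonymous")
      expect_equal(got$protein_change, want$protein_change)
  }
})

test_that("a minus-strand gene classifies like its mirrored plus-strand twin", {
  fx <- make_gene_fixture()
  mir <- mirror_fixture(fx)
  set.seed(42)
  ex <- fx$gene$cds_exons
  pool <- c(seq(ex$start[1], ex$end[1]), seq(ex$start[2], ex$end[2]),
            seq(ex$end[1] + 1, ex$start[2] - 1))
  comp <- function(b) chartr("ACGT", "TGCA", b)
  for (i in 1:60) {
    pos <- sample(pool, 1)
    ref <- bulkmapr::genome_base(fx$genome, fx$chrom, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    plus <- classify_variant(fx$genome, list(fx$gene), fx$chrom, pos, ref, alt)
    minus <- classify_variant(mir$genome, list(mir$gene), fx$chrom,
                              mir$L - pos + 1, comp(ref), comp(alt))
    expect_equal(minus$effect, plus$effect)
    expect_equal(minus$protein_change, plus$protein_change)
  }
})

test_that("the candidate filter keeps missense and stop_gained inside the interval", {
  iv <- genomic_interval("chr2", 1e6, 2e6)
  v <- data.frame(
    chrom = "chr2",
    pos_bp = c(1.1e6, 1.2e6, 1.3e6, 1.4e6, 1.5e6),
    ref = "C", alt = "T",
    gene_id = c("g1", "g1", "g1", "g1", NA),
    effect = c("synonymous", "missense", "stop_gained", "intronic",
               "intergenic"),
    protein_change = c("A2A", "A3V", "Q598X", NA, NA),
    stringsAsFactors = FALSE)
  kept <- filter_candidates(v, iv)
  expect_equal(nrow(kept), 2)
  expect_setequal(kept$effect, c("missense", "stop_gained"))

  # a stop_gained outside the interval is dropped
  v2 <- v
  v2$pos_bp[3] <- 3e6
  expect_equal(filter_candidates(v2, iv)$effect, "missense")

  # subset of input; idempotent; optional splice retention
  expect_identical(filter_candidates(kept, iv), kept)
  expect_true(all(kept$pos_bp %in% v$pos_bp))
  v3 <- v
  v3$effect[4] <- "splice_site"
  expect_equal(nrow(filter_candidates(v3, iv, include_splice = TRUE)), 3)

  # ranked report puts stop_gained first
  rep_lines <- candidate_report(kept)
  expect_match(rep_lines[1], "stop_gained")
  expect_equal(candidate_report(kept[0, ]),
               "no candidates: no retained variant inside the mapped interval")
})
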