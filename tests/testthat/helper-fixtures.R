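# Shared fixture builders. Everything is generated in code at test time.

# Small genome carrying one two-exon gene whose codon 598 is CAG (Gln); the
# C>T change at its first base is the canonical premature-stop lesion.
make_gene_fixture <- function(seed = 42, chrom_length = 10000,
                              exon1_start = 3000) {
  set.seed(seed)
  chrom <- "chrT"
  seq <- paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
               collapse = "")
  codons <- rep("GCT", 600)
  codons[1] <- "ATG"; codons[598] <- "CAG"; codons[600] <- "TAA"
  cds <- paste(codons, collapse = "")
  exon1_len <- 300; intron_len <- 200
  exon1_end <- exon1_start + exon1_len - 1
  exon2_start <- exon1_end + intron_len + 1
  exon2_end <- exon2_start + nchar(cds) - exon1_len - 1
  substr(seq, exon1_start, exon1_end) <- substr(cds, 1, exon1_len)
  substr(seq, exon2_start, exon2_end) <- substr(cds, exon1_len + 1, nchar(cds))
  substr(seq, exon1_end + 1, exon1_end + 2) <- "GT"
  substr(seq, exon2_start - 2, exon2_start - 1) <- "AG"
  genome <- bulkmapr::toy_genome(chrom, chrom_length,
                                 stats::setNames(seq, chrom))
  gene <- bulkmapr::gene_model("geneT", chrom, "+",
                               data.frame(start = c(exon1_start, exon2_start),
                                          end = c(exon1_end, exon2_end)))
  # genomic position of the first base of codon 598 (offset 1792, in exon 2)
  q598_pos <- exon2_start + (3 * 597 + 1 - exon1_len) - 1
  list(genome = genome, gene = gene, chrom = chrom, seq = seq,
       exon1_start = exon1_start, exon1_end = exon1_end,
       exon2_start = exon2_start, exon2_end = exon2_end,
       q598_pos = q598_pos)
}

# Mirror a plus-strand fixture onto the reverse-complemented chromosome:
# the same gene read from the other strand, coordinates flipped.
mirror_fixture <- function(fx) {
  L <- bulkmapr::chrom_length(fx$genome, fx$chrom)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fx$seq)))
  genome <- bulkmapr::toy_genome(fx$chrom, L, stats::setNames(rc, fx$chrom))
  ex <- fx$gene$cds_exons
  mirrored <- data.frame(start = L - ex$end + 1, end = L - ex$start + 1)
  gene <- bulkmapr::gene_model(fx$gene$gene_id, fx$chrom, "-", mirrored)
  list(genome = genome, gene = gene, L = L)
}

# Full-translation oracle for coding SNVs: rebuild the mutant chromosome,
# splice and translate both CDSs with Biostrings, and diff the proteins.
oracle_classify_coding <- function(fx, pos, alt) {
  mut <- fx$seq
  substr(mut, pos, pos) <- alt
  splice <- function(s) {
    ex <- fx$gene$cds_exons
    paste(substring(s, ex$start, ex$end), collapse = "")
  }
  prot <- function(s) strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(splice(s)), no.init.codon = TRUE)), "")[[1]]
  p_ref <- prot(fx$seq); p_alt <- prot(mut)
  d <- which(p_ref != p_alt)
  if (length(d) == 0L) return(list(effect = "synonymous"))
  i <- d[1L]
  eff <- if (p_alt[i] == "*") "stop_gained"
         else if (p_ref[i] == "*") "stop_lost"
         else if (i == 1L) "start_lost"
         else "missense"
  chg <- paste0(ifelse(p_ref[i] == "*", "X", p_ref[i]), i,
                ifelse(p_alt[i] == "*", "X", p_alt[i]))
  list(effect = eff, protein_change = chg)
}

# Small single-chromosome cross setup for simulator tests.
small_cross_config <- function(seed, chrom_length = 1e6, n_markers = 20,
                               genetic_length = 50, causal_frac = 0.5, ...) {
  genome <- bulkmapr::toy_genome("chr1", chrom_length)
  markers <- bulkmapr::even_marker_map(genome, n_markers, genetic_length)
  bulkmapr::cross_config(genome, markers, "chr1",
                         round(chrom_length * causal_frac),
                         seed = seed, ...)
}
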