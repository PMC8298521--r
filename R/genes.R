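#' Construct a gene model
#'
#' A single-isoform protein-coding gene: an ordered set of non-overlapping
#' CDS exons on one strand. The coding sequence is the concatenation of the
#' exons in transcription order (reverse-complemented for minus-strand
#' genes); its total length must be divisible by 3. Optional transcript
#' bounds wider than the CDS span mark untranslated regions.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds_exons Data frame with columns `start`, `end` (1-based
#'   inclusive), non-overlapping.
#' @param tx_start,tx_end Optional transcript bounds (default: CDS span).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, cds_exons,
                       tx_start = NULL, tx_end = NULL) {
  stopifnot(strand %in% c("+", "-"))
  ex <- data.frame(start = as.numeric(cds_exons$start),
                   end = as.numeric(cds_exons$end))
  if (nrow(ex) == 0L) stop("gene needs at least one CDS exon")
  if (any(ex$start > ex$end)) stop("exon start > end in ", gene_id)
  ex <- ex[order(ex$start), , drop = FALSE]
  rownames(ex) <- NULL
  if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
    stop("overlapping CDS exons in ", gene_id)
  cds_len <- sum(ex$end - ex$start + 1)
  if (cds_len %% 3 != 0)
    stop("CDS length of ", gene_id, " (", cds_len, ") not divisible by 3")
  if (is.null(tx_start)) tx_start <- min(ex$start)
  if (is.null(tx_end)) tx_end <- max(ex$end)
  if (tx_start > min(ex$start) || tx_end < max(ex$end))
    stop("transcript bounds must contain the CDS span")
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 strand = strand, cds_exons = ex,
                 tx_start = as.numeric(tx_start), tx_end = as.numeric(tx_end)),
            class = "gene_model")
}

#' Read gene models from GFF3
#'
#' CDS features are grouped into genes by their `Parent` attribute (falling
#' back to `ID`); `gene` features, when present, supply transcript bounds.
#'
#' @param path GFF3 file path.
#' @return Named list of `gene_model`s.
#' @export
load_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_cds <- as.character(md$type) == "CDS"
  if (!any(is_cds)) stop("no CDS features in ", path)
  parent <- if ("Parent" %in% names(md))
    vapply(md$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
  else rep(NA_character_, length(gr))
  ids <- ifelse(is.na(parent) | parent == "", as.character(md$ID), parent)
  cds <- data.frame(gene_id = ids[is_cds],
                    chrom = as.character(GenomicRanges::seqnames(gr)[is_cds]),
                    strand = as.character(GenomicRanges::strand(gr)[is_cds]),
                    start = GenomicRanges::start(gr)[is_cds],
                    end = GenomicRanges::end(gr)[is_cds],
                    stringsAsFactors = FALSE)
  is_gene <- as.character(md$type) == "gene"
  spans <- if (any(is_gene))
    data.frame(gene_id = as.character(md$ID)[is_gene],
               start = GenomicRanges::start(gr)[is_gene],
               end = GenomicRanges::end(gr)[is_gene],
               stringsAsFactors = FALSE)
  else NULL
  genes <- lapply(split(cds, cds$gene_id), function(g) {
    ts <- te <- NULL
    if (!is.null(spans) && g$gene_id[1L] %in% spans$gene_id) {
      sp <- spans[spans$gene_id == g$gene_id[1L], ]
      ts <- sp$start[1L]; te <- sp$end[1L]
    }
    gene_model(g$gene_id[1L], g$chrom[1L], g$strand[1L],
               g[, c("start", "end")], ts, te)
  })
  genes[order(names(genes))]
}

#' Write gene models to GFF3
#'
#' Emits one `gene` feature (transcript bounds) plus its `CDS` features,
#' with `Parent` linking CDS to gene.
#'
#' @param genes List of `gene_model`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  rows <- lapply(genes, function(g) {
    n_ex <- nrow(g$cds_exons)
    lens <- g$cds_exons$end - g$cds_exons$start + 1
    # phase: bases to skip to the next codon boundary, in transcription order
    tx_order <- if (g$strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    before <- cumsum(c(0, lens[tx_order]))[seq_len(n_ex)]
    phase <- integer(n_ex)
    phase[tx_order] <- (3 - before %% 3) %% 3
    data.frame(chrom = g$chrom,
               start = c(g$tx_start, g$cds_exons$start),
               end = c(g$tx_end, g$cds_exons$end),
               strand = g$strand,
               type = c("gene", rep("CDS", n_ex)),
               ID = c(g$gene_id, sprintf("%s.cds%d", g$gene_id,
                                         seq_len(n_ex))),
               Parent = c(NA_character_, rep(g$gene_id, n_ex)),
               phase = c(NA_integer_, phase),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- S4Vectors::List(
    lapply(df$Parent, function(p) if (is.na(p)) character(0) else p))
  S4Vectors::mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Spliced coding sequence of a gene
#'
#' Concatenates the CDS exons and reverse-complements for minus-strand
#' genes, yielding the coding sequence in transcription order.
#'
#' @param gene A `gene_model`.
#' @param genome A `toy_genome` with sequences.
#' @return Character string of the CDS.
#' @export
cds_sequence <- function(gene, genome) {
  stopifnot(inherits(gene, "gene_model"), inherits(genome, "toy_genome"))
  if (is.null(genome$seq)) stop("genome carries no sequences")
  seq <- genome$seq[[gene$chrom]]
  parts <- mapply(function(s, e)
    as.character(Biostrings::subseq(seq, s, e)),
    gene$cds_exons$start, gene$cds_exons$end)
  cds <- paste(parts, collapse = "")
  if (gene$strand == "-")
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  cds
}

# 1-based offset of a genomic position within the spliced CDS (transcription
# order), or NA when the position is not in a CDS exon.
cds_offset <- function(gene, pos) {
  ex <- gene$cds_exons
  hit <- which(pos >= ex$start & pos <= ex$end)
  if (length(hit) == 0L) return(NA_real_)
  lens <- ex$end - ex$start + 1
  if (gene$strand == "+") {
    before <- if (hit > 1L) sum(lens[seq_len(hit - 1L)]) else 0
    before + (pos - ex$start[hit]) + 1
  } else {
    after <- if (hit < nrow(ex)) sum(lens[(hit + 1L):nrow(ex)]) else 0
    after + (ex$end[hit] - pos) + 1
  }
}
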