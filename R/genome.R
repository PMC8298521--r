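#' Construct a toy genome
#'
#' A toy genome is the physical coordinate frame for the whole pipeline: a
#' set of named chromosomes with declared lengths and, optionally, their
#' sequences. Sequences are only needed by the variant-effect stage and the
#' restriction utilities; mapping simulations work from lengths alone.
#'
#' All coordinates in the package are 1-based and inclusive of both
#' endpoints (sliding windows in [window_means()] are the one documented
#' exception).
#'
#' @param names Character vector of unique chromosome names.
#' @param lengths Integer vector of chromosome lengths in bp (all > 0).
#' @param sequences Optional named character vector or
#'   [Biostrings::DNAStringSet] over the alphabet A/C/G/T/N, one per
#'   chromosome, each of the declared length.
#' @return An object of class `toy_genome`.
#' @examples
#' gen <- toy_genome("chr1", 1e6)
#' chrom_length(gen, "chr1")
#' @export
toy_genome <- function(names, lengths, sequences = NULL) {
  names <- as.character(names)
  lengths <- as.numeric(lengths)
  if (length(names) == 0L) stop("a genome needs at least one chromosome")
  if (length(names) != length(lengths))
    stop("'names' and 'lengths' must have equal length")
  if (anyDuplicated(names))
    stop("duplicate chromosome name: ", names[duplicated(names)][1L])
  if (any(!is.finite(lengths) | lengths < 1 | lengths != round(lengths)))
    stop("chromosome lengths must be positive integers")
  seqs <- NULL
  if (!is.null(sequences)) {
    seqs <- Biostrings::DNAStringSet(sequences)
    if (is.null(names(seqs)) && length(seqs) == length(names))
      names(seqs) <- names
    if (!setequal(names(seqs), names))
      stop("sequence names must match chromosome names")
    seqs <- seqs[names]
    bad <- which(Biostrings::width(seqs) != lengths)
    if (length(bad))
      stop("sequence length disagrees with declared length for ", names[bad[1L]])
    .check_alphabet(seqs)
  }
  structure(
    list(chroms = data.frame(name = names, length = lengths,
                             stringsAsFactors = FALSE),
         seq = seqs),
    class = "toy_genome")
}

.check_alphabet <- function(seqs) {
  freq <- Biostrings::alphabetFrequency(seqs)
  ok <- c("A", "C", "G", "T", "N")
  extra <- rowSums(freq[, !(colnames(freq) %in% ok), drop = FALSE])
  if (any(extra > 0))
    stop("non-ACGTN characters in record '", names(seqs)[which(extra > 0)[1L]], "'")
  invisible(TRUE)
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf("toy_genome: %d chromosome(s), %s bp total%s\n",
              nrow(x$chroms), format(sum(x$chroms$length), big.mark = ","),
              if (is.null(x$seq)) " (lengths only)" else ""))
  print(x$chroms, row.names = FALSE)
  invisible(x)
}

#' Chromosome lengths of a toy genome
#'
#' @param genome A `toy_genome`.
#' @param chrom For [chrom_length()], a single chromosome name.
#' @return Named numeric vector of lengths, or a single length.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "toy_genome"))
  stats::setNames(genome$chroms$length, genome$chroms$name)
}

#' @rdname chrom_lengths
#' @export
chrom_length <- function(genome, chrom) {
  len <- chrom_lengths(genome)
  if (!chrom %in% names(len)) stop("unknown chromosome: ", chrom)
  unname(len[chrom])
}

#' Reference base at a genomic position
#'
#' @inheritParams chrom_lengths
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @return Single upper-case character.
#' @export
genome_base <- function(genome, chrom, pos) {
  stopifnot(inherits(genome, "toy_genome"))
  if (is.null(genome$seq)) stop("genome carries no sequences")
  if (pos < 1 || pos > chrom_length(genome, chrom))
    stop("position ", pos, " outside ", chrom)
  as.character(Biostrings::subseq(genome$seq[[chrom]], pos, pos))
}

#' Read a genome from FASTA
#'
#' One chromosome per record, in file order; sequences are uppercased.
#' Record names are taken as the first whitespace-delimited word of the
#' header. Rejects empty files, duplicate record names and non-ACGTN
#' characters, naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return A `toy_genome` with sequences.
#' @export
load_genome <- function(path) {
  # read as raw strings first: the DNA parser silently drops invalid codes
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  names(raw) <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(names(raw)))
    stop("duplicate record name: ", names(raw)[duplicated(names(raw))][1L])
  chars <- toupper(as.character(raw))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad))
    stop("non-ACGTN characters in record '", names(raw)[bad][1L], "'")
  seqs <- Biostrings::DNAStringSet(chars)
  toy_genome(names(seqs), Biostrings::width(seqs), seqs)
}

#' Write a genome to FASTA
#'
#' @inheritParams chrom_lengths
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "toy_genome"))
  if (is.null(genome$seq)) stop("genome carries no sequences to write")
  Biostrings::writeXStringSet(genome$seq, path)
  invisible(path)
}

#' Genomic intervals (1-based, both ends inclusive)
#'
#' @param chrom Chromosome name.
#' @param start,end 1-based endpoints, `start <= end`, both included in the
#'   interval.
#' @return An object of class `genomic_interval`.
#' @examples
#' iv <- genomic_interval("chr2", 6376867, 6381509)
#' interval_width(iv)
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start < 1 || start > end)
    stop("need 1 <= start <= end; got [", start, ", ", end, "]")
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genomic_interval")
}

#' @rdname genomic_interval
#' @param x A `genomic_interval`.
#' @export
interval_width <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  x$end - x$start + 1
}

#' @rdname genomic_interval
#' @param pos Position(s) to test.
#' @export
interval_contains <- function(x, chrom, pos) {
  stopifnot(inherits(x, "genomic_interval"))
  chrom == x$chrom & pos >= x$start & pos <= x$end
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%s kb)\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              kb_label(interval_width(x))))
  invisible(x)
}

#' Write and read intervals as BED
#'
#' BED is 0-based, half-open; conversion to and from the package's 1-based
#' inclusive convention happens on write/read.
#'
#' @param intervals A `genomic_interval` or list of them.
#' @param path File path.
#' @param names Optional feature names.
#' @return `write_bed()` returns `path` invisibly; `read_bed()` a list of
#'   `genomic_interval`s.
#' @export
write_bed <- function(intervals, path, names = NULL) {
  if (inherits(intervals, "genomic_interval")) intervals <- list(intervals)
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(intervals, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(intervals, `[[`, 0, "start"),
      end = vapply(intervals, `[[`, 0, "end")))
  if (!is.null(names)) names(gr) <- names
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  lapply(seq_along(gr), function(i)
    genomic_interval(as.character(GenomicRanges::seqnames(gr)[i]),
                     GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))
}

#' Restriction fragment lengths from cut positions
#'
#' Given sorted cut positions along a linear molecule, returns the lengths
#' of the consecutive pieces including both end pieces. The internal
#' fragment between two adjacent sites has length equal to the difference of
#' their positions, so the fragment released by EcoRI sites at chromosome 2
#' positions 6,376,867 and 6,381,509 is 4,642 bp (ca. 4.64 kb) -- the
#' single-band expectation used to confirm clean gene targeting by Southern
#' blot.
#'
#' @param site_positions Sorted numeric cut positions in `[1, chrom_length]`.
#'   Empty means an uncut molecule.
#' @param chrom_length Molecule length in bp.
#' @return Numeric vector of fragment lengths summing to `chrom_length`.
#' @examples
#' fragment_lengths(c(6376867, 6381509), 10e6)[2]  # 4642
#' @export
fragment_lengths <- function(site_positions, chrom_length) {
  stopifnot(length(chrom_length) == 1L, chrom_length >= 1)
  p <- as.numeric(site_positions)
  if (length(p)) {
    if (is.unsorted(p, strictly = TRUE))
      stop("cut positions must be strictly increasing")
    if (p[1L] < 1 || p[length(p)] > chrom_length)
      stop("cut positions must lie within [1, chrom_length]")
  }
  diff(c(0, p, chrom_length))
}

#' Format a bp length in kb
#'
#' Divides by 1000 and rounds half-up to two decimals, e.g. 4,642 bp is
#' reported as "4.64".
#'
#' @param bp Length in bp.
#' @return Character, two decimals.
#' @export
kb_label <- function(bp) {
  sprintf("%.2f", floor(bp / 10 + 0.5) / 100)
}

#' Find exact motif matches in a sequence
#'
#' All exact, possibly overlapping occurrences, in ascending order. A motif
#' longer than the sequence yields an empty result, not an error.
#'
#' @param sequence Base string (character or [Biostrings::DNAString]).
#' @param motif Non-empty base string, e.g. `"GAATTC"` for EcoRI.
#' @return Integer vector of 1-based match start positions.
#' @export
find_sites <- function(sequence, motif) {
  motif <- as.character(motif)
  if (nchar(motif) == 0L) stop("motif must be non-empty")
  if (!inherits(sequence, "DNAString"))
    sequence <- Biostrings::DNAString(as.character(sequence))
  if (nchar(motif) > length(sequence)) return(integer(0))
  Biostrings::start(Biostrings::matchPattern(motif, sequence))
}
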