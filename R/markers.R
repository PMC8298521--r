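#' Construct a marker map
#'
#' Ordered biallelic SNP markers with the two parental alleles (Gd =
#' mutagenised parent, Vx = divergent wild-type parent), physical position
#' in bp and genetic position in cM. The constructor sorts by
#' `(chrom, pos_bp)` and then enforces the map invariants: distinct parental
#' alleles at every marker and non-decreasing cM within a chromosome.
#'
#' @param chrom,pos_bp,pos_cM,id,gd_allele,vx_allele Equal-length vectors,
#'   or pass a data frame with these columns as the single first argument.
#' @return A data frame of class `marker_map` with columns
#'   `chrom, pos_bp, pos_cM, id, gd_allele, vx_allele`.
#' @export
marker_map <- function(chrom, pos_bp = NULL, pos_cM = NULL, id = NULL,
                       gd_allele = NULL, vx_allele = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    need <- c("chrom", "pos_bp", "pos_cM", "id", "gd_allele", "vx_allele")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing marker columns: ", paste(miss, collapse = ", "))
    df <- df[need]
  } else {
    df <- data.frame(chrom = as.character(chrom), pos_bp = as.numeric(pos_bp),
                     pos_cM = as.numeric(pos_cM), id = as.character(id),
                     gd_allele = toupper(gd_allele),
                     vx_allele = toupper(vx_allele),
                     stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L) stop("marker map must contain at least one marker")
  df <- df[order(df$chrom, df$pos_bp), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df$id)) stop("duplicate marker id: ",
                                 df$id[duplicated(df$id)][1L])
  if (any(df$gd_allele == df$vx_allele))
    stop("gd_allele equals vx_allele at marker ",
         df$id[df$gd_allele == df$vx_allele][1L])
  for (ch in unique(df$chrom)) {
    cm <- df$pos_cM[df$chrom == ch]
    if (is.unsorted(cm))
      stop("pos_cM must be non-decreasing within ", ch)
  }
  class(df) <- c("marker_map", "data.frame")
  df
}

#' Read/write a marker map as TSV
#'
#' Tab-separated with header columns
#' `chrom, pos_bp, pos_cM, id, gd_allele, vx_allele`.
#'
#' @param path File path.
#' @param markers A `marker_map`.
#' @return `read_marker_map()` returns a `marker_map`; `write_marker_map()`
#'   returns `path` invisibly.
#' @export
read_marker_map <- function(path) {
  marker_map(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_marker_map
#' @export
write_marker_map <- function(markers, path) {
  utils::write.table(as.data.frame(markers), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Evenly spaced synthetic marker panel
#'
#' Convenience builder for simulations: `n` markers per chromosome, evenly
#' spaced in bp, with cM linear in bp from 0 to the chromosome's genetic
#' length (i.e. uniform recombination rate). Alleles default to Gd = A,
#' Vx = G at every marker; only allele identity, not composition, matters to
#' the mapping statistics.
#'
#' @param genome A `toy_genome`.
#' @param n_markers Markers per chromosome (recycled).
#' @param genetic_length_cM Genetic length per chromosome in cM (recycled).
#' @return A `marker_map`.
#' @export
even_marker_map <- function(genome, n_markers, genetic_length_cM) {
  stopifnot(inherits(genome, "toy_genome"))
  nc <- nrow(genome$chroms)
  n_markers <- rep_len(n_markers, nc)
  genetic_length_cM <- rep_len(genetic_length_cM, nc)
  parts <- lapply(seq_len(nc), function(i) {
    name <- genome$chroms$name[i]
    len <- genome$chroms$length[i]
    n <- n_markers[i]
    pos <- round(seq(len / (n + 1), len * n / (n + 1), length.out = n))
    data.frame(chrom = name, pos_bp = pos,
               pos_cM = genetic_length_cM[i] * pos / len,
               id = sprintf("%s_m%04d", name, seq_len(n)),
               gd_allele = "A", vx_allele = "G", stringsAsFactors = FALSE)
  })
  marker_map(do.call(rbind, parts))
}

# cM -> bp by piecewise-linear interpolation through the chromosome's
# marker (pos_cM, pos_bp) pairs; constant extrapolation beyond terminal
# markers (approx rule = 2).
cm_to_bp <- function(markers, chrom, cM) {
  m <- markers[markers$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0L) stop("no markers on ", chrom)
  if (nrow(m) == 1L) return(rep(m$pos_bp, length(cM)))
  stats::approx(m$pos_cM, m$pos_bp, xout = cM, rule = 2,
                ties = "ordered")$y
}

bp_to_cm <- function(markers, chrom, bp) {
  m <- markers[markers$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0L) stop("no markers on ", chrom)
  if (nrow(m) == 1L) return(rep(m$pos_cM, length(bp)))
  stats::approx(m$pos_bp, m$pos_cM, xout = bp, rule = 2,
                ties = "ordered")$y
}

# Genetic length used for meiosis on a chromosome: the cM span of its
# markers (0 when the chromosome carries no or a single marker).
chrom_genetic_length <- function(markers, chrom) {
  cm <- markers$pos_cM[markers$chrom == chrom]
  if (length(cm) < 2L) return(0)
  max(cm) - min(cm)
}
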