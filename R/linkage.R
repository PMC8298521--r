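#' Haldane map function
#'
#' Converts between the recombination fraction r and map distance d under
#' the no-interference (Poisson crossover) model:
#' `d = -50 * log(1 - 2r)` cM and `r = (1 - exp(-d/50)) / 2`.
#'
#' @param r Recombination fraction(s), `0 <= r < 0.5` (0.5 means unlinked
#'   and has no finite map distance).
#' @param d_cM Map distance(s) in cM, `>= 0`.
#' @return [haldane_cM()] returns cM; [haldane_r()] returns r.
#' @examples
#' haldane_r(10)          # ~0.0906
#' haldane_cM(haldane_r(10))  # 10
#' @export
haldane_cM <- function(r) {
  if (any(r < 0 | r >= 0.5))
    stop("r must satisfy 0 <= r < 0.5 (r = 0.5 is unlinked)")
  -50 * log(1 - 2 * r)
}

#' @rdname haldane_cM
#' @export
haldane_r <- function(d_cM) {
  if (any(d_cM < 0)) stop("map distance must be non-negative")
  (1 - exp(-d_cM / 50)) / 2
}

#' Two-point recombination fraction between a marker and the phenotype
#'
#' In a haploid cross with a fully penetrant monogenic phenotype, the
#' phenotype reads out the parental origin at the causal locus (down =>
#' Gd, up => Vx), so marker-phenotype discordance counts recombinant
#' meioses directly. Undetermined phenotypes and missing genotypes are
#' dropped and do not count as informative.
#'
#' @param genotypes Per-segregant marker origins, `"G"`/`"V"` (NA allowed).
#' @param phenos Per-segregant phenotypes, `"down"`/`"up"`/`"undetermined"`.
#' @return List with `n_informative`, `n_recombinant`, `r_hat`.
#' @export
recombination_fraction <- function(genotypes, phenos) {
  if (length(genotypes) != length(phenos))
    stop("genotype and phenotype vectors must have equal length")
  ok <- genotypes %in% c("G", "V") & phenos %in% c("down", "up")
  n_inf <- sum(ok)
  if (n_inf == 0L) stop("no informative segregants")
  rec <- sum((phenos[ok] == "down" & genotypes[ok] == "V") |
               (phenos[ok] == "up" & genotypes[ok] == "G"))
  list(n_informative = n_inf, n_recombinant = rec, r_hat = rec / n_inf)
}

#' Two-point linkage scan over a marker panel
#'
#' Applies [recombination_fraction()] at every marker of a genotyped
#' segregant population and adds the Haldane map distance where defined
#' (`r_hat < 0.5`).
#'
#' @param segregants A `haploid_cross` or list of segregants.
#' @param markers A `marker_map` (typically the local refinement panel).
#' @return Data frame `id, chrom, pos_bp, n_informative, n_recombinant,
#'   r_hat, d_cM` ordered by `(chrom, pos_bp)`; `d_cM` is NA when
#'   `r_hat >= 0.5`.
#' @export
linkage_scan <- function(segregants, markers) {
  geno <- genotype_matrix(segregants, markers)
  ph <- phenotypes(segregants)
  res <- lapply(seq_len(nrow(markers)), function(j)
    recombination_fraction(geno[, j], ph))
  out <- data.frame(
    id = markers$id, chrom = markers$chrom, pos_bp = markers$pos_bp,
    n_informative = vapply(res, `[[`, 0, "n_informative"),
    n_recombinant = vapply(res, `[[`, 0, "n_recombinant"),
    r_hat = vapply(res, `[[`, 0, "r_hat"), stringsAsFactors = FALSE)
  out$d_cM <- ifelse(out$r_hat < 0.5, haldane_cM(pmin(out$r_hat, 0.5 - 1e-12)),
                     NA_real_)
  out[order(out$chrom, out$pos_bp), , drop = FALSE]
}

#' Refine the candidate interval to the nearest flanking recombinants
#'
#' The causal locus must lie within the block of fully cosegregating
#' markers (zero recombinants). The refined interval runs from the nearest
#' marker left of that block showing at least one recombinant to the
#' nearest such marker on the right -- the classic second-round manual
#' genotyping step that shrinks a coarse array-mapped region to a few
#' hundred kb. Where no flanking recombinant marker exists on a side, the
#' interval extends to the chromosome end on that side, with a warning.
#'
#' @param linkage Per-marker linkage table from [linkage_scan()]; all
#'   markers must be on one chromosome.
#' @param chrom_length Optional chromosome length in bp, needed only when a
#'   flank is missing on the right.
#' @return A `genomic_interval` containing every zero-recombinant marker.
#' @export
refine_interval <- function(linkage, chrom_length = NULL) {
  if (length(unique(linkage$chrom)) != 1L)
    stop("refine_interval expects markers on a single chromosome")
  linkage <- linkage[order(linkage$pos_bp), , drop = FALSE]
  zero <- which(linkage$n_recombinant == 0)
  if (length(zero) == 0L)
    stop("locus not in the genotyped region: no fully cosegregating marker")
  lo <- min(linkage$pos_bp[zero]); hi <- max(linkage$pos_bp[zero])
  left <- linkage$pos_bp[linkage$n_recombinant >= 1 & linkage$pos_bp < lo]
  right <- linkage$pos_bp[linkage$n_recombinant >= 1 & linkage$pos_bp > hi]
  if (length(left)) {
    start <- max(left)
  } else {
    warning("no recombinant marker left of the cosegregating block; ",
            "extending to the chromosome start")
    start <- 1
  }
  if (length(right)) {
    end <- min(right)
  } else {
    warning("no recombinant marker right of the cosegregating block; ",
            "extending to the chromosome end")
    if (is.null(chrom_length))
      stop("chrom_length is required when no right flanking marker exists")
    end <- chrom_length
  }
  genomic_interval(linkage$chrom[1L], start, end)
}

#' Write a linkage scan as TSV
#'
#' @param linkage Output of [linkage_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_linkage <- function(linkage, path) {
  utils::write.table(linkage, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
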