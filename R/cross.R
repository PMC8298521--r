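#' Configuration of a simulated haploid cross
#'
#' Describes a Gd (mutant) x Vx (wild-type) haploid cross: each meiotic
#' product is a haploid segregant whose genotype is read directly, without
#' phase ambiguity. Carriers of the Gd allele at the causal locus express
#' the selected ("down") phenotype with probability `penetrance`; all other
#' progeny score "up"; any progeny may independently be relabelled
#' "undetermined". The study-scale defaults are a 48-member phenotypic bulk
#' pooled and sequenced at a mean 50 reads per marker with a 1% per-read
#' allele error.
#'
#' @param genome A `toy_genome`.
#' @param markers A `marker_map` on that genome.
#' @param causal_chrom,causal_pos Location of the causal mutation.
#' @param n_progeny Number of meiotic products to simulate (default 150,
#'   comfortably above twice the default bulk size under 1:1 segregation).
#' @param n_bulk Bulk size (default 48).
#' @param coverage Mean reads per marker in the pooled bulk (default 50).
#' @param error_rate Per-read probability that a read reports the other
#'   parental allele (default 0.01).
#' @param penetrance P(carrier scores "down") (default 1).
#' @param undetermined_rate P(progeny relabelled "undetermined") (default 0).
#' @param seed Optional integer seed; when set, [simulate_cross()] is fully
#'   reproducible.
#' @return An object of class `cross_config`.
#' @export
cross_config <- function(genome, markers, causal_chrom, causal_pos,
                         n_progeny = 150, n_bulk = 48, coverage = 50,
                         error_rate = 0.01, penetrance = 1,
                         undetermined_rate = 0, seed = NULL) {
  stopifnot(inherits(genome, "toy_genome"), inherits(markers, "marker_map"))
  if (!causal_chrom %in% genome$chroms$name)
    stop("causal locus chromosome not in genome: ", causal_chrom)
  if (causal_pos < 1 || causal_pos > chrom_length(genome, causal_chrom))
    stop("causal locus position outside ", causal_chrom)
  if (!all(markers$chrom %in% genome$chroms$name))
    stop("marker map references chromosomes absent from the genome")
  if (n_bulk > n_progeny) stop("n_bulk must not exceed n_progeny")
  stopifnot(error_rate >= 0, error_rate <= 1,
            undetermined_rate >= 0, undetermined_rate <= 1,
            penetrance > 0, penetrance <= 1, coverage > 0)
  structure(list(genome = genome, markers = markers,
                 causal_chrom = causal_chrom, causal_pos = causal_pos,
                 n_progeny = as.integer(n_progeny),
                 n_bulk = as.integer(n_bulk), coverage = coverage,
                 error_rate = error_rate, penetrance = penetrance,
                 undetermined_rate = undetermined_rate, seed = seed),
            class = "cross_config")
}

#' Simulate one meiosis on one chromosome
#'
#' No-interference crossover model: the crossover count is Poisson with mean
#' equal to the genetic length in Morgans, crossover genetic positions are
#' uniform, and genetic positions are mapped to bp by piecewise-linear
#' interpolation through the `(pos_cM, pos_bp)` pairs of `cm_map` (constant
#' extrapolation beyond the terminal markers). The starting parental origin
#' is Bernoulli(1/2). Under this model the discordance between two loci
#' d cM apart follows the Haldane map function, matching the linkage stage.
#'
#' Uses the current R random number stream; seed at the caller (see
#' [simulate_cross()]).
#'
#' @param genetic_length_cM Genetic length of the chromosome in cM (>= 0).
#' @param chrom_length Physical length in bp.
#' @param cm_map Data frame with columns `pos_cM`, `pos_bp`; `NULL` means a
#'   uniform map from `[0, genetic_length_cM]` onto `[1, chrom_length]`.
#' @return A haplotype segment table: data frame with columns
#'   `start`, `end`, `origin` ("Gd"/"Vx") tiling `[1, chrom_length]` with
#'   alternating origins.
#' @export
simulate_meiosis <- function(genetic_length_cM, chrom_length, cm_map = NULL) {
  stopifnot(genetic_length_cM >= 0, chrom_length >= 1)
  if (is.null(cm_map))
    cm_map <- data.frame(pos_cM = c(0, genetic_length_cM),
                         pos_bp = c(1, chrom_length))
  cm_lo <- min(cm_map$pos_cM)
  n_xo <- stats::rpois(1L, genetic_length_cM / 100)
  bp <- numeric(0)
  if (n_xo > 0L) {
    xo_cM <- stats::runif(n_xo, cm_lo, cm_lo + genetic_length_cM)
    if (nrow(cm_map) >= 2L) {
      xo_bp <- stats::approx(cm_map$pos_cM, cm_map$pos_bp, xout = xo_cM,
                             rule = 2, ties = "ordered")$y
    } else {
      xo_bp <- rep(cm_map$pos_bp, n_xo)
    }
    xo_bp <- pmin(pmax(round(xo_bp), 1), chrom_length - 1)
    # crossovers collapsing onto the same bp cancel pairwise
    tab <- table(xo_bp)
    bp <- sort(as.numeric(names(tab))[tab %% 2 == 1])
  }
  origins <- c("Gd", "Vx")
  first <- sample(origins, 1L)
  starts <- c(1, bp + 1)
  ends <- c(bp, chrom_length)
  data.frame(start = starts, end = ends,
             origin = origins[(match(first, origins) + seq_along(starts) - 2L) %% 2L + 1L],
             stringsAsFactors = FALSE)
}

#' Parental origin of a haplotype at a position
#'
#' @param haplotype Named list of per-chromosome segment tables (as stored
#'   in a segregant), or a single segment table.
#' @param chrom Chromosome name (ignored when a single table is given).
#' @param pos 1-based position(s).
#' @return Character vector of "Gd"/"Vx".
#' @export
origin_at <- function(haplotype, chrom = NULL, pos) {
  seg <- if (is.data.frame(haplotype)) haplotype else haplotype[[chrom]]
  if (is.null(seg)) stop("haplotype has no chromosome ", chrom)
  seg$origin[findInterval(pos, seg$start)]
}

#' Simulate a haploid cross
#'
#' Generates `n_progeny` independent meioses across all chromosomes (the
#' genetic length of each chromosome is the cM span of its markers; a
#' chromosome without markers segregates as a single non-recombining unit)
#' and scores the phenotype from the parental origin at the causal locus:
#' Gd carriers are "down" with probability `penetrance`, otherwise "up";
#' non-carriers are "up"; each progeny is independently relabelled
#' "undetermined" with probability `undetermined_rate`. With full penetrance
#' and no undetermined class this reproduces the 1:1 phenotype segregation
#' expected of a monogenic haploid cross.
#'
#' @param config A [cross_config()].
#' @return List of segregants (class `haploid_cross`), each a list with
#'   `id`, `haplotype` (named list of segment tables) and `phenotype`
#'   ("down"/"up"/"undetermined"). The config is attached as attribute
#'   `config`.
#' @export
simulate_cross <- function(config) {
  stopifnot(inherits(config, "cross_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  chroms <- config$genome$chroms
  glen <- vapply(chroms$name, function(ch)
    chrom_genetic_length(config$markers, ch), 0)
  maps <- lapply(chroms$name, function(ch) {
    m <- config$markers[config$markers$chrom == ch, , drop = FALSE]
    if (nrow(m) >= 2L) data.frame(pos_cM = m$pos_cM, pos_bp = m$pos_bp) else NULL
  })
  names(maps) <- chroms$name
  segregants <- vector("list", config$n_progeny)
  for (i in seq_len(config$n_progeny)) {
    hap <- lapply(seq_len(nrow(chroms)), function(k)
      simulate_meiosis(glen[k], chroms$length[k], maps[[k]]))
    names(hap) <- chroms$name
    carrier <- origin_at(hap, config$causal_chrom, config$causal_pos) == "Gd"
    pheno <- if (carrier && stats::runif(1) <= config$penetrance) "down" else "up"
    if (config$undetermined_rate > 0 &&
        stats::runif(1) < config$undetermined_rate) pheno <- "undetermined"
    segregants[[i]] <- list(id = sprintf("seg%04d", i), haplotype = hap,
                            phenotype = pheno)
  }
  structure(segregants, class = "haploid_cross", config = config)
}

#' Phenotypes of a cross or segregant list
#'
#' @param segregants A `haploid_cross` or plain list of segregants.
#' @return Character vector.
#' @export
phenotypes <- function(segregants) {
  vapply(segregants, `[[`, "", "phenotype")
}

#' Select the phenotypic bulk
#'
#' The first `n_bulk` segregants (in input order, hence deterministic) with
#' the requested phenotype. "undetermined" progeny never enter a bulk.
#'
#' @inheritParams phenotypes
#' @param phenotype Phenotype selected into the bulk (default "down", the
#'   mutant class).
#' @param n_bulk Bulk size (default 48).
#' @return List of segregants of length `n_bulk`.
#' @export
make_bulk <- function(segregants, phenotype = "down", n_bulk = 48) {
  if (phenotype == "undetermined")
    stop("undetermined progeny cannot form a bulk")
  hit <- which(phenotypes(segregants) == phenotype)
  if (length(hit) < n_bulk)
    stop("cannot form a bulk of ", n_bulk, " '", phenotype,
         "' segregants: only ", length(hit), " available")
  unclass(segregants)[hit[seq_len(n_bulk)]]
}

#' Genotype segregants at the map markers
#'
#' @inheritParams phenotypes
#' @param markers A `marker_map`.
#' @return Character matrix (`"G"` = Gd origin, `"V"` = Vx origin) with one
#'   row per segregant (rownames = ids) and one column per marker
#'   (colnames = marker ids).
#' @export
genotype_matrix <- function(segregants, markers) {
  stopifnot(inherits(markers, "marker_map"))
  n <- length(segregants)
  out <- matrix(NA_character_, n, nrow(markers),
                dimnames = list(vapply(segregants, `[[`, "", "id"),
                                markers$id))
  for (ch in unique(markers$chrom)) {
    sel <- markers$chrom == ch
    pos <- markers$pos_bp[sel]
    for (i in seq_len(n)) {
      seg <- segregants[[i]]$haplotype[[ch]]
      out[i, sel] <- ifelse(seg$origin[findInterval(pos, seg$start)] == "Gd",
                            "G", "V")
    }
  }
  out
}

#' Simulate pooled sequencing depths for a bulk
#'
#' Per marker, the total read depth is Poisson(`coverage`); each read is
#' drawn from the origin allele of a uniformly chosen bulk member and flips
#' to the other parental allele with probability `error_rate`. (Implemented
#' by the equivalent binomial thinning: Gd-template reads are
#' Binomial(total, bulk Gd fraction) and errors flip each direction
#' independently.)
#'
#' @param bulk List of segregants (see [make_bulk()]).
#' @param markers A `marker_map`.
#' @param coverage Mean reads per marker.
#' @param error_rate Per-read allele flip probability.
#' @param seed Optional seed.
#' @return Bulk depth table: data frame with columns
#'   `chrom, pos_bp, id, gd_depth, vx_depth`.
#' @export
simulate_pool_depths <- function(bulk, markers, coverage = 50,
                                 error_rate = 0.01, seed = NULL) {
  if (length(bulk) == 0L) stop("bulk is empty")
  stopifnot(coverage > 0, error_rate >= 0, error_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  geno <- genotype_matrix(bulk, markers)
  p_gd <- colMeans(geno == "G")
  nm <- nrow(markers)
  total <- stats::rpois(nm, coverage)
  gd_templates <- stats::rbinom(nm, total, p_gd)
  gd_depth <- stats::rbinom(nm, gd_templates, 1 - error_rate) +
    stats::rbinom(nm, total - gd_templates, error_rate)
  data.frame(chrom = markers$chrom, pos_bp = markers$pos_bp,
             id = markers$id, gd_depth = gd_depth,
             vx_depth = total - gd_depth, stringsAsFactors = FALSE)
}

#' Read/write bulk depth tables and segregant tables as TSV
#'
#' Depth tables have columns `chrom, pos_bp, id, gd_depth, vx_depth`.
#' Segregant tables have one row per segregant: `id`, `phenotype`, then one
#' G/V column per marker.
#'
#' @param depths,path,segregants,markers Arguments as named.
#' @return Readers return the table; writers return `path` invisibly.
#' @export
write_depth_table <- function(depths, path) {
  utils::write.table(depths, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_table
#' @export
read_depth_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos_bp", "id", "gd_depth", "vx_depth")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing depth columns: ", paste(miss, collapse = ", "))
  if (any(df$gd_depth < 0 | df$vx_depth < 0)) stop("negative depths")
  df[need]
}

#' @rdname write_depth_table
#' @export
write_segregant_table <- function(segregants, markers, path) {
  geno <- genotype_matrix(segregants, markers)
  df <- data.frame(id = rownames(geno), phenotype = phenotypes(segregants),
                   geno, stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_depth_table
#' @export
read_segregant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("id", "phenotype") %in% names(df)))
    stop("segregant table needs 'id' and 'phenotype' columns")
  df
}
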