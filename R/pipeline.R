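#' Assemble a full pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: the simulated cross (or, via
#' [read_depth_table()] and [read_segregant_table()], tables loaded from
#' disk can be substituted stage by stage), the gene models and the variant
#' list to annotate, the BSA windowing parameters, and an optional local
#' marker panel for the second-round linkage refinement.
#'
#' @param cross A [cross_config()] (carries genome, markers, causal locus,
#'   bulk and sequencing parameters, and the seed).
#' @param genes List of `gene_model`s.
#' @param variants Data frame of SNVs (`chrom, pos_bp, ref, alt`) to
#'   annotate and filter; typically the causal mutation plus decoys.
#' @param window,step,threshold,min_markers,min_run BSA parameters, see
#'   [window_means()] and [detect_peaks()].
#' @param refine_markers Optional `marker_map` of the local refinement
#'   panel; when given, a two-point linkage scan of all (non-bulk-selected)
#'   segregants refines the peak interval.
#' @param include_splice Passed to [filter_candidates()].
#' @param out_dir Optional directory; when given, every stage output is
#'   written there as TSV/BED plus a plain-text report.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cross, genes, variants, window = 5e5,
                            step = 2.5e5, threshold = 0.9, min_markers = 5,
                            min_run = 1, refine_markers = NULL,
                            include_splice = FALSE, out_dir = NULL) {
  stopifnot(inherits(cross, "cross_config"))
  structure(list(cross = cross, genes = genes, variants = variants,
                 window = window, step = step, threshold = threshold,
                 min_markers = min_markers, min_run = min_run,
                 refine_markers = refine_markers,
                 include_splice = include_splice, out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the mapping pipeline end to end
#'
#' Executes simulate -> bulk -> pooled depths -> ratio track -> sliding
#' windows -> peak detection -> (optional) linkage refinement -> variant
#' annotation -> candidate filtering. Every stage logs its parameters; with
#' `out_dir` set, every intermediate is written (depths, per-marker ratios,
#' windows as TSV; peaks and the final interval as BED; candidates as TSV;
#' the report as text). Identical configurations with identical seeds give
#' identical outputs. An empty candidate list is a valid outcome and is
#' reported as such.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with elements `cross`, `bulk`,
#'   `depths`, `track`, `windows`, `peaks`, `interval` (the final mapped
#'   interval or NULL), `linkage` (or NULL), `annotated`, `candidates`,
#'   `report` (character lines) and `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    message(line)
    invisible(NULL)
  }
  cc <- config$cross
  note("stage=simulate n_progeny=%d seed=%s penetrance=%g undetermined=%g",
       cc$n_progeny, if (is.null(cc$seed)) "NULL" else cc$seed,
       cc$penetrance, cc$undetermined_rate)
  cross <- simulate_cross(cc)
  ph <- table(factor(phenotypes(cross), c("down", "up", "undetermined")))
  note("stage=simulate down=%d up=%d undetermined=%d",
       ph[["down"]], ph[["up"]], ph[["undetermined"]])

  note("stage=bulk phenotype=down n_bulk=%d", cc$n_bulk)
  bulk <- make_bulk(cross, "down", cc$n_bulk)

  note("stage=depths coverage=%g error_rate=%g n_markers=%d",
       cc$coverage, cc$error_rate, nrow(cc$markers))
  depths <- simulate_pool_depths(bulk, cc$markers, cc$coverage, cc$error_rate)

  track <- ratio_track(depths)
  note("stage=ratio n_defined=%d of %d markers", nrow(track), nrow(cc$markers))
  windows <- window_means(track, cc$genome, config$window, config$step,
                          config$min_markers)
  note("stage=windows window=%g step=%g min_markers=%d n_windows=%d",
       config$window, config$step, config$min_markers, nrow(windows))
  peaks <- detect_peaks(windows, config$threshold, config$min_run)
  note("stage=peaks threshold=%g min_run=%d n_peaks=%d",
       config$threshold, config$min_run, length(peaks))

  interval <- if (length(peaks)) peaks[[1L]]$interval else NULL
  linkage <- NULL
  if (!is.null(interval) && !is.null(config$refine_markers)) {
    panel <- config$refine_markers
    panel <- panel[panel$chrom == interval$chrom, , drop = FALSE]
    class(panel) <- class(config$refine_markers)
    note("stage=refine n_segregants=%d n_panel_markers=%d",
         length(cross), nrow(panel))
    linkage <- linkage_scan(cross, panel)
    interval <- refine_interval(linkage,
                                chrom_length(cc$genome, interval$chrom))
    note("stage=refine interval=%s:%d-%d width_kb=%s", interval$chrom,
         interval$start, interval$end, kb_label(interval_width(interval)))
  }

  annotated <- classify_variants(cc$genome, config$genes, config$variants)
  candidates <- if (is.null(interval)) annotated[0, , drop = FALSE] else
    filter_candidates(annotated, interval, config$include_splice)
  note("stage=filter n_variants=%d n_candidates=%d include_splice=%s",
       nrow(annotated), nrow(candidates), config$include_splice)

  report <- c(
    sprintf("haploid bulk mapping report (seed=%s)",
            if (is.null(cc$seed)) "NULL" else cc$seed),
    if (is.null(interval)) "mapped interval: none (no peak detected)" else
      sprintf("mapped interval: %s:%d-%d (%s kb)", interval$chrom,
              interval$start, interval$end,
              kb_label(interval_width(interval))),
    candidate_report(candidates))
  out <- structure(list(cross = cross, bulk = bulk, depths = depths,
                        track = track, windows = windows, peaks = peaks,
                        interval = interval, linkage = linkage,
                        annotated = annotated, candidates = candidates,
                        report = report, log = log),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) .write_pipeline_outputs(out, config)
  out
}

.write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  write_depth_table(result$depths, p("depths.tsv"))
  utils::write.table(result$track, p("ratios.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$windows, p("windows.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_peaks(result$peaks, p("peaks.bed"))
  if (!is.null(result$interval))
    write_bed(result$interval, p("interval.bed"), names = "mapped_interval")
  if (!is.null(result$linkage)) write_linkage(result$linkage, p("linkage.tsv"))
  utils::write.table(result$candidates, p("candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(c(result$report, "", result$log), p("report.txt"))
  invisible(config$out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  writeLines(x$report)
  invisible(x)
}

#' Simulate a complete toy mapping study
#'
#' Builds a self-contained study on one chromosome: a random-sequence
#' genome, an even marker panel, a causal gene carrying a stop-gained
#' mutation (a Gln CAG codon at protein position 598 mutated to TAG, the
#' classic premature-stop lesion) at the causal locus, a decoy gene with
#' its own stop-gained variant far from the causal locus, plus synonymous,
#' missense and intronic decoy variants near the causal gene.
#'
#' @param seed Integer seed.
#' @param chrom_length Chromosome length in bp (default 4e6).
#' @param genetic_length_cM Genetic length of the chromosome (default 100,
#'   a full-length chromosome, so loci at opposite ends are effectively
#'   unlinked regardless of the physical scale).
#' @param n_markers Marker count (default 400).
#' @param causal_frac Causal locus position as a fraction of the chromosome
#'   (default 0.5).
#' @param n_progeny,n_bulk,coverage,error_rate Passed to [cross_config()].
#' @return List with `genome`, `markers`, `genes`, `variants`,
#'   `causal` (list `chrom, pos_bp, gene_id`) and `cross` (a
#'   [cross_config()]).
#' @export
simulate_toy_study <- function(seed, chrom_length = 4e6,
                               genetic_length_cM = 100, n_markers = 400,
                               causal_frac = 0.5, n_progeny = 150,
                               n_bulk = 48, coverage = 50,
                               error_rate = 0.01) {
  set.seed(seed)
  chrom <- "chr2"
  seq <- paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
               collapse = "")

  # 600-codon CDS: ATG, Ala filler, Gln CAG at codon 598, TAA stop
  make_cds <- function() {
    codons <- rep("GCT", 600)
    codons[1] <- "ATG"; codons[598] <- "CAG"; codons[600] <- "TAA"
    paste(codons, collapse = "")
  }
  # plant a two-exon gene whose codon-598 first base sits at `anchor`
  plant_gene <- function(seq, gene_id, anchor) {
    cds <- make_cds()
    exon1_len <- 300; intron_len <- 200
    cds_pos <- 3 * 597 + 1            # first base of codon 598
    exon2_start <- anchor - (cds_pos - exon1_len) + 1
    exon1_start <- exon2_start - intron_len - exon1_len
    exon1_end <- exon1_start + exon1_len - 1
    exon2_end <- exon2_start + (nchar(cds) - exon1_len) - 1
    substr(seq, exon1_start, exon1_end) <- substr(cds, 1, exon1_len)
    substr(seq, exon2_start, exon2_end) <- substr(cds, exon1_len + 1,
                                                  nchar(cds))
    # canonical GT...AG intron
    substr(seq, exon1_end + 1, exon1_end + 2) <- "GT"
    substr(seq, exon2_start - 2, exon2_start - 1) <- "AG"
    gene <- gene_model(gene_id, chrom, "+",
                       data.frame(start = c(exon1_start, exon2_start),
                                  end = c(exon1_end, exon2_end)))
    list(seq = seq, gene = gene,
         exon1_start = exon1_start, exon1_end = exon1_end)
  }

  causal_pos <- round(chrom_length * causal_frac)
  g1 <- plant_gene(seq, "geneA", causal_pos)
  decoy_pos <- round(chrom_length * 0.1)
  g2 <- plant_gene(g1$seq, "geneB", decoy_pos)
  seq <- g2$seq

  genome <- toy_genome(chrom, chrom_length, stats::setNames(seq, chrom))
  markers <- even_marker_map(genome, n_markers, genetic_length_cM)
  variants <- data.frame(
    chrom = chrom,
    pos_bp = c(causal_pos,                    # stop_gained: CAG > TAG, Q598X
               g1$exon1_start + 5,            # synonymous: GCT > GCC (codon 2)
               g1$exon1_start + 7,            # missense:   GCT > GTT (codon 3)
               g1$exon1_end + 50,             # intronic
               decoy_pos),                    # stop_gained decoy, far away
    ref = c("C", "T", "C", substr(seq, g1$exon1_end + 50, g1$exon1_end + 50),
            "C"),
    alt = c("T", "C", "T",
            setdiff(c("A", "C", "G", "T"),
                    substr(seq, g1$exon1_end + 50, g1$exon1_end + 50))[1L],
            "T"),
    stringsAsFactors = FALSE)
  cross <- cross_config(genome, markers, chrom, causal_pos,
                        n_progeny = n_progeny, n_bulk = n_bulk,
                        coverage = coverage, error_rate = error_rate,
                        seed = seed)
  list(genome = genome, markers = markers, genes = list(g1$gene, g2$gene),
       variants = variants,
       causal = list(chrom = chrom, pos_bp = causal_pos, gene_id = "geneA"),
       cross = cross)
}
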