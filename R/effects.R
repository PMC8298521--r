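#' Translate a codon with the standard nuclear genetic code
#'
#' @param codon Three bases over A/C/G/T.
#' @return One-letter amino acid, `"*"` for a stop codon.
#' @export
translate_codon <- function(codon) {
  codon <- toupper(as.character(codon))
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("invalid codon: '", codon, "'")
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify a single-codon change
#'
#' Translates both codons with the standard code and compares: a residue
#' changing to a stop is `stop_gained` (a nonsense mutation, e.g. CAG (Gln)
#' to TAG or TAA), a stop changing to a residue is `stop_lost`, the same
#' residue is `synonymous` (e.g. CAG to CAA, both Gln, or AGT to TCA, both
#' Ser), and different residues are `missense`.
#'
#' @param ref_codon,alt_codon Three-base codons over A/C/G/T.
#' @return List with `effect` (one of `synonymous`, `missense`,
#'   `stop_gained`, `stop_lost`), `aa_ref`, `aa_alt` (one-letter, `"*"` for
#'   stop).
#' @examples
#' classify_codon_change("CAG", "TAG")$effect  # stop_gained
#' classify_codon_change("CAG", "CAA")$effect  # synonymous
#' @export
classify_codon_change <- function(ref_codon, alt_codon) {
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  effect <-
    if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "stop_gained"
    else if (aa_ref == "*") "stop_lost"
    else "missense"
  list(effect = effect, aa_ref = aa_ref, aa_alt = aa_alt)
}

.complement <- function(base) chartr("ACGT", "TGCA", base)

#' Classify a single-nucleotide variant against gene models
#'
#' Maps the position onto the gene models: outside every gene is
#' `intergenic`; within a transcript but outside the CDS span is `utr`;
#' inside an intron and within 2 bp of an exon boundary (the canonical
#' GT/AG dinucleotides) is `splice_site`, deeper is `intronic`. Inside the
#' CDS the affected codon is located strand-aware, classified with
#' [classify_codon_change()], and the protein change is reported as
#' residue + codon index + replacement with `"X"` for a stop (e.g. `Q598X`
#' for a Gln codon at position 598 mutated to a premature stop). A
#' non-synonymous change in codon 1 is reported as `start_lost`.
#'
#' @param genome `toy_genome` with sequences.
#' @param genes List of `gene_model`s.
#' @param chrom,pos,ref,alt The SNV; `ref` must match the genome (an N in
#'   the reference is rejected).
#' @return A list of class `variant_call` with fields `chrom, pos_bp,
#'   ref, alt, gene_id, effect, protein_change` (`gene_id` and
#'   `protein_change` are NA where not applicable).
#' @export
classify_variant <- function(genome, genes, chrom, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!grepl("^[ACGT]$", ref) || !grepl("^[ACGT]$", alt) || ref == alt)
    stop("ref and alt must be distinct single bases over ACGT")
  base <- genome_base(genome, chrom, pos)
  if (base == "N")
    stop("variant at ", chrom, ":", pos, " falls on an N reference base")
  if (base != ref)
    stop("reference mismatch at ", chrom, ":", pos,
         ": genome has ", base, ", variant claims ", ref)
  if (inherits(genes, "gene_model")) genes <- list(genes)
  call <- list(chrom = chrom, pos_bp = pos, ref = ref, alt = alt,
               gene_id = NA_character_, effect = "intergenic",
               protein_change = NA_character_)
  for (g in genes) {
    if (g$chrom != chrom || pos < g$tx_start || pos > g$tx_end) next
    call$gene_id <- g$gene_id
    off <- cds_offset(g, pos)
    if (!is.na(off)) {
      cds <- cds_sequence(g, genome)
      codon_idx <- (off - 1) %/% 3 + 1
      pos_in_codon <- (off - 1) %% 3 + 1
      ref_codon <- substr(cds, (codon_idx - 1) * 3 + 1, codon_idx * 3)
      alt_cds_base <- if (g$strand == "+") alt else .complement(alt)
      alt_codon <- ref_codon
      substr(alt_codon, pos_in_codon, pos_in_codon) <- alt_cds_base
      cc <- classify_codon_change(ref_codon, alt_codon)
      call$effect <- cc$effect
      if (codon_idx == 1 && cc$effect != "synonymous")
        call$effect <- "start_lost"
      call$protein_change <- paste0(
        if (cc$aa_ref == "*") "X" else cc$aa_ref, codon_idx,
        if (cc$aa_alt == "*") "X" else cc$aa_alt)
    } else {
      ex <- g$cds_exons
      if (pos < min(ex$start) || pos > max(ex$end)) {
        call$effect <- "utr"
        call$protein_change <- NA_character_
      } else {
        # distance into the intron from the nearest exon boundary
        d_left <- pos - max(ex$end[ex$end < pos])
        d_right <- min(ex$start[ex$start > pos]) - pos
        call$effect <- if (min(d_left, d_right) <= 2) "splice_site" else "intronic"
        call$protein_change <- NA_character_
      }
    }
    break
  }
  structure(call, class = "variant_call")
}

#' @export
print.variant_call <- function(x, ...) {
  cat(sprintf("%s:%s %s>%s  %s%s%s\n", x$chrom,
              format(x$pos_bp, big.mark = ","), x$ref, x$alt, x$effect,
              if (is.na(x$gene_id)) "" else paste0("  gene=", x$gene_id),
              if (is.na(x$protein_change)) "" else
                paste0("  ", x$protein_change)))
  invisible(x)
}

#' Classify a table of SNVs
#'
#' @inheritParams classify_variant
#' @param variants Data frame with columns `chrom, pos_bp, ref, alt`.
#' @return The input with `gene_id`, `effect`, `protein_change` columns
#'   appended.
#' @export
classify_variants <- function(genome, genes, variants) {
  need <- c("chrom", "pos_bp", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("missing variant columns: ", paste(miss, collapse = ", "))
  calls <- lapply(seq_len(nrow(variants)), function(i)
    classify_variant(genome, genes, variants$chrom[i], variants$pos_bp[i],
                     variants$ref[i], variants$alt[i]))
  variants$gene_id <- vapply(calls, `[[`, "", "gene_id")
  variants$effect <- vapply(calls, `[[`, "", "effect")
  variants$protein_change <- vapply(calls, `[[`, "", "protein_change")
  variants
}

#' Filter annotated variants to mapping candidates
#'
#' Retains only nonsynonymous (`missense`) and nonsense (`stop_gained`)
#' variants within genes inside the mapped interval -- the candidate filter
#' applied after mapping. Splice-site variants can optionally be kept as
#' well (off by default).
#'
#' @param variants Annotated variant table (see [classify_variants()]).
#' @param interval A `genomic_interval` (e.g. the top mapping peak's
#'   interval or the refined linkage interval).
#' @param include_splice Also retain `splice_site` variants (default FALSE).
#' @return The retained rows, sorted by position. Subset of the input;
#'   idempotent.
#' @export
filter_candidates <- function(variants, interval, include_splice = FALSE) {
  stopifnot(inherits(interval, "genomic_interval"))
  keep_effects <- c("missense", "stop_gained",
                    if (include_splice) "splice_site")
  keep <- variants$effect %in% keep_effects &
    interval_contains(interval, variants$chrom, variants$pos_bp)
  out <- variants[keep, , drop = FALSE]
  out <- out[order(out$pos_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Human-readable candidate report lines
#'
#' Stop-gained candidates are ranked above missense (then splice-site),
#' positional order within each class.
#'
#' @param candidates Output of [filter_candidates()].
#' @return Character vector of report lines (empty input gives a single
#'   "no candidates" line).
#' @export
candidate_report <- function(candidates) {
  if (nrow(candidates) == 0L)
    return("no candidates: no retained variant inside the mapped interval")
  rank <- match(candidates$effect, c("stop_gained", "missense", "splice_site"))
  ord <- order(rank, candidates$pos_bp)
  x <- candidates[ord, , drop = FALSE]
  sprintf("%-12s %s:%s %s>%s gene=%s %s", x$effect, x$chrom,
          format(x$pos_bp, big.mark = ",", trim = TRUE), x$ref, x$alt,
          x$gene_id, ifelse(is.na(x$protein_change), "", x$protein_change))
}
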