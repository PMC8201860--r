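# End-to-end orchestration: simulate -> detect -> assemble -> annotate ->
# frame impact -> allele-specific expression -> verdict.

# 0-based genomic offset -> 1-based CDS nt (NA outside the CDS).
genomic_to_cds <- function(pos0, cds_intervals) {
  cum <- 0L
  for (i in seq_len(nrow(cds_intervals))) {
    s <- cds_intervals[i, 1]; e <- cds_intervals[i, 2]
    if (pos0 >= s && pos0 < e) return(cum + (pos0 - s) + 1L)
    cum <- cum + (e - s)
  }
  NA_integer_
}

# Spliced CDS of the reference sequence.
reference_cds <- function(truth) {
  paste(substring(truth$reference, truth$cds_intervals[, 1] + 1L,
                  truth$cds_intervals[, 2]), collapse = "")
}

#' Run the full analysis chain on a simulated clone
#'
#' Builds the ground-truth locus for a clone archetype, simulates DNA and
#' RNA reads, detects insertion breakpoints from soft-clipped alignments,
#' reconstructs any insertion by iterative extension, annotates it (TIRs,
#' library identity, truncation), computes the reading-frame impact on the
#' CDS, quantifies allele-specific expression at the variant sites, and
#' predicts the insecticide-response phenotype from the archetype's
#' haplotype pair.
#'
#' @param archetype clone archetype (see [build_locus()]).
#' @param seed integer seed driving every stochastic stage.
#' @param outdir optional output directory; when given, all intermediate
#'   files (FASTA/FASTQ/SAM/TSV/JSON) are written there.
#' @param dna_coverage,rna_coverage fold coverages for the two read sets.
#' @param nmd_retention residual abundance of PTC-bearing transcripts.
#' @param te_library optional named character vector of full-length
#'   elements for annotation; defaults to the simulated element's
#'   full-length parent (a synthetic stand-in for a curated library).
#' @return a `run_report`: list with `verdict` (one-row data.frame),
#'   `truth`, `calls`, `insertion`, `annotation`, `impact`, `ase`,
#'   `files`.
#' @examples
#' \donttest{
#' rep <- run_end_to_end("62H2", seed = 1)
#' rep$verdict
#' }
#' @export
run_end_to_end <- function(archetype = "62H2", seed = 1, outdir = NULL,
                           dna_coverage = 40, rna_coverage = 100,
                           nmd_retention = 0.05, te_library = NULL) {
  truth <- build_locus(archetype, seed = seed)
  files <- character(0)
  emit <- function(name, writer) {
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      path <- file.path(outdir, name)
      writer(path)
      files <<- c(files, path)
    }
  }

  dna <- simulate_reads(truth, "dna", coverage = dna_coverage, seed = seed)
  aln <- sim_alignments(dna)
  emit("dna.sam", function(p) write_sam(dna, p))
  emit("reads_1.fq", function(p)
    write_fastq(dna, p, file.path(outdir, "reads_2.fq")))
  emit("locus.fa", function(p) write_fasta(c(locus = truth$reference), p))

  clusters <- collect_clips(aln)
  calls <- call_insertions(clusters, aln)
  emit("calls.tsv", function(p) write_calls(calls, tsv_path = p))

  insertion <- NULL; annotation <- NULL; impact <- NULL
  if (nrow(calls) > 0) {
    best <- calls[which.max(calls$clipped_support), ]
    insertion <- assemble_insertion(best, dna$reads$seq_plus)
    if (insertion$status == "merged") {
      emit("insert.fa", function(p) write_insertion(insertion, p))
      lib <- te_library
      if (is.null(lib)) {
        te <- NULL
        for (h in truth$haplotypes) {
          if (h$insert_length > 0) te <- h$insertion$te
        }
        lib <- if (!is.null(te)) {
          c(full_length_element = te$parent_sequence %||% te$sequence)
        }
      }
      if (!is.null(lib)) {
        annotation <- compare_to_library(insertion$sequence, lib)
        emit("te_annotation.json", function(p)
          write_te_annotation(annotation, json_path = p))
      }
      cds_pos <- genomic_to_cds(best$breakpoint, truth$cds_intervals)
      if (!is.na(cds_pos)) {
        cds <- reference_cds(truth)
        modified <- apply_insertion(cds, cds_pos, insertion$sequence)
        impact <- annotate_impact(modified, cds_pos, insertion$length)
      }
    }
  }

  rna <- simulate_reads(truth, "rna", coverage = rna_coverage,
                        nmd_retention = nmd_retention, seed = seed + 1L)
  emit("rna.sam", function(p) write_sam(rna, p))
  rna_aln <- sim_alignments(rna)
  counts <- count_alleles(rna_aln, truth$sites,
                          ref_length = nchar(truth$reference))
  ase <- classify_expression(counts)
  # ASE is only meaningful at heterozygous sites: genotype each site from
  # the DNA alignments and mark fixed sites as such.
  dna_counts <- count_alleles(aln, truth$sites,
                              ref_length = nchar(truth$reference))
  het <- !is.na(dna_counts$alt_fraction) &
    dna_counts$alt_fraction > 0.2 & dna_counts$alt_fraction < 0.8
  ase$sites$dna_alt_fraction <- dna_counts$alt_fraction
  ase$sites$classification[!het] <-
    ifelse(dna_counts$alt_fraction[!het] >= 0.5, "fixed_alt", "fixed_ref")
  ase$verdict <- if (!any(het)) "no_heterozygous_site" else
    classify_expression(counts[het, , drop = FALSE])$verdict
  emit("ase.tsv", function(p) write_ase_tsv(ase$sites, p))

  geno <- vapply(truth$haplotypes, `[[`, character(1), "name")
  pheno <- phenotype(geno)

  verdict <- data.frame(
    archetype = archetype,
    insertion_detected = nrow(calls) > 0,
    breakpoint = if (nrow(calls)) calls$breakpoint[which.max(calls$clipped_support)]
                 else NA_integer_,
    zygosity = if (nrow(calls)) calls$zygosity[which.max(calls$clipped_support)]
               else NA_character_,
    insert_length = if (!is.null(insertion) && insertion$status == "merged")
      insertion$length else NA_integer_,
    tir = if (!is.null(annotation) && !is.null(annotation$tir))
      sprintf("%dnt/%dmm", annotation$tir$length, annotation$tir$mismatches)
      else "none",
    truncation = if (!is.null(annotation)) annotation$truncation$end
                 else NA_character_,
    first_disrupted_codon = if (!is.null(impact))
      impact$first_disrupted_codon else NA_integer_,
    first_ptc_codon = if (!is.null(impact)) impact$first_ptc_codon
                      else NA_integer_,
    nmd_target = if (!is.null(impact)) impact$nmd_target else NA,
    ase_verdict = ase$verdict,
    genotype = paste(sort(geno), collapse = "/"),
    phenotype = pheno,
    stringsAsFactors = FALSE)
  emit("verdict.json", function(p)
    jsonlite::write_json(verdict, p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA))

  structure(list(verdict = verdict, truth = truth, calls = calls,
                 insertion = insertion, annotation = annotation,
                 impact = impact, ase = ase, files = files),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  v <- x$verdict
  cat(sprintf("Archetype %s (genotype %s): phenotype %s\n",
              v$archetype, v$genotype, v$phenotype))
  if (v$insertion_detected) {
    cat(sprintf(
      "  insertion: %s, breakpoint %d, reconstructed length %s nt, TIR %s, truncation %s\n",
      v$zygosity, v$breakpoint,
      ifelse(is.na(v$insert_length), "?", v$insert_length), v$tir,
      v$truncation))
    if (!is.na(v$first_disrupted_codon)) {
      cat(sprintf("  frame: first disrupted codon %d, first PTC %s, NMD %s\n",
                  v$first_disrupted_codon,
                  ifelse(is.na(v$first_ptc_codon), "none",
                         v$first_ptc_codon),
                  v$nmd_target))
    }
  } else {
    cat("  insertion: none detected\n")
  }
  ss <- x$ase$sites
  for (i in seq_len(nrow(ss))) {
    cat(sprintf("  ASE %s: %d alt / %d ref (%.1f%% alt) -> %s\n",
                ss$label[i], ss$alt_count[i], ss$ref_count[i],
                100 * ss$alt_fraction[i], ss$classification[i]))
  }
  cat(sprintf("  expression verdict: %s\n", v$ase_verdict))
  invisible(x)
}
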