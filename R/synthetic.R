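# Ground-truth locus construction and paired-end read simulation.
#
# The simulator emulates the situation in which a clonal, diploid insect
# carries (i) a voltage-gated sodium channel (VGSC)-like gene whose coding
# sequence is interrupted on one haplotype by a DNA transposon with terminal
# inverted repeats (TIRs), and (ii) two linked resistance SNPs (kdr/skdr
# analogues) on the other haplotype.  Reads are emitted together with
# analytically computed truth alignments, so breakpoint detection, targeted
# assembly and allele-specific expression can all be tested without an
# external aligner.

#' Construct a random DNA transposon-like element with terminal inverted repeats
#'
#' The last `tir_length` bases of the element are the reverse complement of
#' the first `tir_length` bases, except at exactly `tir_mismatches` positions
#' ("imperfect" TIRs).
#'
#' @param length element length in nt.
#' @param tir_length TIR length in nt (0 for an element without TIRs).
#' @param tir_mismatches number of mismatched positions between the left TIR
#'   and the reverse complement of the right TIR.
#' @param seed integer seed; if `NULL` the current RNG stream is used (only
#'   sensible inside another seeded call).
#' @return an object of class `te_spec` with fields `sequence`, `tir_length`,
#'   `tir_mismatches`, `truncated_5p` (0 here) and `parent_sequence` (`NULL`).
#' @examples
#' te <- make_te(300, 50, 0, seed = 7)
#' nchar(te$sequence)
#' @export
make_te <- function(length, tir_length = 109, tir_mismatches = 5, seed = NULL) {
  if (length < 2 * tir_length) {
    stop("element length must be at least twice the TIR length")
  }
  if (tir_length > 0 && tir_mismatches >= tir_length) {
    stop("tir_mismatches must be smaller than tir_length")
  }
  if (tir_length == 0 && tir_mismatches != 0) {
    stop("tir_mismatches must be 0 when tir_length is 0")
  }
  build <- function() {
    s <- seq_chars(random_dna(length))
    if (tir_length > 0) {
      left <- s[1:tir_length]
      right <- seq_chars(revcomp(paste(left, collapse = "")))
      if (tir_mismatches > 0) {
        at <- sample.int(tir_length, tir_mismatches)
        right[at] <- vapply(right[at], function(b)
          sample(setdiff(DNA_BASES, b), 1L), character(1))
      }
      s[(length - tir_length + 1L):length] <- right
    }
    paste(s, collapse = "")
  }
  sequence <- if (is.null(seed)) build() else with_seed(seed, build())
  structure(list(sequence = sequence, tir_length = tir_length,
                 tir_mismatches = tir_mismatches, truncated_5p = 0L,
                 parent_sequence = NULL),
            class = "te_spec")
}

#' Truncate an element at its 5' end
#'
#' Models a 5'-truncated transposon copy: the result is a suffix of the
#' parent element, with the parent retained for library comparisons.
#'
#' @param te a `te_spec`.
#' @param bases number of 5' bases to remove.
#' @return a `te_spec` with `truncated_5p = bases` and `parent_sequence` set.
#' @export
truncate_te <- function(te, bases) {
  stopifnot(inherits(te, "te_spec"), bases >= 0,
            bases < nchar(te$sequence))
  if (bases == 0) return(te)
  structure(list(sequence = substr(te$sequence, bases + 1L, nchar(te$sequence)),
                 tir_length = te$tir_length,
                 tir_mismatches = te$tir_mismatches,
                 truncated_5p = as.integer(bases),
                 parent_sequence = te$sequence),
            class = "te_spec")
}

#' Assemble a ground-truth diploid locus
#'
#' Low-level constructor used both by [build_locus()] archetypes and by tests
#' that need bespoke loci. Coordinates are 0-based half-open on the reference;
#' an insertion breakpoint `b` means the element sits immediately before
#' reference offset `b`.
#'
#' @param reference reference locus sequence (the haplotype without the
#'   insertion and with reference bases at all variant sites).
#' @param haplotypes list of exactly two haplotype definitions, each a list
#'   with `name`, `alt_sites` (integer indices into `sites` whose alternate
#'   allele the haplotype carries) and optional `insertion = list(breakpoint,
#'   te)`.
#' @param sites optional data.frame with columns `pos` (0-based), `ref`,
#'   `alt`, `label` and optionally `cds_pos` (1-based CDS nt).
#' @param cds_intervals optional 2-column matrix of 0-based half-open CDS
#'   intervals (ordered, non-overlapping).
#' @param exon_intervals optional 2-column matrix of exon intervals; required
#'   for RNA simulation.
#' @return an object of class `locus_truth`.
#' @export
locus_truth <- function(reference, haplotypes, sites = NULL,
                        cds_intervals = NULL, exon_intervals = NULL) {
  L <- nchar(reference)
  if (length(haplotypes) != 2L) stop("exactly two haplotypes required")
  if (!is.null(sites) && nrow(sites)) {
    stopifnot(all(sites$pos >= 0), all(sites$pos < L))
    if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
    ref_at <- substring(reference, sites$pos + 1L, sites$pos + 1L)
    if (!all(ref_at == sites$ref)) {
      stop("site ref allele does not match the reference sequence")
    }
    if (!is.null(cds_intervals) && !is.null(sites$cds_pos)) {
      in_cds <- vapply(sites$pos, function(p)
        any(p >= cds_intervals[, 1] & p < cds_intervals[, 2]), logical(1))
      if (!all(in_cds)) stop("sites with CDS coordinates must lie in the CDS")
    }
  }
  truth <- structure(list(reference = reference, sites = sites,
                          cds_intervals = cds_intervals,
                          exon_intervals = exon_intervals,
                          haplotypes = haplotypes),
                     class = "locus_truth")
  truth$haplotypes <- lapply(haplotypes, derive_haplotype, truth = truth)
  truth
}

# Fill in derived per-haplotype state: full sequence, hap->ref coordinate
# map, spliced mRNA (if exons annotated), CDS sequence and NMD-target flag.
derive_haplotype <- function(hap, truth) {
  L <- nchar(truth$reference)
  seq <- truth$reference
  if (length(hap$alt_sites)) {
    s <- seq_chars(seq)
    idx <- truth$sites$pos[hap$alt_sites] + 1L
    s[idx] <- truth$sites$alt[hap$alt_sites]
    seq <- paste(s, collapse = "")
  }
  refmap <- 0:(L - 1L)
  b <- NA_integer_
  ilen <- 0L
  if (!is.null(hap$insertion)) {
    b <- hap$insertion$breakpoint
    stopifnot(b >= 0, b <= L)
    ins <- hap$insertion$te$sequence
    ilen <- nchar(ins)
    seq <- paste0(substr(seq, 1L, b), ins, substr(seq, b + 1L, L))
    refmap <- c(if (b > 0) 0:(b - 1L), rep(NA_integer_, ilen),
                if (b < L) b:(L - 1L))
  }
  hap$seq <- seq
  hap$refmap <- refmap
  hap$insert_length <- ilen

  shift_iv <- function(iv) {
    if (is.null(iv)) return(NULL)
    out <- iv
    if (!is.na(b)) {
      for (i in seq_len(nrow(iv))) {
        s <- iv[i, 1]; e <- iv[i, 2]
        if (b <= s) { out[i, ] <- c(s + ilen, e + ilen) }
        else if (b < e) { out[i, 2] <- e + ilen }
      }
    }
    out
  }
  hap$exon_intervals <- shift_iv(truth$exon_intervals)
  hap$cds_intervals_hap <- shift_iv(truth$cds_intervals)

  splice <- function(iv) {
    if (is.null(iv)) return(NULL)
    paste(substring(seq, iv[, 1] + 1L, iv[, 2]), collapse = "")
  }
  hap$mrna <- splice(hap$exon_intervals)
  hap$cds_seq <- splice(hap$cds_intervals_hap)
  if (!is.null(hap$exon_intervals)) {
    hap$tx_refmap <- unlist(lapply(seq_len(nrow(hap$exon_intervals)),
      function(i) refmap[(hap$exon_intervals[i, 1] + 1L):hap$exon_intervals[i, 2]]))
  }
  hap$nmd_target <- if (!is.null(hap$cds_seq)) has_ptc(hap$cds_seq) else FALSE
  hap
}

# TRUE if the in-frame translation of `cds` hits a stop codon before its
# final codon (i.e. the transcript is a nonsense-mediated-decay target).
has_ptc <- function(cds) {
  prot <- translate_dna(cds)
  stop_at <- which(prot == "*")
  length(stop_at) > 0 && stop_at[1] < floor(nchar(cds) / 3)
}

# Translate in frame from base 1; incomplete terminal codons are dropped and
# codons containing non-ACGT characters give "X" (never a stop).
translate_dna <- function(dna) {
  n <- floor(nchar(dna) / 3)
  if (n == 0) return(character(0))
  codons <- substring(dna, 3 * (seq_len(n) - 1) + 1, 3 * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' @export
print.locus_truth <- function(x, ...) {
  cat("Ground-truth diploid locus (", nchar(x$reference), " nt)\n", sep = "")
  for (h in x$haplotypes) {
    ins <- if (h$insert_length > 0)
      sprintf(", %d-nt insertion before ref offset %d", h$insert_length,
              h$insertion$breakpoint) else ""
    cat(sprintf("  haplotype %-4s alt sites: %s%s\n", h$name,
                if (length(h$alt_sites))
                  paste(x$sites$label[h$alt_sites], collapse = "+")
                else "none", ins))
  }
  invisible(x)
}

# Default locus geometry.  An ~8-kb gene with two exons; CDS of 3,306 nt
# (1,102 codons) so that an insertion at CDS nt 2,360 (codon 787) and two
# variant sites 346 and 634 nt downstream of it all fit in the second exon.
DEFAULT_LOCUS <- list(
  length = 8000L,
  exon_intervals = rbind(c(599L, 1699L), c(2199L, 4805L)),
  cds_intervals = rbind(c(699L, 1699L), c(2199L, 4505L)),
  breakpoint_cds = 2360L,   # 1-based CDS index of first displaced base
  site_cds = c(skdr = 2706L, kdr = 2994L),
  te_parent_length = 2476L, te_tir = 109L, te_tir_mm = 5L,
  te_truncate = 400L        # inserted copy lacks its first 400 nt
)

# 1-based CDS nt -> 0-based genomic offset under a CDS interval set.
cds_to_genomic <- function(cds_nt, cds_intervals) {
  lens <- cds_intervals[, 2] - cds_intervals[, 1]
  cum <- cumsum(lens)
  i <- which(cds_nt <= cum)[1]
  prev <- if (i == 1) 0L else cum[i - 1]
  cds_intervals[i, 1] + (cds_nt - prev - 1L)
}

#' Build a ground-truth locus for a clone archetype
#'
#' Archetypes mirror the genotypes of the study clones: `"1X"` = S/S
#' (susceptible homozygote), `"4H"` = S/R (resistance heterozygote),
#' `"62H2"` and `"88H2"` = M/R (transposon-silenced wild-type allele over
#' the resistance allele), `"92H6"` = R/R. The S and R haplotypes differ at
#' two CDS variant sites (skdr and kdr analogues, 346 and 634 nt downstream
#' of the insertion breakpoint); the M haplotype carries a 5'-truncated
#' 2,076-nt transposon (109-bp imperfect TIRs on the full-length parent)
#' inserted so that its first displaced CDS base is nt 2,360.
#'
#' @param archetype one of "1X", "4H", "62H2", "88H2", "92H6".
#' @param seed integer seed controlling reference and element sequence.
#' @param insert_te optional `te_spec` overriding the default truncated
#'   element (e.g. elements of other lengths for assembly experiments).
#' @return a `locus_truth`.
#' @examples
#' truth <- build_locus("62H2", seed = 1)
#' truth
#' @export
build_locus <- function(archetype = c("62H2", "1X", "4H", "88H2", "92H6"),
                        seed = 1, insert_te = NULL) {
  archetype <- match.arg(archetype)
  d <- DEFAULT_LOCUS
  with_seed(seed, {
    ref <- seq_chars(random_dna(d$length))
    # CDS without internal stops, start/stop codons planted
    n_codon <- sum(d$cds_intervals[, 2] - d$cds_intervals[, 1]) / 3L
    all_codons <- names(Biostrings::GENETIC_CODE)
    sense <- all_codons[Biostrings::GENETIC_CODE != "*"]
    codons <- sample(sense, n_codon, replace = TRUE)
    codons[1] <- "ATG"
    codons[n_codon] <- "TAA"
    codons[d$site_cds["skdr"] / 3L] <- "ATG"  # -> ATA (Met->Ile) at alt
    codons[d$site_cds["kdr"] / 3L] <- "TTA"   # -> TTT (Leu->Phe) at alt
    cds_pos <- unlist(lapply(seq_len(nrow(d$cds_intervals)), function(i)
      (d$cds_intervals[i, 1] + 1L):d$cds_intervals[i, 2]))
    ref[cds_pos] <- unlist(strsplit(codons, "", fixed = TRUE))
    reference <- paste(ref, collapse = "")

    te <- if (!is.null(insert_te)) insert_te else
      truncate_te(make_te(d$te_parent_length, d$te_tir, d$te_tir_mm),
                  d$te_truncate)

    sites <- data.frame(
      pos = vapply(d$site_cds, cds_to_genomic, integer(1),
                   cds_intervals = d$cds_intervals),
      ref = c("G", "A"), alt = c("A", "T"),
      label = names(d$site_cds),
      cds_pos = unname(d$site_cds),
      codon = as.integer(ceiling(d$site_cds / 3)),
      stringsAsFactors = FALSE)
    rownames(sites) <- NULL

    breakpoint <- cds_to_genomic(d$breakpoint_cds, d$cds_intervals)
    hap_def <- list(
      S = list(name = "S", alt_sites = integer(0)),
      R = list(name = "R", alt_sites = 1:2),
      M = list(name = "M", alt_sites = integer(0),
               insertion = list(breakpoint = breakpoint, te = te)))
    pair <- switch(archetype,
                   "1X" = c("S", "S"), "4H" = c("S", "R"),
                   "62H2" = c("M", "R"), "88H2" = c("M", "R"),
                   "92H6" = c("R", "R"))
    truth <- locus_truth(reference, haplotypes = hap_def[pair],
                         sites = sites, cds_intervals = d$cds_intervals,
                         exon_intervals = d$exon_intervals)
    truth$archetype <- archetype
    truth$breakpoint_cds <- d$breakpoint_cds
    truth
  })
}

# Truth CIGAR from a per-base reference map (0-based ref offset per query
# base, NA for bases absent from the reference).  When anchored blocks are
# separated by absent sequence, the longest block is kept and the remainder
# soft-clipped, as a local aligner would report it; jumps inside the kept
# block become N (spliced) ops.  Blocks shorter than `min_anchor` are
# treated as unmappable.
cigar_from_refmap <- function(v, min_anchor = 20L) {
  n <- length(v)
  ok <- !is.na(v)
  if (!any(ok)) return(list(pos = NA_integer_, cigar = NA_character_))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  s <- starts[best]; e <- ends[best]
  if (r$lengths[best] < min_anchor) {
    return(list(pos = NA_integer_, cigar = NA_character_))
  }
  vals <- v[s:e]
  d <- diff(vals)
  if (any(d < 1)) stop("non-monotone reference map")
  parts <- character(0)
  if (s > 1L) parts <- c(parts, paste0(s - 1L, "S"))
  jump_at <- which(d > 1L)
  block_start <- 1L
  for (j in c(jump_at, length(vals))) {
    parts <- c(parts, paste0(j - block_start + 1L, "M"))
    if (j < length(vals)) {
      parts <- c(parts, paste0(d[j] - 1L, "N"))
      block_start <- j + 1L
    }
  }
  if (e < n) parts <- c(parts, paste0(n - e, "S"))
  list(pos = vals[1] + 1L, cigar = paste(parts, collapse = ""))
}

#' Simulate paired-end reads with analytic truth alignments
#'
#' DNA mode draws fragments uniformly from the two haplotypes with equal
#' probability; RNA mode draws from the spliced transcripts, down-weighting
#' any transcript carrying a premature termination codon to relative
#' abundance `nmd_retention` (the NMD model). Truth alignments against the
#' reference are computed analytically: read bases falling inside an
#' insertion absent from the reference are soft-clipped, intron gaps become
#' N ops, and reads without a >= 20 nt anchor are emitted unmapped.
#'
#' @param truth a `locus_truth`.
#' @param mode `"dna"` or `"rna"` (RNA requires exon annotation).
#' @param coverage mean diploid fold coverage: the pair count is
#'   `round(coverage * L / (2 * read_length))` with `L` the mean haplotype
#'   length (DNA; equal to the locus length in the absence of insertions)
#'   or the reference transcript length (RNA), so each haplotype base —
#'   inserted sequence included — is covered at `coverage / 2`.
#' @param read_length read length in nt.
#' @param fragment_mean,fragment_sd fragment length distribution (nt).
#' @param error_rate per-base substitution error rate.
#' @param nmd_retention relative abundance of PTC-bearing transcripts
#'   (RNA mode), in `[0, 1]`.
#' @param seed integer seed; identical seed and configuration give
#'   byte-identical FASTQ/SAM output.
#' @return an object of class `sim_reads`; see [write_fastq()], [write_sam()]
#'   and `sim_alignments` for consumers.
#' @examples
#' truth <- build_locus("62H2", seed = 1)
#' sim <- simulate_reads(truth, "dna", coverage = 5, seed = 1)
#' nrow(sim$reads)
#' @export
simulate_reads <- function(truth, mode = c("dna", "rna"), coverage = 40,
                           read_length = 150L, fragment_mean = 400,
                           fragment_sd = 50, error_rate = 0,
                           nmd_retention = 0.05, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "locus_truth"), coverage > 0)
  if (fragment_mean < read_length) stop("fragment shorter than read length")
  if (mode == "rna") {
    if (is.null(truth$exon_intervals)) stop("RNA mode requires exon intervals")
    if (nmd_retention < 0 || nmd_retention > 1) {
      stop("nmd_retention must be in [0, 1]")
    }
  }

  haps <- truth$haplotypes
  if (mode == "dna") {
    templates <- lapply(haps, `[[`, "seq")
    maps <- lapply(haps, `[[`, "refmap")
    tlen <- vapply(templates, nchar, integer(1))
    # uniform fragment sampling across the diploid: fragments per haplotype
    # proportional to its length, so per-base depth is allele balanced and
    # every haplotype base (insertions included) sees coverage/2
    w <- as.numeric(tlen)
    base_len <- mean(tlen)
  } else {
    templates <- lapply(haps, `[[`, "mrna")
    maps <- lapply(haps, `[[`, "tx_refmap")
    tlen <- vapply(templates, nchar, integer(1))
    # per-site read depth must scale with transcript abundance, so pair
    # counts scale with abundance x transcript length
    abund <- vapply(haps, function(h) if (h$nmd_target) nmd_retention else 1,
                    numeric(1))
    if (sum(abund) == 0) stop("all transcripts fully degraded")
    w <- abund * tlen
    base_len <- sum(truth$exon_intervals[, 2] - truth$exon_intervals[, 1])
  }
  n_pairs <- round(coverage * base_len / (2 * read_length))

  with_seed(seed, {
    hap_idx <- sample.int(2L, n_pairs, replace = TRUE, prob = w / sum(w))
    fl <- pmax(read_length, round(stats::rnorm(n_pairs, fragment_mean,
                                               fragment_sd)))
    fl <- pmin(fl, tlen[hap_idx])
    start <- floor(stats::runif(n_pairs) * (tlen[hap_idx] - fl + 1)) + 1L

    qname <- sprintf("r%06d", seq_len(n_pairs))
    r1_s <- start
    r2_s <- start + fl - read_length
    seq1 <- substring(unlist(templates)[hap_idx], r1_s, r1_s + read_length - 1L)
    seq2 <- substring(unlist(templates)[hap_idx], r2_s, r2_s + read_length - 1L)
    if (error_rate > 0) {
      seq1 <- add_errors(seq1, error_rate)
      seq2 <- add_errors(seq2, error_rate)
    }

    aln <- function(starts) {
      out_pos <- integer(n_pairs); out_cig <- character(n_pairs)
      for (i in seq_len(n_pairs)) {
        sl <- maps[[hap_idx[i]]][starts[i]:(starts[i] + read_length - 1L)]
        if (!anyNA(sl) && sl[read_length] - sl[1] == read_length - 1L) {
          out_pos[i] <- sl[1] + 1L
          out_cig[i] <- paste0(read_length, "M")
        } else {
          cg <- cigar_from_refmap(sl)
          out_pos[i] <- cg$pos
          out_cig[i] <- cg$cigar
        }
      }
      list(pos = out_pos, cigar = out_cig)
    }
    a1 <- aln(r1_s)
    a2 <- aln(r2_s)

    flag1 <- ifelse(is.na(a1$pos), 69L, 99L) + ifelse(is.na(a2$pos), 8L, 0L)
    flag2 <- ifelse(is.na(a2$pos), 133L, 147L) + ifelse(is.na(a1$pos), 8L, 0L)
    qual <- strrep("F", read_length)

    reads <- data.frame(
      qname = rep(qname, 2L), mate = rep(1:2, each = n_pairs),
      hap = rep(vapply(haps, `[[`, character(1), "name")[hap_idx], 2L),
      tstart = c(r1_s, r2_s),
      seq_plus = c(seq1, seq2), qual = qual,
      flag = c(flag1, flag2), pos = c(a1$pos, a2$pos),
      cigar = c(a1$cigar, a2$cigar), stringsAsFactors = FALSE)
    structure(list(reads = reads, mode = mode, rname = "locus",
                   ref_length = nchar(truth$reference),
                   read_length = read_length, coverage = coverage,
                   seed = seed),
              class = "sim_reads")
  })
}

# Uniform substitution errors at the given per-base rate.
add_errors <- function(seqs, rate) {
  n <- nchar(seqs[1])
  k <- length(seqs)
  hit <- which(stats::runif(n * k) < rate)
  if (!length(hit)) return(seqs)
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = n)
  mat[hit] <- vapply(mat[hit], function(b)
    sample(setdiff(DNA_BASES, b), 1L), character(1))
  apply(mat, 2, paste, collapse = "")
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("Simulated %s reads: %d pairs of %d nt (coverage %g, seed %d)\n",
              toupper(x$mode), nrow(x$reads) / 2L, x$read_length,
              x$coverage, x$seed))
  invisible(x)
}

#' Write the full ground truth of a simulation to disk
#'
#' Emits the locus FASTA, a read-truth TSV (read name, haplotype, template
#' start) and a JSON serialisation of the locus definition.
#'
#' @param truth a `locus_truth`.
#' @param sim a `sim_reads` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_truth <- function(truth, sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(c(locus = truth$reference), file.path(dir, "locus.fa"))
  utils::write.table(sim$reads[, c("qname", "mate", "hap", "tstart")],
                     file.path(dir, "read_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  js <- list(
    reference_length = nchar(truth$reference),
    cds_intervals = truth$cds_intervals,
    exon_intervals = truth$exon_intervals,
    sites = truth$sites,
    haplotypes = lapply(truth$haplotypes, function(h)
      list(name = h$name, alt_sites = h$alt_sites,
           insertion_breakpoint = if (h$insert_length > 0)
             h$insertion$breakpoint else NULL,
           insert_length = h$insert_length, nmd_target = h$nmd_target)))
  jsonlite::write_json(js, file.path(dir, "locus.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
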