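# Coding consequence of an intragenic insertion: first disrupted codon,
# premature termination codons (PTCs), truncated protein length and a
# nonsense-mediated decay (NMD) flag.
#
# Coordinate convention: `position` is the 1-based index of the first CDS
# base displaced rightward by the insertion, so an insertion at CDS nt
# 2,360 disrupts codon ceiling(2360/3) = 787.

#' Insert a sequence into a CDS
#'
#' @param cds coding sequence (length divisible by 3).
#' @param position 1-based index of the first displaced CDS base; may be
#'   `nchar(cds) + 1` for a pure append.
#' @param insert inserted sequence.
#' @return the modified CDS.
#' @examples
#' apply_insertion("ATGAAATAG", 4, "CCC")
#' @export
apply_insertion <- function(cds, position, insert) {
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length must be divisible by 3")
  if (position < 1 || position > n + 1) stop("insertion position out of range")
  paste0(substr(cds, 1L, position - 1L), insert, substr(cds, position, n))
}

#' Annotate the reading-frame impact of an insertion
#'
#' Translates the modified CDS in frame from codon 1 and reports the first
#' disrupted codon (`ceiling(position / 3)`), the first stop codon, whether
#' the original frame is restored downstream (`insert_length` divisible by
#' 3), the truncated protein length, and whether the transcript is an NMD
#' target (a stop before the transcript's final complete codon).
#' Ambiguity codes translate to `X` and never count as stop.
#'
#' @param modified_cds CDS with the insertion applied (see
#'   [apply_insertion()]).
#' @param insertion_position 1-based first displaced base of the original
#'   CDS.
#' @param insert_length length of the inserted sequence, nt.
#' @return a `frame_impact`: list with `insertion_cds_position`,
#'   `first_disrupted_codon`, `first_ptc_codon` (`NA` if none),
#'   `frame_restored_downstream`, `truncated_protein_length` (`NA` if no
#'   PTC), `nmd_target`.
#' @examples
#' cds <- paste(c("ATG", rep("GCT", 1000), "TAA"), collapse = "")
#' mod <- apply_insertion(cds, 2360, strrep("C", 2076))
#' annotate_impact(mod, 2360, 2076)$first_disrupted_codon
#' @export
annotate_impact <- function(modified_cds, insertion_position, insert_length) {
  orig <- paste0(substr(modified_cds, 1L, insertion_position - 1L),
                 substr(modified_cds, insertion_position + insert_length,
                        nchar(modified_cds)))
  if (substr(orig, 1L, 3L) != "ATG") stop("original CDS lacks a start codon")
  if (nchar(orig) %% 3 != 0) stop("original CDS length not divisible by 3")
  last_codon <- translate_dna(substr(orig, nchar(orig) - 2L, nchar(orig)))
  if (!identical(last_codon, "*")) stop("original CDS lacks a stop codon")

  prot <- translate_dna(modified_cds)
  stops <- which(prot == "*")
  final_codon <- floor(nchar(modified_cds) / 3)
  ptc <- stops[stops < final_codon]
  first_ptc <- if (length(ptc)) ptc[1] else NA_integer_
  structure(list(
    insertion_cds_position = insertion_position,
    first_disrupted_codon = as.integer(ceiling(insertion_position / 3)),
    first_ptc_codon = first_ptc,
    frame_restored_downstream = insert_length %% 3 == 0,
    truncated_protein_length = if (is.na(first_ptc)) NA_integer_
                               else first_ptc - 1L,
    nmd_target = !is.na(first_ptc)), class = "frame_impact")
}

#' @export
print.frame_impact <- function(x, ...) {
  cat(sprintf("Insertion at CDS nt %d: first disrupted codon %d\n",
              x$insertion_cds_position, x$first_disrupted_codon))
  if (x$nmd_target) {
    cat(sprintf(
      "  first premature stop at codon %d (truncated protein: %d aa); NMD target\n",
      x$first_ptc_codon, x$truncated_protein_length))
  } else {
    cat("  no premature stop codon; not an NMD target\n")
  }
  cat(sprintf("  reading frame %s downstream of the insert\n",
              if (x$frame_restored_downstream) "restored" else "shifted"))
  invisible(x)
}
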