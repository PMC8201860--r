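# Structural annotation of a reconstructed insert as a DNA transposon:
# terminal inverted repeats (TIRs), identity against a library of full-length
# elements, and truncation classification.

#' Find terminal inverted repeats
#'
#' Tests whether the reverse complement of the element's 3' terminus matches
#' its 5' terminus. TIRs are anchored at the element's ends (where DNA
#' transposon TIRs sit); the reported hit is the longest length `L` in
#' `[min_length, search_window]` such that (i) the innermost base pair
#' matches, (ii) the overall mismatch fraction is at most
#' `max_mismatch_fraction`, and (iii) the innermost `boundary_window` pairs
#' contain at most `boundary_mismatches` mismatches — the local condition
#' stops the repeat at its true boundary instead of drifting into flanking
#' sequence while the global budget lasts. Substitutions only: the
#' comparison is position-wise, without indels.
#'
#' @param element element sequence.
#' @param min_length minimum TIR length to report, nt.
#' @param max_mismatch_fraction maximum fraction of mismatched positions.
#' @param search_window how far from each end to search, nt.
#' @param boundary_window,boundary_mismatches local identity condition at
#'   the repeat's inner boundary (see above).
#' @return a `tir_hit` (fields `length`, `mismatches`, `identity`,
#'   `left_interval`, `right_interval`, both 0-based half-open on the
#'   element) or `NULL` when no terminal repeat qualifies.
#' @examples
#' te <- make_te(300, 50, 0, seed = 7)
#' find_tirs(te$sequence)
#' @export
find_tirs <- function(element, min_length = 15L, max_mismatch_fraction = 0.1,
                      search_window = 300L, boundary_window = 12L,
                      boundary_mismatches = 2L) {
  n <- nchar(element)
  if (n < 2L * min_length) stop("element shorter than twice min_length")
  w <- min(search_window, n %/% 2L)
  pre <- seq_chars(substr(element, 1L, w))
  sufrc <- seq_chars(revcomp(substr(element, n - w + 1L, n)))
  mism <- pre != sufrc
  mm <- cumsum(mism)           # mismatches over lengths 1..w
  len <- seq_len(w)
  win_lo <- pmax(len - boundary_window + 1L, 1L)
  win_mm <- mm - c(0L, mm)[win_lo]   # mismatches in the innermost window
  cand <- which(len >= min_length & !mism &
                  mm <= max_mismatch_fraction * len &
                  win_mm <= boundary_mismatches)
  if (!length(cand)) return(NULL)
  L <- max(cand)
  structure(list(length = L, mismatches = as.integer(mm[L]),
                 identity = 1 - mm[L] / L,
                 left_interval = c(0L, L),
                 right_interval = c(n - L, n)),
            class = "tir_hit")
}

#' @export
print.tir_hit <- function(x, ...) {
  cat(sprintf("TIR: %d nt, %d mismatch(es), identity %.3f\n",
              x$length, x$mismatches, x$identity))
  invisible(x)
}

#' Compare an element against a library of full-length elements
#'
#' Aligns the element to each library entry with an ends-free (overlap)
#' pairwise alignment and reports percent identity over the aligned span.
#' The element is classified 5'-truncated when it aligns essentially in
#' full as a suffix of a longer library entry at or above `min_identity`,
#' with `bases_missing` equal to the unaligned library prefix; 3'
#' truncation is the mirror case.
#'
#' @param element element sequence.
#' @param library named character vector of library sequences.
#' @param min_identity minimum identity (fraction) for a reportable match.
#' @param end_slack nt of slack allowed at aligned ends when classifying
#'   truncation.
#' @return a `te_annotation`: list with `element_length`, `tir`
#'   (from [find_tirs()]), `matches` (data.frame: name, identity (%),
#'   element/library spans), `best` and `truncation`
#'   (`list(end = "5p"|"3p"|"none", bases_missing)`).
#' @export
compare_to_library <- function(element, library, min_identity = 0.9,
                               end_slack = 5L) {
  if (length(library) == 0L) stop("empty element library")
  if (is.null(names(library))) {
    names(library) <- paste0("lib", seq_along(library))
  }
  el <- Biostrings::DNAString(element)
  rows <- lapply(names(library), function(nm) {
    aln <- Biostrings::pairwiseAlignment(
      el, Biostrings::DNAString(library[[nm]]), type = "overlap",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3),
      gapOpening = 5, gapExtension = 2)
    p <- Biostrings::pattern(aln)
    s <- Biostrings::subject(aln)
    data.frame(name = nm,
               identity = Biostrings::pid(aln),
               element_start = Biostrings::start(p),
               element_end = Biostrings::end(p),
               library_start = Biostrings::start(s),
               library_end = Biostrings::end(s),
               library_length = nchar(library[[nm]]),
               stringsAsFactors = FALSE)
  })
  matches <- do.call(rbind, rows)
  matches <- matches[order(-matches$identity), ]
  rownames(matches) <- NULL
  best <- matches[1, ]
  truncation <- list(end = "none", bases_missing = 0L)
  n <- nchar(element)
  if (best$identity >= 100 * min_identity) {
    el_full <- best$element_start <= end_slack &&
      best$element_end >= n - end_slack
    miss_5p <- best$library_start - 1L
    miss_3p <- best$library_length - best$library_end
    if (el_full && miss_5p > end_slack && miss_3p <= end_slack) {
      truncation <- list(end = "5p", bases_missing = miss_5p)
    } else if (el_full && miss_3p > end_slack && miss_5p <= end_slack) {
      truncation <- list(end = "3p", bases_missing = miss_3p)
    }
  }
  structure(list(element_length = n,
                 tir = tryCatch(find_tirs(element), error = function(e) NULL),
                 matches = matches, best = best, truncation = truncation),
            class = "te_annotation")
}

#' @export
print.te_annotation <- function(x, ...) {
  cat(sprintf("Element: %d nt\n", x$element_length))
  if (is.null(x$tir)) cat("  TIR: none detected\n") else
    cat(sprintf("  TIR: %d nt with %d mismatch(es)\n",
                x$tir$length, x$tir$mismatches))
  cat(sprintf("  best library match: %s at %.1f%% identity\n",
              x$best$name, x$best$identity))
  if (x$truncation$end == "none") cat("  truncation: none\n") else
    cat(sprintf("  truncation: %s, %d bases missing\n",
                x$truncation$end, x$truncation$bases_missing))
  invisible(x)
}

#' Write a TE annotation as JSON and TSV
#'
#' @param ann a `te_annotation`.
#' @param json_path,tsv_path output paths (`NULL` to skip either).
#' @return invisibly, `ann`.
#' @export
write_te_annotation <- function(ann, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    js <- list(element_length = ann$element_length,
               tir = if (is.null(ann$tir)) NULL else
                 ann$tir[c("length", "mismatches", "identity")],
               truncation = ann$truncation,
               matches = ann$matches)
    jsonlite::write_json(js, json_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(ann$matches, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(ann)
}
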