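# Targeted reconstruction of an inserted sequence by iterative seed
# extension, the in-silico analogue of repeatedly remapping raw reads to a
# growing contig at highest stringency until the two flanks of the
# insertion meet.
#
# Each round recruits reads (in either orientation) containing the contig's
# terminal k-mer with at most `max_mismatch` substitutions and extends the
# contig by the strict-majority consensus of the recruited overhangs; an
# exact tie between bases aborts extension at that column, favouring a
# truncated contig over a chimeric one.

#' Iteratively extend a seed sequence against raw reads
#'
#' @param seed seed sequence; must be at least `k_overlap` nt.
#' @param reads character vector (or `DNAStringSet`) of raw reads; both the
#'   read and its reverse complement are candidates each round.
#' @param direction `"right"` or `"left"` (leftward extension is performed
#'   on the reverse complement internally).
#' @param k_overlap anchor length: reads must contain the contig's terminal
#'   `k_overlap` bases.
#' @param max_mismatch substitutions tolerated in the anchor match.
#' @param min_reads minimum overhang depth per extended column.
#' @param max_rounds round cap; hitting it with extension still ongoing
#'   flags the contig `"incomplete"` rather than erroring.
#' @return an `extension_contig`: list with `sequence`, `direction`,
#'   `rounds`, `ext_lengths`, `support`, `status`
#'   (`"exhausted"` = no further extension possible, `"incomplete"` = round
#'   cap hit while still growing).
#' @examples
#' reads <- c("ACGTACGTACGTACGTAAATTTCCC")
#' ctg <- iterative_extend("ACGTACGTACGTACGT", reads, "right",
#'                         k_overlap = 8, min_reads = 1)
#' ctg$sequence
#' @export
iterative_extend <- function(seed, reads, direction = c("right", "left"),
                             k_overlap = 31L, max_mismatch = 1L,
                             min_reads = 3L, max_rounds = 100L) {
  direction <- match.arg(direction)
  if (nchar(seed) < k_overlap) stop("seed shorter than k_overlap")
  pool <- read_pool(reads)
  contig <- if (direction == "left") revcomp(seed) else seed
  rounds <- 0L
  ext_lengths <- integer(0)
  support <- integer(0)
  status <- "exhausted"
  while (rounds < max_rounds) {
    step <- extend_once(contig, pool, k_overlap, max_mismatch, min_reads)
    if (step$extension == 0L) break
    contig <- step$contig
    rounds <- rounds + 1L
    ext_lengths <- c(ext_lengths, step$extension)
    support <- c(support, step$n_reads)
    if (rounds == max_rounds) status <- "incomplete"
  }
  structure(list(
    sequence = if (direction == "left") revcomp(contig) else contig,
    direction = direction, rounds = rounds, ext_lengths = ext_lengths,
    support = support, status = status), class = "extension_contig")
}

# Both-orientation read pool as a DNAStringSet (built once per assembly).
read_pool <- function(reads) {
  if (inherits(reads, "DNAStringSet")) reads <- as.character(reads)
  reads <- unname(reads)
  Biostrings::DNAStringSet(c(reads, revcomp(reads)))
}

# One rightward extension round: anchor = terminal k-mer of the contig;
# overhangs = read suffixes following an anchor match.
extend_once <- function(contig, pool, k, max_mismatch, min_reads) {
  anchor <- substr(contig, nchar(contig) - k + 1L, nchar(contig))
  hits <- Biostrings::vmatchPattern(anchor, pool,
                                    max.mismatch = max_mismatch, fixed = TRUE)
  starts <- Biostrings::startIndex(hits)
  widths <- Biostrings::width(pool)
  overhangs <- character(0)
  for (i in which(lengths(starts) > 0)) {
    for (s in starts[[i]]) {
      if (s < 1L) next
      from <- s + k
      if (from <= widths[i]) {
        overhangs <- c(overhangs,
                       as.character(Biostrings::subseq(pool[i], from)))
      }
    }
  }
  if (length(overhangs) < min_reads) {
    return(list(contig = contig, extension = 0L, n_reads = length(overhangs)))
  }
  ext <- majority_extension(overhangs, min_reads)
  list(contig = paste0(contig, ext), extension = nchar(ext),
       n_reads = length(overhangs))
}

# Column-wise strict-majority consensus over ragged overhangs; stops at the
# first column whose depth drops below min_reads or whose top bases tie.
majority_extension <- function(overhangs, min_reads) {
  w <- max(nchar(overhangs))
  mat <- matrix(NA_character_, nrow = length(overhangs), ncol = w)
  for (i in seq_along(overhangs)) {
    s <- seq_chars(overhangs[i])
    mat[i, seq_along(s)] <- s
  }
  out <- character(0)
  for (j in seq_len(w)) {
    col <- mat[, j]
    col <- col[!is.na(col)]
    if (length(col) < min_reads) break
    tb <- sort(table(col), decreasing = TRUE)
    if (length(tb) > 1 && tb[1] == tb[2]) break  # exact tie: do not guess
    out <- c(out, names(tb)[1])
  }
  paste(out, collapse = "")
}

# Best co-linear placement of `right_ctg` starting at or after position 1
# of `left_ctg`.  Candidate offsets come from exact matches of two
# pigeonhole seed halves of right_ctg's prefix (any overlap with <=
# max_mismatch substitutions contains an exact copy of one half), each
# verified base by base.  Returns NULL or list(offset, overlap, mismatches).
overlap_placement <- function(left_ctg, right_ctg, min_overlap = 40L,
                              max_mismatch = 1L) {
  seed_len <- max(10L, min_overlap %/% 4L)
  lraw <- charToRaw(left_ctg); rraw <- charToRaw(right_ctg)
  nl <- length(lraw); nr <- length(rraw)
  offsets <- integer(0)
  for (piece in 1:2) {
    from <- (piece - 1L) * seed_len + 1L
    seedseq <- substr(right_ctg, from, from + seed_len - 1L)
    if (nchar(seedseq) < seed_len) next
    m <- gregexpr(seedseq, left_ctg, fixed = TRUE)[[1]]
    if (m[1] != -1L) offsets <- c(offsets, as.integer(m) - from + 1L)
  }
  offsets <- sort(unique(offsets[offsets >= 1L]))
  best <- NULL
  for (off in offsets) {  # right_ctg[1] sits at left_ctg position `off`
    ov <- min(nl - off + 1L, nr)
    if (ov < min_overlap) next
    mm <- sum(lraw[off:(off + ov - 1L)] != rraw[1:ov])
    if (mm > max_mismatch) next
    if (is.null(best) || ov > best$overlap) {
      best <- list(offset = off, overlap = ov, mismatches = mm)
    }
  }
  best
}

#' Reconstruct an inserted sequence from an insertion call and raw reads
#'
#' Extends the right-cluster tail consensus (which begins at the insert's
#' first base) rightward and the left-cluster tail consensus (which ends at
#' the insert's last base) leftward, one round each per iteration, testing
#' after every iteration for an exact-or-near overlap between the two
#' contigs. Because the two seeds anchor the insert's termini exactly, the
#' reported sequence is the span from the 5' contig's first base to the 3'
#' contig's last base: reference flank bases recruited during extension
#' fall outside that span and are dropped (a target-site duplication, were
#' one present, would survive inside the span and remain visible).
#'
#' @param call one row of an `insertion_calls` data.frame.
#' @param reads character vector of raw reads (e.g. from [read_fastq()]).
#' @param k_overlap,max_mismatch,min_reads,max_rounds see
#'   [iterative_extend()].
#' @param min_merge_overlap,merge_mismatch overlap length and mismatch
#'   tolerance for merging the two contigs.
#' @return an `insertion_sequence`: list with `sequence`, `length`,
#'   `breakpoint`, `status` (`"merged"` or `"unmerged"`), `rounds` (left,
#'   right), `overlap`, `overlap_mismatches`, and on failure the two
#'   contigs as `contig_5p` / `contig_3p`.
#' @export
assemble_insertion <- function(call, reads,
                               k_overlap = 31L, max_mismatch = 1L,
                               min_reads = 3L, max_rounds = 100L,
                               min_merge_overlap = 40L, merge_mismatch = 1L) {
  if (is.data.frame(call)) {
    stopifnot(nrow(call) == 1L)
    call <- as.list(call)
  }
  # each tail consensus is anchored at one end only; truncate at the first
  # masked (N) column so the seed stays exact for k-mer recruitment
  seed5 <- sub("N.*$", "", call$consensus_5p)
  seed3 <- sub("^.*N", "", call$consensus_3p)
  if (nchar(seed5) < k_overlap || nchar(seed3) < k_overlap) {
    stop("tail consensus shorter than k_overlap; lower k_overlap")
  }
  pool <- read_pool(reads)
  ctg5 <- seed5   # grows rightward into the insert; starts at insert[1]
  ctg3 <- seed3   # grows leftward; ends at insert[length]
  rounds5 <- 0L; rounds3 <- 0L
  done5 <- FALSE; done3 <- FALSE
  repeat {
    ins <- extract_insert(ctg5, ctg3, min_merge_overlap, merge_mismatch)
    if (!is.null(ins)) break
    if ((done5 && done3) || (rounds5 + rounds3) >= 2L * max_rounds) break
    if (!done5) {
      st <- extend_once(ctg5, pool, k_overlap, max_mismatch, min_reads)
      if (st$extension == 0L) done5 <- TRUE
      else { ctg5 <- st$contig; rounds5 <- rounds5 + 1L }
    }
    if (!done3) {
      rc <- revcomp(ctg3)
      st <- extend_once(rc, pool, k_overlap, max_mismatch, min_reads)
      if (st$extension == 0L) done3 <- TRUE
      else { ctg3 <- revcomp(st$contig); rounds3 <- rounds3 + 1L }
    }
  }
  if (is.null(ins)) {
    return(structure(list(sequence = NA_character_, length = NA_integer_,
                          breakpoint = call$breakpoint, status = "unmerged",
                          rounds = c(left = rounds3, right = rounds5),
                          contig_5p = ctg5, contig_3p = ctg3),
                     class = "insertion_sequence"))
  }
  structure(list(sequence = ins$sequence, length = nchar(ins$sequence),
                 breakpoint = call$breakpoint, status = "merged",
                 rounds = c(left = rounds3, right = rounds5),
                 overlap = ins$overlap,
                 overlap_mismatches = ins$mismatches),
            class = "insertion_sequence")
}

# Given the 5'-anchored and 3'-anchored contigs, find their co-linear
# placement (either contig may extend past the other on both sides) and
# return the sequence between the insert's two anchored termini.
extract_insert <- function(ctg5, ctg3, min_overlap, max_mismatch) {
  # usual case: ctg3 starts inside (or right of start of) ctg5
  pl <- overlap_placement(ctg5, ctg3, min_overlap, max_mismatch)
  if (!is.null(pl)) {
    seqn <- paste0(substr(ctg5, 1L, pl$offset - 1L), ctg3)
    return(list(sequence = seqn, overlap = pl$overlap,
                mismatches = pl$mismatches))
  }
  # short-insert case: ctg3 (clipped flank + insert) starts left of ctg5
  pl <- overlap_placement(ctg3, ctg5, min_overlap, max_mismatch)
  if (!is.null(pl)) {
    # insert runs from ctg5's first base to ctg3's last base
    seqn <- substr(ctg3, pl$offset, nchar(ctg3))
    return(list(sequence = seqn, overlap = pl$overlap,
                mismatches = pl$mismatches))
  }
  NULL
}

#' @export
print.insertion_sequence <- function(x, ...) {
  if (x$status == "merged") {
    cat(sprintf(
      "Reconstructed insertion: %d nt at breakpoint %d (1-based: after nucleotide %d); rounds L=%d R=%d, merge overlap %d (%d mm)\n",
      x$length, x$breakpoint, x$breakpoint, x$rounds["left"],
      x$rounds["right"], x$overlap, x$overlap_mismatches))
  } else {
    cat(sprintf(
      "Unmerged insertion contigs (5': %d nt, 3': %d nt) at breakpoint %d\n",
      nchar(x$contig_5p), nchar(x$contig_3p), x$breakpoint))
  }
  invisible(x)
}

#' Write a reconstructed insertion to FASTA
#'
#' The header records breakpoint (1-based "after nucleotide" convention),
#' length and extension rounds.
#'
#' @param ins an `insertion_sequence`.
#' @param fasta_path output FASTA.
#' @return invisibly, `fasta_path`.
#' @export
write_insertion <- function(ins, fasta_path) {
  stopifnot(inherits(ins, "insertion_sequence"), ins$status == "merged")
  seqs <- ins$sequence
  names(seqs) <- sprintf("insertion_after%d_len%d_rounds%dL%dR",
                         ins$breakpoint, ins$length,
                         ins$rounds["left"], ins$rounds["right"])
  write_fasta(seqs, fasta_path)
}
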