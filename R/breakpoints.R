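# Detection of candidate insertion breakpoints from soft-clipped alignments.
#
# A non-reference insertion leaves two signatures in a pileup: reads whose
# 3' ends are clipped at the breakpoint (their tails are the insert's 5'
# start) and reads whose 5' ends are clipped there (tails = the insert's 3'
# end).  Clips are clustered by position and side, a per-column majority
# consensus is built from the tails, and left/right clusters are paired into
# insertion calls with an allele-fraction-based zygosity estimate.

#' Cluster soft-clipped read ends
#'
#' Scans primary mapped alignments for terminal soft clips of at least
#' `min_clip_length` nt and clusters them by clip position and side.
#' `side = "right"` denotes tail clips (clip point at the end of the aligned
#' segment; tails read into the insertion's 5' end), `side = "left"` head
#' clips (clip point at the alignment start; tails are the insertion's 3'
#' end). Positions within `merge_window` nt are merged into one cluster at
#' the modal position. Consensus columns whose majority base falls below
#' `min_base_agreement` are masked as N.
#'
#' @param alignments data.frame as returned by [read_sam()], sorted by
#'   position.
#' @param min_clip_length minimum clip length in nt to count as evidence.
#' @param min_base_agreement minimum per-column agreement fraction for the
#'   tail consensus.
#' @param merge_window positional slack for clustering, in nt.
#' @return list of `clip_cluster` objects (fields: position (0-based clip
#'   point), side, reads, tails, consensus, n_skipped attribute on the list).
#' @export
collect_clips <- function(alignments, min_clip_length = 20L,
                          min_base_agreement = 0.7, merge_window = 5L) {
  stopifnot(min_clip_length >= 1L)
  a <- alignments
  mapped <- !bitwAnd(a$flag, 4L) & !bitwAnd(a$flag, 256L) &
    !bitwAnd(a$flag, 2048L)
  n_skipped <- sum(!mapped)
  a <- a[mapped, , drop = FALSE]
  if (nrow(a) && is.unsorted(a$pos)) {
    stop("alignments must be sorted by reference position")
  }

  pos <- integer(0); side <- character(0)
  qname <- character(0); tail <- character(0)
  for (i in seq_len(nrow(a))) {
    ops <- cigar_ops(a$cigar[i])
    k <- length(ops$op)
    if (k == 0L) next
    qlen <- nchar(a$seq[i])
    if (ops$op[1] == "S" && ops$len[1] >= min_clip_length) {
      pos <- c(pos, a$pos[i] - 1L)          # 0-based clip point
      side <- c(side, "left")
      qname <- c(qname, a$qname[i])
      tail <- c(tail, substr(a$seq[i], 1L, ops$len[1]))
    }
    if (ops$op[k] == "S" && ops$len[k] >= min_clip_length) {
      ref_end <- a$pos[i] - 1L +
        sum(ops$len[ops$op %in% c("M", "D", "N", "=", "X")])
      pos <- c(pos, ref_end)                # 0-based first clipped ref offset
      side <- c(side, "right")
      qname <- c(qname, a$qname[i])
      tail <- c(tail, substr(a$seq[i], qlen - ops$len[k] + 1L, qlen))
    }
  }

  clusters <- list()
  for (sd in c("right", "left")) {
    sel <- which(side == sd)
    if (!length(sel)) next
    p <- pos[sel]
    o <- order(p)
    grp <- cumsum(c(1L, diff(p[o]) > merge_window))
    for (g in unique(grp)) {
      idx <- sel[o[grp == g]]
      # duplicate read names count once per side
      idx <- idx[!duplicated(qname[idx])]
      cpos <- as.integer(names(which.max(table(pos[idx]))))
      tails <- tail[idx]
      # left-side tails end at the clip point: align on their right edge
      cons <- tail_consensus(tails, from_right = (sd == "left"),
                             min_base_agreement)
      clusters[[length(clusters) + 1L]] <- structure(
        list(position = cpos, side = sd, reads = qname[idx],
             tails = tails, consensus = cons),
        class = "clip_cluster")
    }
  }
  attr(clusters, "n_skipped") <- n_skipped
  clusters
}

# Majority consensus over variable-length tails. Right-side tails share
# their first base (clip point at their left edge); left-side tails share
# their last base, so they are aligned from the right.
tail_consensus <- function(tails, from_right, min_base_agreement) {
  w <- max(nchar(tails))
  mat <- matrix(NA_character_, nrow = length(tails), ncol = w)
  for (i in seq_along(tails)) {
    s <- seq_chars(tails[i])
    if (from_right) mat[i, (w - length(s) + 1L):w] <- s
    else mat[i, seq_along(s)] <- s
  }
  cons <- apply(mat, 2, function(col) {
    col <- col[!is.na(col)]
    tb <- sort(table(col), decreasing = TRUE)
    top <- tb[1] / length(col)
    if (length(tb) > 1 && tb[1] == tb[2]) return("N")  # exact tie
    if (top >= min_base_agreement) names(tb)[1] else "N"
  })
  paste(cons, collapse = "")
}

#' Pair clip clusters into insertion calls
#'
#' A right-side (tail-clip) cluster and a left-side (head-clip) cluster
#' whose positions agree within `merge_window` are paired into a single
#' insertion call. The insertion allele fraction compares clipped against
#' unclipped breakpoint-spanning fragments; because a long insertion exposes
#' two clip junctions at the same reference breakpoint, clipped support
#' enters as the per-side mean, and unclipped fragments must span the
#' breakpoint with at least `min_clip_length` aligned nt on each side so
#' that the clipped and unclipped capture windows are the same width —
#' this makes the estimator unbiased (expectation 0.5) for a heterozygous
#' insertion. Zygosity is called heterozygous inside `het_band`, homozygous
#' above it, ambiguous below.
#'
#' @param clusters output of [collect_clips()].
#' @param alignments the same alignment data.frame (needed to count
#'   unclipped spanning reads).
#' @param min_support minimum clipped reads supporting a call.
#' @param merge_window maximum left/right cluster distance, nt.
#' @param het_band numeric length-2: allele-fraction band called het.
#' @param min_clip_length the clip-length threshold used in
#'   [collect_clips()]; sets the symmetric spanning window.
#' @return an `insertion_calls` data.frame: breakpoint (0-based),
#'   clipped_support, spanning_unclipped, allele_fraction, zygosity,
#'   consensus_5p (right-cluster tail = insert 5' start), consensus_3p.
#' @export
call_insertions <- function(clusters, alignments, min_support = 3L,
                            merge_window = 5L, het_band = c(0.2, 0.8),
                            min_clip_length = 20L) {
  right <- Filter(function(cl) cl$side == "right", clusters)
  left <- Filter(function(cl) cl$side == "left", clusters)
  calls <- list()
  used_left <- logical(length(left))
  for (rc in right) {
    dist <- vapply(left, function(lc) abs(lc$position - rc$position),
                   numeric(1))
    j <- if (length(dist)) which.min(ifelse(used_left, Inf, dist)) else 0L
    if (!length(dist) || used_left[j] || dist[j] > merge_window) next
    lc <- left[[j]]
    used_left[j] <- TRUE
    b <- rc$position
    support <- length(unique(c(rc$reads, lc$reads)))
    if (support < min_support) next
    spanning <- count_spanning_unclipped(alignments, b,
                                         exclude = c(rc$reads, lc$reads),
                                         min_flank = min_clip_length)
    per_side <- (length(unique(rc$reads)) + length(unique(lc$reads))) / 2
    af <- per_side / (per_side + spanning)
    zyg <- if (af >= het_band[1] && af <= het_band[2]) "het"
           else if (af > het_band[2]) "hom" else "ambiguous"
    calls[[length(calls) + 1L]] <- data.frame(
      breakpoint = b, clipped_support = support,
      spanning_unclipped = spanning, allele_fraction = af,
      zygosity = zyg, consensus_5p = rc$consensus, consensus_3p = lc$consensus,
      stringsAsFactors = FALSE)
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(breakpoint = integer(0), clipped_support = integer(0),
               spanning_unclipped = integer(0), allele_fraction = numeric(0),
               zygosity = character(0), consensus_5p = character(0),
               consensus_3p = character(0), stringsAsFactors = FALSE)
  class(out) <- c("insertion_calls", "data.frame")
  out
}

# Fragments (unique read names) with at least one record covering the
# junction [b-1, b] inside a single M run with >= min_flank aligned nt on
# each side.  Primary mapped records only; clipped supporters excluded so
# the clipped/unclipped split partitions breakpoint-spanning fragments.
count_spanning_unclipped <- function(alignments, b, exclude = character(0),
                                     min_flank = 1L) {
  a <- alignments
  keep <- !bitwAnd(a$flag, 4L) & !bitwAnd(a$flag, 256L) &
    !bitwAnd(a$flag, 2048L) & !(a$qname %in% exclude)
  a <- a[keep & a$pos <= b, , drop = FALSE]
  spanning <- character(0)
  for (i in seq_len(nrow(a))) {
    ops <- cigar_ops(a$cigar[i])
    r <- a$pos[i] - 1L
    for (k in seq_along(ops$op)) {
      if (ops$op[k] %in% c("M", "=", "X")) {
        if (r + min_flank <= b && r + ops$len[k] >= b + min_flank) {
          spanning <- c(spanning, a$qname[i])
          break
        }
      }
      if (ops$op[k] %in% c("M", "D", "N", "=", "X")) r <- r + ops$len[k]
    }
  }
  length(unique(spanning))
}

#' Write insertion calls as TSV and a VCF-like symbolic record
#'
#' Breakpoints are reported 1-based in both outputs.
#'
#' @param calls an `insertion_calls` data.frame.
#' @param tsv_path,vcf_path output paths (either may be `NULL` to skip).
#' @param rname reference name for the VCF record.
#' @return invisibly, `calls`.
#' @export
write_calls <- function(calls, tsv_path = NULL, vcf_path = NULL,
                        rname = "locus") {
  out <- calls
  out$breakpoint <- out$breakpoint + 1L
  if (!is.null(tsv_path)) {
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(vcf_path)) {
    hdr <- c("##fileformat=VCFv4.2",
             "##ALT=<ID=INS,Description=\"Insertion\">",
             "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End\">",
             "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Clipped support\">",
             "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Insertion allele fraction\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- sprintf("%s\t%d\t.\tN\t<INS>\t.\tPASS\tEND=%d;SUPPORT=%d;AF=%.4f",
                    rname, out$breakpoint, out$breakpoint,
                    out$clipped_support, out$allele_fraction)
    writeLines(c(hdr, body), vcf_path)
  }
  invisible(calls)
}
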