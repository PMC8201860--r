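# Allele-specific expression: per-site allele counts from RNA alignments at
# heterozygous variant sites, and classification of biallelic vs monoallelic
# expression with an exact binomial test against the 50:50 expectation.

#' Count alleles at variant sites from RNA alignments
#'
#' Tallies, per site, aligned read bases equal to the reference allele, the
#' alternate allele, or any other base. Spliced alignments (CIGAR N) are
#' honoured; deleted and soft-clipped positions do not contribute; bases
#' below `min_base_quality` are skipped; duplicate read names are counted
#' once per site.
#'
#' @param alignments data.frame as returned by [read_sam()].
#' @param sites data.frame with columns `pos` (0-based reference offset),
#'   `ref`, `alt` and optionally `label`.
#' @param ref_length reference length (for validating site positions); pass
#'   `NULL` to skip the check.
#' @param min_base_quality minimum Phred base quality.
#' @return an `allele_counts` data.frame: label, pos, ref, alt, ref_count,
#'   alt_count, other_count, alt_fraction (NA when ref+alt = 0), p_value
#'   (two-sided exact binomial vs 0.5).
#' @export
count_alleles <- function(alignments, sites, ref_length = NULL,
                          min_base_quality = 20L) {
  if (!is.null(ref_length) && any(sites$pos < 0 | sites$pos >= ref_length)) {
    stop("variant site outside the reference")
  }
  a <- alignments
  keep <- !bitwAnd(a$flag, 4L) & !bitwAnd(a$flag, 256L) &
    !bitwAnd(a$flag, 2048L)
  a <- a[keep, , drop = FALSE]

  out <- lapply(seq_len(nrow(sites)), function(si) {
    p0 <- sites$pos[si]
    counted <- character(0)
    refc <- altc <- otherc <- 0L
    # only alignments that can span the site (N ops can widen the span,
    # so the coarse filter is generous and the walk decides)
    plain <- grepl("^\\d+M$", a$cigar)
    mlen <- rep(NA_integer_, length(plain))
    mlen[plain] <- as.integer(sub("M$", "", a$cigar[plain]))
    cand <- which(a$pos - 1L <= p0 &
                    (ifelse(plain, a$pos - 1L + mlen,
                            a$pos + nchar(a$seq) + 1e4) > p0))
    for (i in cand) {
      if (a$qname[i] %in% counted) next
      if (plain[i]) {
        q <- p0 - a$pos[i] + 2L
      } else {
        map <- query_refmap(a$pos[i], a$cigar[i])
        q <- which(map == p0)
        if (!length(q)) next
      }
      qual <- utf8ToInt(substr(a$qual[i], q, q)) - 33L
      if (qual < min_base_quality) next
      base <- substr(a$seq[i], q, q)
      counted <- c(counted, a$qname[i])
      if (base == sites$ref[si]) refc <- refc + 1L
      else if (base == sites$alt[si]) altc <- altc + 1L
      else otherc <- otherc + 1L
    }
    n <- refc + altc
    data.frame(label = if (!is.null(sites$label)) sites$label[si]
                       else paste0("site", si),
               pos = p0, ref = sites$ref[si], alt = sites$alt[si],
               ref_count = refc, alt_count = altc, other_count = otherc,
               alt_fraction = if (n > 0) altc / n else NA_real_,
               p_value = if (n > 0)
                 stats::binom.test(altc, n, p = 0.5)$p.value else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("allele_counts", "data.frame")
  out
}

#' Classify allele-specific expression
#'
#' Sites with `ref_count + alt_count < min_coverage` are `low_coverage`.
#' Otherwise a site is `monoallelic_alt` when the alternate-allele fraction
#' is at least `mono_threshold` and the exact binomial p-value against
#' 50:50 is below `alpha`; `monoallelic_ref` is the mirror case; everything
#' else is `biallelic`. The per-gene verdict is `"monoallelic"` when all
#' classifiable sites agree on the same monoallelic direction,
#' `"biallelic"` when all are biallelic, `"discordant"` when monoallelic
#' directions conflict, and `"mixed"` otherwise.
#'
#' @param counts an `allele_counts` data.frame from [count_alleles()].
#' @param mono_threshold allele-fraction threshold for a monoallelic call.
#' @param alpha significance level for the exact binomial test.
#' @param min_coverage minimum ref+alt coverage for classification.
#' @return list with `sites` (counts plus a `classification` column) and
#'   `verdict`.
#' @export
classify_expression <- function(counts, mono_threshold = 0.85, alpha = 0.01,
                                min_coverage = 20L) {
  cls <- character(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    n <- counts$ref_count[i] + counts$alt_count[i]
    if (n < min_coverage) { cls[i] <- "low_coverage"; next }
    f <- counts$alt_fraction[i]
    p <- counts$p_value[i]
    cls[i] <- if (f >= mono_threshold && p < alpha) "monoallelic_alt"
      else if (f <= 1 - mono_threshold && p < alpha) "monoallelic_ref"
      else "biallelic"
  }
  counts$classification <- cls
  informative <- cls[cls != "low_coverage"]
  verdict <- if (!length(informative)) "low_coverage"
    else if (all(informative == "monoallelic_alt") ||
             all(informative == "monoallelic_ref")) "monoallelic"
    else if (all(informative == "biallelic")) "biallelic"
    else if (all(informative %in% c("monoallelic_alt", "monoallelic_ref")))
      "discordant"
    else "mixed"
  list(sites = counts, verdict = verdict)
}

#' Write per-site allele counts as TSV
#'
#' Positions are written 1-based; the layout mirrors a per-site
#' supplementary table (site, ref reads, alt reads, percent alt).
#'
#' @param counts an `allele_counts` data.frame (optionally classified).
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
write_ase_tsv <- function(counts, path) {
  out <- data.frame(site = counts$label, pos = counts$pos + 1L,
                    ref = counts$ref, alt = counts$alt,
                    ref_reads = counts$ref_count,
                    alt_reads = counts$alt_count,
                    pct_alt = round(100 * counts$alt_fraction, 1))
  if (!is.null(counts$classification)) {
    out$classification <- counts$classification
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
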