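# In-silico PCR: predict amplicons for allele-specific primer schemes and
# call insertion presence/absence from band patterns.
#
# Site matching is purely sequence-based (no melting-temperature or dimer
# model): a primer binds where it matches the template within its mismatch
# budget, except that its 3'-terminal `anchor` bases must match exactly
# (mismatches at the extension end abolish amplification).

#' Define a primer
#'
#' @param name primer name.
#' @param sequence 5'->3' sequence over A/C/G/T.
#' @param allowed_mismatches substitutions tolerated outside the anchor.
#' @param three_prime_anchor number of 3'-terminal bases that must match
#'   exactly.
#' @return a one-row data.frame; rows can be `rbind`-ed into a primer
#'   table.
#' @export
primer <- function(name, sequence, allowed_mismatches = 0L,
                   three_prime_anchor = 3L) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) stop("primer sequence must be A/C/G/T")
  if (three_prime_anchor > nchar(sequence)) {
    stop("anchor longer than the primer")
  }
  data.frame(name = name, sequence = sequence,
             allowed_mismatches = as.integer(allowed_mismatches),
             three_prime_anchor = as.integer(three_prime_anchor),
             stringsAsFactors = FALSE)
}

# 0-based start offsets where a primer binds the plus strand of `template`.
# `strand` "+": primer as given, anchor at the match's right edge;
# "-": the primer binds the minus strand, so its site on the plus strand is
# the reverse complement and the anchor sits at the left edge.
primer_sites <- function(primer_row, template, strand) {
  p <- primer_row
  site_seq <- if (strand == "+") p$sequence else revcomp(p$sequence)
  k <- nchar(site_seq)
  hits <- Biostrings::matchPattern(site_seq, Biostrings::DNAString(template),
                                   max.mismatch = p$allowed_mismatches,
                                   fixed = TRUE)
  starts <- Biostrings::start(hits) - 1L
  if (!length(starts) || p$three_prime_anchor == 0L) return(starts)
  anchor <- p$three_prime_anchor
  keep <- vapply(starts, function(s) {
    if (strand == "+") {
      a_site <- substr(template, s + k - anchor + 1L, s + k)
      a_prim <- substr(site_seq, k - anchor + 1L, k)
    } else {
      a_site <- substr(template, s + 1L, s + anchor)
      a_prim <- substr(site_seq, 1L, anchor)
    }
    a_site == a_prim
  }, logical(1))
  starts[keep]
}

#' Predict PCR amplicons
#'
#' For each template and each (forward, reverse) primer pair, finds forward
#' sites on the plus strand and reverse sites (the reverse complement of
#' the reverse primer) downstream, and emits every product up to
#' `max_amplicon`. Product length runs from the forward site's 5' end to
#' the distal end of the reverse-primer site, both primers included.
#'
#' @param templates named character vector of template sequences.
#' @param primers primer table (rbind of [primer()] rows).
#' @param pairs 2-column matrix or data.frame of (forward, reverse) primer
#'   names.
#' @param max_amplicon maximum product length, nt.
#' @return data.frame: template, forward, reverse, start, end (0-based
#'   half-open on the template), length. Zero rows when nothing amplifies.
#' @export
amplify <- function(templates, primers, pairs, max_amplicon = 5000L) {
  if (!length(templates) || !nrow(as.data.frame(pairs))) {
    stop("templates and primer pairs must be non-empty")
  }
  if (is.null(names(templates))) {
    names(templates) <- paste0("template", seq_along(templates))
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  out <- list()
  for (tn in names(templates)) {
    tmpl <- templates[[tn]]
    for (pi in seq_len(nrow(pairs))) {
      fwd <- primers[primers$name == pairs[pi, 1], ]
      rev <- primers[primers$name == pairs[pi, 2], ]
      if (nrow(fwd) != 1L || nrow(rev) != 1L) {
        stop("primer pair references unknown primer name(s)")
      }
      fs <- primer_sites(fwd, tmpl, "+")
      rs <- primer_sites(rev, tmpl, "-")
      for (f in fs) for (r in rs) {
        start <- f
        end <- r + nchar(rev$sequence)        # distal end of reverse site
        if (end <= start + nchar(fwd$sequence)) next  # reverse not downstream
        len <- end - start
        if (len > max_amplicon) next
        out[[length(out) + 1L]] <- data.frame(
          template = tn, forward = fwd$name, reverse = rev$name,
          start = start, end = end, length = len, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(template = character(0), forward = character(0),
                      reverse = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Build a PCR diagnostic scheme
#'
#' A scheme declares, per reaction (primer pair), the expected product size
#' and which allele class (`"mule"` for the insertion allele, `"wt"` for
#' the allele without it) the reaction is specific for.
#'
#' @param reactions data.frame with columns `forward`, `reverse`,
#'   `allele_class` ("mule"/"wt") and `expected_size`.
#' @param size_tolerance band-size tolerance in nt.
#' @return a `pcr_scheme` list.
#' @export
pcr_scheme <- function(reactions, size_tolerance = 5L) {
  stopifnot(all(c("forward", "reverse", "allele_class", "expected_size")
                %in% names(reactions)),
            all(reactions$allele_class %in% c("mule", "wt")))
  reactions$reaction <- paste0(reactions$forward, "+", reactions$reverse)
  structure(list(reactions = reactions,
                 size_tolerance = as.integer(size_tolerance)),
            class = "pcr_scheme")
}

#' Call insertion genotype from band patterns
#'
#' @param band_lengths named list: reaction name (`"FWD+REV"`) to numeric
#'   vector of observed band lengths (possibly empty).
#' @param scheme a `pcr_scheme`.
#' @return `"present"` when any insertion-specific reaction shows a band at
#'   its expected size, `"absent"` when only wild-type-specific reactions
#'   do, `"invalid"` when no expected band appears in any reaction.
#' @export
call_genotype <- function(band_lengths, scheme) {
  stopifnot(inherits(scheme, "pcr_scheme"))
  rx <- scheme$reactions
  tol <- scheme$size_tolerance
  seen <- vapply(seq_len(nrow(rx)), function(i) {
    bands <- band_lengths[[rx$reaction[i]]]
    !is.null(bands) && any(abs(bands - rx$expected_size[i]) <= tol)
  }, logical(1))
  mule_band <- any(seen[rx$allele_class == "mule"])
  wt_band <- any(seen[rx$allele_class == "wt"])
  if (mule_band) "present" else if (wt_band) "absent" else "invalid"
}

#' Run a diagnostic scheme on templates and call the genotype
#'
#' Convenience wrapper: amplifies every scheme reaction on the supplied
#' haplotype templates (a diploid sample is the two haplotypes together)
#' and calls insertion presence/absence from the predicted bands.
#'
#' @param templates named character vector of haplotype sequences.
#' @param primers primer table.
#' @param scheme a `pcr_scheme`.
#' @return list with `amplicons` (data.frame) and `call`.
#' @export
run_pcr_diagnostic <- function(templates, primers, scheme) {
  rx <- scheme$reactions
  amp <- amplify(templates, primers, rx[, c("forward", "reverse")],
                 max_amplicon = max(rx$expected_size) + 1000L)
  bands <- lapply(seq_len(nrow(rx)), function(i) {
    sel <- amp$forward == rx$forward[i] & amp$reverse == rx$reverse[i]
    amp$length[sel]
  })
  names(bands) <- rx$reaction
  list(amplicons = amp, call = call_genotype(bands, scheme))
}
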