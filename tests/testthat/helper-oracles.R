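# Independent oracles and fixture builders used across the suite.  Every
# oracle is a deliberately naive re-derivation, kept separate from the
# implementation paths it checks.

rc_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Naive terminal-inverted-repeat scan: for every candidate length L,
# recount mismatches between the prefix and the reverse complement of the
# suffix from scratch; report the longest L whose innermost pair matches,
# whose overall mismatch fraction is within budget, and whose innermost 12
# pairs hold at most 2 mismatches.
oracle_tirs <- function(element, min_length = 15, max_frac = 0.1,
                        window = 300, bwin = 12, bmm = 2) {
  n <- nchar(element)
  w <- min(window, n %/% 2)
  best <- NULL
  for (L in seq_len(w)) {
    if (L < min_length) next
    a <- strsplit(substr(element, 1, L), "")[[1]]
    b <- strsplit(rc_chr(substr(element, n - L + 1, n)), "")[[1]]
    mism <- a != b
    lo <- max(1, L - bwin + 1)
    if (!mism[L] && sum(mism) <= max_frac * L && sum(mism[lo:L]) <= bmm) {
      best <- list(length = L, mismatches = sum(mism))
    }
  }
  best
}

# Planted-TIR fixture: random element with a TIR of length L and m
# mismatches planted at the termini.  Mismatches are kept away from the
# repeat's inner boundary and the three base pairs just inside the flanks
# are forced to mismatch, so the planted boundary is unambiguous and exact
# recovery is well defined.
planted_tir_element <- function(total, L, m) {
  s <- strsplit(rand_dna(total), "")[[1]]
  left <- s[1:L]
  right <- strsplit(rc_chr(paste(left, collapse = "")), "")[[1]]
  if (m > 0) {
    # right-TIR index i pairs with prefix position L - i + 1, so indices
    # > 12 keep the innermost 12 pairs mismatch free
    at <- sample.int(L - 12L, m) + 12L
    right[at] <- vapply(right[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  }
  s[(total - L + 1):total] <- right
  # guard: positions L+1..L+3 from each end must not complement
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (k in (L + 1):(L + 3)) {
    partner <- comp[[s[total - k + 1]]]
    if (s[k] == partner) {
      s[k] <- sample(setdiff(c("A", "C", "G", "T"), partner), 1)
    }
  }
  paste(s, collapse = "")
}

# Brute-force clip scan over simulated truth CIGARs: returns clip events
# (position, side, qname) straight from the read table.
oracle_clip_scan <- function(sim, min_clip = 20) {
  rd <- sim$reads[!is.na(sim$reads$cigar), ]
  out <- list()
  for (i in seq_len(nrow(rd))) {
    toks <- regmatches(rd$cigar[i], gregexpr("\\d+[MIDNS]", rd$cigar[i]))[[1]]
    len <- as.integer(sub(".$", "", toks))
    op <- sub("^\\d+", "", toks)
    k <- length(op)
    if (op[1] == "S" && len[1] >= min_clip) {
      out[[length(out) + 1]] <- data.frame(
        pos = rd$pos[i] - 1L, side = "left", qname = rd$qname[i])
    }
    if (op[k] == "S" && len[k] >= min_clip) {
      ref_span <- sum(len[op %in% c("M", "D", "N")])
      out[[length(out) + 1]] <- data.frame(
        pos = rd$pos[i] - 1L + ref_span, side = "right", qname = rd$qname[i])
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Sliding-window primer matcher: every 0-based offset where the site
# sequence matches the template with <= budget substitutions, honouring an
# exact anchor at the stated end ("right" = 3' end of a plus-strand
# primer, "left" = 3' end of a minus-strand primer site).
oracle_primer_sites <- function(site_seq, template, budget, anchor,
                                anchor_end) {
  k <- nchar(site_seq)
  n <- nchar(template)
  p <- strsplit(site_seq, "")[[1]]
  hits <- integer(0)
  for (s in 0:(n - k)) {
    t <- strsplit(substr(template, s + 1, s + k), "")[[1]]
    mm <- p != t
    if (sum(mm) > budget) next
    anchor_idx <- if (anchor_end == "right") (k - anchor + 1):k
                  else seq_len(anchor)
    if (anchor > 0 && any(mm[anchor_idx])) next
    hits <- c(hits, s)
  }
  hits
}

# Exact two-sided binomial tail probability against p = 0.5 by direct
# enumeration of outcomes no more probable than the observed one.
oracle_binom_p <- function(x, n) {
  d <- dbinom(0:n, n, 0.5)
  sum(d[d <= d[x + 1] * (1 + 1e-7)])
}

# Exhaustive 2x2 gamete enumeration with the phenotype rule applied
# directly from an alphabet table.
oracle_cross <- function(p1, p2, alphabet) {
  phen <- function(g) {
    h <- alphabet[match(g, alphabet$name), ]
    if (!any(h$expressed)) return("nonviable")
    if (all(h$resistance_conferring[h$expressed])) "resistant"
    else "susceptible"
  }
  out <- c(resistant = 0, susceptible = 0, nonviable = 0)
  for (a in p1) for (b in p2) out[phen(c(a, b))] <- out[phen(c(a, b))] + 25
  out
}

# Small bespoke locus: `flank` nt of random sequence either side of an
# insertion of te_spec `te` placed before 0-based offset `bp`.  No CDS or
# sites: a pure DNA-level fixture for detection/assembly work.
insertion_only_locus <- function(te, flank = 2500, seed = 1) {
  teunmask:::with_seed(seed, {
    reference <- rand_dna(2 * flank)
    locus_truth(reference,
                haplotypes = list(
                  list(name = "wt", alt_sites = integer(0)),
                  list(name = "ins", alt_sites = integer(0),
                       insertion = list(breakpoint = flank, te = te))))
  })
}
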