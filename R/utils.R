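# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of plain character DNA
#'
#' Vectorised reverse complement for character vectors. IUPAC ambiguity codes
#' other than N are not expected anywhere in the package and map to N.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route through this: no function
# touches the global stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Random DNA string(s) of the given lengths.
random_dna <- function(n) {
  vapply(n, function(len)
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = ""), character(1))
}

# Split a sequence into single characters.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Tokenise a CIGAR string into lengths and ops.
cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    return(list(len = integer(0), op = character(0)))
  }
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  tok <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (length(tok) == 0L || sum(nchar(tok)) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar)
  }
  list(len = as.integer(sub("[A-Z=]$", "", tok)),
       op  = sub("^\\d+", "", tok))
}

# For one alignment record, return the 0-based reference position aligned to
# each query base (NA for soft-clipped or inserted bases).  `pos` is the
# 1-based leftmost mapped reference position as in SAM.
query_refmap <- function(pos, cigar) {
  ops <- cigar_ops(cigar)
  qlen <- sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
  out <- rep(NA_integer_, qlen)
  q <- 1L
  r <- pos - 1L  # 0-based
  for (i in seq_along(ops$op)) {
    len <- ops$len[i]
    switch(ops$op[i],
      "M" = , "=" = , "X" = {
        out[q:(q + len - 1L)] <- r + 0:(len - 1L)
        q <- q + len; r <- r + len
      },
      "I" = , "S" = { q <- q + len },
      "D" = , "N" = { r <- r + len },
      "H" = , "P" = NULL)
  }
  out
}

# Format a number to 1 decimal place as numeric.
round1 <- function(x) round(x, 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
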