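# File formats: FASTA via Biostrings, FASTQ and a restricted SAM dialect
# written/read directly.  The SAM dialect is the one the simulator emits:
# single reference sequence, primary records only, CIGAR ops M/I/D/N/S.

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path input file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write paired reads to FASTQ
#'
#' Read names carry `/1` and `/2` suffixes. Mate-2 sequences are written
#' reverse-complemented (sequencing orientation).
#'
#' @param sim a `sim_reads` object from [simulate_reads()].
#' @param r1_path,r2_path output files for mates 1 and 2.
#' @return invisibly, the two paths.
#' @export
write_fastq <- function(sim, r1_path, r2_path) {
  stopifnot(inherits(sim, "sim_reads"))
  rd <- sim$reads
  for (mate in 1:2) {
    m <- rd[rd$mate == mate, ]
    seqs <- if (mate == 2L) revcomp(m$seq_plus) else m$seq_plus
    lines <- as.vector(rbind(paste0("@", m$qname, "/", mate),
                             seqs, "+", m$qual))
    writeLines(lines, if (mate == 1L) r1_path else r2_path)
  }
  invisible(c(r1_path, r2_path))
}

#' Read FASTQ sequences
#'
#' Returns sequences only (base qualities are not used by the assembler).
#'
#' @param paths one or more FASTQ files.
#' @return character vector of read sequences, named by read name.
#' @export
read_fastq <- function(paths) {
  out <- lapply(paths, function(p) {
    x <- readLines(p)
    if (length(x) %% 4L != 0L) stop("truncated FASTQ: ", p)
    s <- x[seq(2L, length(x), by = 4L)]
    names(s) <- sub("^@", "", x[seq(1L, length(x), by = 4L)])
    s
  })
  unlist(out)
}

#' Write simulated alignments as SAM
#'
#' Records are coordinate sorted; unmapped mates are written with flag bit
#' 0x4, `POS 0`, `CIGAR *`. SEQ is stored in reference (plus-strand)
#' orientation as SAM requires.
#'
#' @param sim a `sim_reads` object.
#' @param path output SAM file.
#' @return invisibly, `path`.
#' @export
write_sam <- function(sim, path) {
  stopifnot(inherits(sim, "sim_reads"))
  rd <- sim$reads
  ord <- order(rd$pos, method = "radix", na.last = TRUE)
  rd <- rd[ord, ]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", sim$rname, sim$ref_length))
  pos <- ifelse(is.na(rd$pos), 0L, rd$pos)
  cig <- ifelse(is.na(rd$cigar), "*", rd$cigar)
  rname <- ifelse(is.na(rd$pos), "*", sim$rname)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  rd$qname, rd$flag, rname, pos,
                  ifelse(is.na(rd$pos), 0L, 60L), cig,
                  "=", 0L, 0L, rd$seq_plus, rd$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into an alignment data frame
#'
#' Parses the restricted SAM dialect used throughout the package (single
#' reference, 11 mandatory fields; optional fields ignored).
#'
#' @param path SAM file.
#' @return data.frame with columns qname, flag, rname, pos, mapq, cigar,
#'   seq, qual.
#' @export
read_sam <- function(path) {
  x <- readLines(path)
  x <- x[!startsWith(x, "@")]
  f <- strsplit(x, "\t", fixed = TRUE)
  bad <- vapply(f, length, integer(1)) < 11L
  if (any(bad)) stop("SAM records with fewer than 11 fields in ", path)
  data.frame(
    qname = vapply(f, `[`, character(1), 1L),
    flag  = as.integer(vapply(f, `[`, character(1), 2L)),
    rname = vapply(f, `[`, character(1), 3L),
    pos   = as.integer(vapply(f, `[`, character(1), 4L)),
    mapq  = as.integer(vapply(f, `[`, character(1), 5L)),
    cigar = vapply(f, `[`, character(1), 6L),
    seq   = vapply(f, `[`, character(1), 10L),
    qual  = vapply(f, `[`, character(1), 11L),
    stringsAsFactors = FALSE)
}

# Alignment data frame from a sim_reads object without a file round trip.
sim_alignments <- function(sim) {
  rd <- sim$reads
  ord <- order(rd$pos, method = "radix", na.last = TRUE)
  rd <- rd[ord, ]
  data.frame(qname = rd$qname, flag = rd$flag,
             rname = ifelse(is.na(rd$pos), "*", sim$rname),
             pos = ifelse(is.na(rd$pos), 0L, rd$pos), mapq = 60L,
             cigar = ifelse(is.na(rd$cigar), "*", rd$cigar),
             seq = rd$seq_plus, qual = rd$qual, stringsAsFactors = FALSE)
}
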