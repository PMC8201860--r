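# Ground-truth locus construction and read simulation.

test_that("make_te plants exact terminal inverted repeats", {
  te <- make_te(300, 50, 0, seed = 7)
  expect_equal(nchar(te$sequence), 300)
  # direct string check: reverse complement of the suffix equals the prefix
  expect_identical(rc_chr(substr(te$sequence, 251, 300)),
                   substr(te$sequence, 1, 50))

  te2 <- make_te(2076, 109, 5, seed = 1)
  pre <- strsplit(substr(te2$sequence, 1, 109), "")[[1]]
  sufrc <- strsplit(rc_chr(substr(te2$sequence, 2076 - 108, 2076)), "")[[1]]
  expect_equal(sum(pre != sufrc), 5)

  expect_equal(make_te(200, 0, 0, seed = 1)$tir_length, 0)
  expect_error(make_te(100, 60, 0), "twice")
  expect_error(make_te(300, 50, 50), "smaller")
})

test_that("truncate_te keeps the parent and returns its suffix", {
  te <- make_te(500, 40, 2, seed = 3)
  tr <- truncate_te(te, 120)
  expect_equal(tr$truncated_5p, 120)
  expect_identical(tr$sequence, substr(te$sequence, 121, 500))
  expect_identical(tr$parent_sequence, te$sequence)
})

test_that("archetype haplotype pairs match the clone genotypes", {
  t62 <- build_locus("62H2", seed = 1)
  names62 <- vapply(t62$haplotypes, `[[`, character(1), "name")
  expect_setequal(names62, c("M", "R"))
  hM <- t62$haplotypes[[which(names62 == "M")]]
  hR <- t62$haplotypes[[which(names62 == "R")]]
  expect_length(hM$alt_sites, 0)           # insertion on the wild-type allele
  expect_equal(hR$alt_sites, 1:2)          # both resistance SNPs on the other
  expect_gt(hM$insert_length, 0)
  expect_equal(hR$insert_length, 0)

  t1x <- build_locus("1X", seed = 1)
  expect_identical(t1x$haplotypes[[1]]$seq, t1x$haplotypes[[2]]$seq)
  expect_true(all(vapply(t1x$haplotypes, `[[`, integer(1),
                         "insert_length") == 0))

  t92 <- build_locus("92H6", seed = 1)
  expect_true(all(vapply(t92$haplotypes, function(h)
    identical(h$alt_sites, 1:2), logical(1))))
})

test_that("default locus geometry places breakpoint and sites as annotated", {
  truth <- build_locus("62H2", seed = 4)
  hM <- truth$haplotypes[[1]]
  b <- hM$insertion$breakpoint
  # breakpoint's CDS coordinate and the site offsets downstream of it
  expect_equal(teunmask:::genomic_to_cds(b, truth$cds_intervals), 2360)
  expect_equal(truth$sites$cds_pos - 2360, c(346, 634))
  # sites fall inside the CDS and carry the annotated codon index
  expect_equal(truth$sites$codon, ceiling(truth$sites$cds_pos / 3))
  # reference CDS is a clean ORF
  cds <- teunmask:::reference_cds(truth)
  expect_equal(nchar(cds) %% 3, 0)
  prot <- teunmask:::translate_dna(cds)
  expect_identical(prot[1], "M")
  expect_identical(prot[length(prot)], "*")
  expect_false(any(prot[-length(prot)] == "*"))
  # the insertion-bearing transcript is an NMD target, the others are not
  expect_true(hM$nmd_target)
  expect_false(truth$haplotypes[[2]]$nmd_target)
})

test_that("read-pair count follows coverage conservation", {
  truth <- build_locus("4H", seed = 2)
  for (cov in c(10, 40)) {
    sim <- simulate_reads(truth, "dna", coverage = cov, seed = 5)
    expected <- round(cov * nchar(truth$reference) / (2 * 150))
    expect_lte(abs(nrow(sim$reads) / 2 - expected), 1)
  }
})

test_that("truth CIGARs consume the read length and clipped tails are exact", {
  truth <- build_locus("62H2", seed = 3)
  sim <- simulate_reads(truth, "dna", coverage = 30, seed = 9)
  rd <- sim$reads[!is.na(sim$reads$cigar), ]
  consumed <- vapply(rd$cigar, function(cg) {
    ops <- teunmask:::cigar_ops(cg)
    sum(ops$len[ops$op %in% c("M", "I", "S")])
  }, integer(1))
  expect_true(all(consumed == 150))

  # error-free clipped tails reproduce the insert-derived bases exactly
  te <- truth$haplotypes[[1]]$insertion$te$sequence
  b <- truth$haplotypes[[1]]$insertion$breakpoint
  n_checked <- 0
  for (i in seq_len(nrow(rd))) {
    ops <- teunmask:::cigar_ops(rd$cigar[i])
    k <- length(ops$op)
    if (ops$op[k] == "S" && ops$len[k] >= 20) {
      clip_pos <- rd$pos[i] - 1 + sum(ops$len[ops$op %in% c("M", "D", "N")])
      if (clip_pos == b) {   # tail reads into the insert's 5' end
        tail <- substr(rd$seq_plus[i], 151 - ops$len[k], 150)
        expect_identical(tail, substr(te, 1, ops$len[k]))
        n_checked <- n_checked + 1
      }
    }
    if (ops$op[1] == "S" && ops$len[1] >= 20 && rd$pos[i] - 1 == b) {
      head <- substr(rd$seq_plus[i], 1, ops$len[1])  # insert's 3' end
      expect_identical(head,
                       substr(te, nchar(te) - ops$len[1] + 1, nchar(te)))
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 5)
})

test_that("clipped fraction of spanning fragments reflects heterozygosity", {
  truth <- build_locus("62H2", seed = 6)
  b <- truth$haplotypes[[1]]$insertion$breakpoint
  clipped <- 0; unclipped <- 0
  for (s in 1:10) {
    sim <- simulate_reads(truth, "dna", coverage = 300, seed = 100 + s)
    clips <- oracle_clip_scan(sim, min_clip = 20)
    clipped <- clipped + length(unique(clips$qname[clips$pos == b]))
    rd <- sim$reads[!is.na(sim$reads$pos) & grepl("^150M$", sim$reads$cigar), ]
    span <- rd$pos - 1 + 20 <= b & rd$pos - 1 + 150 >= b + 20
    unclipped <- unclipped + length(unique(rd$qname[span]))
  }
  # per-side clipped count vs unclipped spanning count, as in the caller
  n <- clipped / 2 + unclipped
  expect_gt(n, 1000)
  phat <- (clipped / 2) / n
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / n))
})

# Fraction of site-covering reads carrying the alternate base, tallied
# straight from the read table (plain 150M records cover the variant sites
# in these loci).
site_alt_fraction <- function(sim, p0, ref, alt) {
  rd <- sim$reads[!is.na(sim$reads$pos) & sim$reads$cigar == "150M", ]
  covers <- rd$pos - 1 <= p0 & rd$pos - 1 + 150 > p0
  base <- substr(rd$seq_plus[covers], p0 - rd$pos[covers] + 2,
                 p0 - rd$pos[covers] + 2)
  c(alt = sum(base == alt), ref = sum(base == ref))
}

test_that("allelic depth at variant sites follows the NMD down-weighting", {
  truth <- build_locus("62H2", seed = 1)
  site <- truth$sites[1, ]
  for (ret in c(0.05, 0.2)) {
    sim <- simulate_reads(truth, "rna", coverage = 150,
                          nmd_retention = ret, seed = 11)
    cnt <- site_alt_fraction(sim, site$pos, site$ref, site$alt)
    n <- sum(cnt)
    expected <- 1 / (1 + ret)
    expect_lt(abs(cnt["alt"] / n - expected),
              3 * sqrt(expected * (1 - expected) / n))
  }
  # a locus without any PTC transcript is unaffected by the retention value
  t4 <- build_locus("4H", seed = 1)
  sim <- simulate_reads(t4, "rna", coverage = 150, nmd_retention = 0.05,
                        seed = 11)
  cnt <- site_alt_fraction(sim, site$pos, site$ref, site$alt)
  expect_lt(abs(cnt["alt"] / sum(cnt) - 0.5), 3 * sqrt(0.25 / sum(cnt)))
})

test_that("identical seed and config give byte-identical FASTQ and SAM", {
  truth <- build_locus("62H2", seed = 2)
  d <- withr::local_tempdir()
  paths <- function(tag) file.path(d, paste0(tag, c("_1.fq", "_2.fq", ".sam")))
  for (tag in c("a", "b")) {
    sim <- simulate_reads(truth, "dna", coverage = 10, seed = 42)
    p <- paths(tag)
    write_fastq(sim, p[1], p[2])
    write_sam(sim, p[3])
  }
  for (k in 1:3) {
    expect_identical(readLines(paths("a")[k]), readLines(paths("b")[k]))
  }
  sim2 <- simulate_reads(truth, "dna", coverage = 10, seed = 43)
  sim1 <- simulate_reads(truth, "dna", coverage = 10, seed = 42)
  expect_false(identical(sim1$reads$seq_plus, sim2$reads$seq_plus))
})

test_that("simulator rejects inconsistent parameters", {
  truth <- build_locus("1X", seed = 1)
  expect_error(simulate_reads(truth, "dna", coverage = 10,
                              fragment_mean = 100, read_length = 150),
               "fragment shorter")
  expect_error(simulate_reads(truth, "rna", nmd_retention = 1.5), "0, 1")
})

test_that("spliced RNA truth alignments carry N over introns", {
  truth <- build_locus("4H", seed = 5)
  sim <- simulate_reads(truth, "rna", coverage = 60, seed = 8)
  has_n <- grepl("N", sim$reads$cigar)
  expect_gt(sum(has_n), 0)
  # N gap length equals the intron length for junction-spanning reads
  intron <- truth$exon_intervals[2, 1] - truth$exon_intervals[1, 2]
  ncig <- sim$reads$cigar[has_n][1]
  gap <- as.integer(sub(".*?(\\d+)N.*", "\\1", ncig))
  expect_equal(gap, intron)
})
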