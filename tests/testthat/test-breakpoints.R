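# Soft-clip clustering and insertion calling.

sim_aln <- function(sim) teunmask:::sim_alignments(sim)

test_that("a heterozygous insertion yields two clusters at the breakpoint", {
  truth <- build_locus("62H2", seed = 1)
  b <- truth$haplotypes[[1]]$insertion$breakpoint
  te <- truth$haplotypes[[1]]$insertion$te$sequence
  sim <- simulate_reads(truth, "dna", coverage = 40, seed = 2)
  cl <- collect_clips(sim_aln(sim))
  expect_length(cl, 2)
  expect_setequal(vapply(cl, `[[`, character(1), "side"),
                  c("right", "left"))
  expect_true(all(vapply(cl, `[[`, integer(1), "position") == b))
  # consensus tails reproduce the insert termini (ignoring masked columns)
  right <- cl[[which(vapply(cl, `[[`, character(1), "side") == "right")]]
  left <- cl[[which(vapply(cl, `[[`, character(1), "side") == "left")]]
  w <- nchar(right$consensus)
  expect_identical(gsub("N", "", right$consensus),
                   gsub("N", "", substr(te, 1, w)))
  wl <- nchar(left$consensus)
  expect_identical(gsub("N", "", left$consensus),
                   gsub("N", "", substr(te, nchar(te) - wl + 1, nchar(te))))
})

test_that("an insertion-free locus produces no clusters and no calls", {
  truth <- build_locus("1X", seed = 3)
  sim <- simulate_reads(truth, "dna", coverage = 40, seed = 4)
  aln <- sim_aln(sim)
  cl <- collect_clips(aln)
  expect_length(cl, 0)
  calls <- call_insertions(cl, aln)
  expect_equal(nrow(calls), 0)
})

test_that("consensus columns follow the per-column majority rule", {
  # three reads clipped at position 100 with tails ACGT/ACGT/ACTT:
  # column 3 majority G at 2/3 = 0.67 >= 0.6 -> consensus ACGT
  aln <- data.frame(
    qname = c("a", "b", "c"), flag = 0L, rname = "locus",
    pos = c(21L, 21L, 21L), mapq = 60L,
    cigar = "80M4S",
    seq = paste0(strrep("A", 80), c("ACGT", "ACGT", "ACTT")),
    qual = strrep("F", 84), stringsAsFactors = FALSE)
  cl <- collect_clips(aln, min_clip_length = 4, min_base_agreement = 0.6)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$position, 100)
  expect_identical(cl[[1]]$consensus, "ACGT")
  # at a stricter threshold the 2/3 column is masked
  cl2 <- collect_clips(aln, min_clip_length = 4, min_base_agreement = 0.8)
  expect_identical(cl2[[1]]$consensus, "ACNT")
})

test_that("allele fraction and zygosity arithmetic", {
  mk_cluster <- function(side, reads) {
    structure(list(position = 100L, side = side, reads = reads,
                   tails = rep(strrep("A", 25), length(reads)),
                   consensus = strrep("A", 25)), class = "clip_cluster")
  }
  # 10 right + 10 left clipped, 10 unclipped spanning -> af 0.5, het
  clusters <- list(mk_cluster("right", paste0("r", 1:10)),
                   mk_cluster("left", paste0("l", 1:10)))
  span <- data.frame(qname = paste0("s", 1:10), flag = 0L, rname = "locus",
                     pos = 41L, mapq = 60L, cigar = "150M",
                     seq = strrep("A", 150), qual = strrep("F", 150),
                     stringsAsFactors = FALSE)
  calls <- call_insertions(clusters, span)
  expect_equal(calls$allele_fraction, 0.5)
  expect_identical(calls$zygosity, "het")
  expect_equal(calls$clipped_support, 20)
  # no unclipped spanning reads -> af 1, hom
  empty <- span[0, ]
  calls2 <- call_insertions(clusters, empty)
  expect_equal(calls2$allele_fraction, 1)
  expect_identical(calls2$zygosity, "hom")
  # below min_support: suppressed
  few <- list(mk_cluster("right", "r1"), mk_cluster("left", "l1"))
  expect_equal(nrow(call_insertions(few, span, min_support = 3)), 0)
})

test_that("unsorted input errors; unmapped and secondary records skipped", {
  aln <- data.frame(qname = c("a", "b"), flag = 0L, rname = "locus",
                    pos = c(50L, 10L), mapq = 60L, cigar = "150M",
                    seq = strrep("A", 150), qual = strrep("F", 150),
                    stringsAsFactors = FALSE)
  expect_error(collect_clips(aln), "sorted")
  aln2 <- data.frame(qname = c("u", "s"), flag = c(4L, 256L),
                     rname = "locus", pos = c(0L, 10L), mapq = 0L,
                     cigar = c("*", "30S120M"),
                     seq = strrep("A", 150), qual = strrep("F", 150),
                     stringsAsFactors = FALSE)
  cl <- collect_clips(aln2)
  expect_length(cl, 0)
  expect_equal(attr(cl, "n_skipped"), 2)
})

test_that("clusters reproduce a brute-force scan of the truth CIGARs", {
  truth <- build_locus("62H2", seed = 7)
  sim <- simulate_reads(truth, "dna", coverage = 40, seed = 8)
  cl <- collect_clips(sim_aln(sim))
  oracle <- oracle_clip_scan(sim, min_clip = 20)
  for (sd in c("right", "left")) {
    got <- cl[vapply(cl, `[[`, character(1), "side") == sd]
    want <- oracle[oracle$side == sd, ]
    expect_setequal(got[[1]]$reads, unique(want$qname))
    expect_true(all(want$pos == got[[1]]$position))
  }
})

test_that("breakpoint recall is exact and clean loci stay call-free", {
  hits <- 0
  for (s in 1:8) {
    truth <- build_locus("62H2", seed = 200 + s)
    b <- truth$haplotypes[[1]]$insertion$breakpoint
    sim <- simulate_reads(truth, "dna", coverage = 40, seed = 300 + s)
    aln <- sim_aln(sim)
    calls <- call_insertions(collect_clips(aln), aln)
    expect_equal(nrow(calls), 1)
    expect_equal(calls$breakpoint, b)
    expect_identical(calls$zygosity, "het")
    hits <- hits + 1
  }
  expect_equal(hits, 8)
  for (s in 1:8) {
    truth <- build_locus("1X", seed = 400 + s)
    sim <- simulate_reads(truth, "dna", coverage = 40, seed = 500 + s)
    aln <- sim_aln(sim)
    expect_equal(nrow(call_insertions(collect_clips(aln), aln)), 0)
  }
})

test_that("calls round-trip through TSV and VCF with 1-based positions", {
  truth <- build_locus("62H2", seed = 1)
  sim <- simulate_reads(truth, "dna", coverage = 40, seed = 2)
  aln <- sim_aln(sim)
  calls <- call_insertions(collect_clips(aln), aln)
  d <- withr::local_tempdir()
  write_calls(calls, tsv_path = file.path(d, "c.tsv"),
              vcf_path = file.path(d, "c.vcf"))
  tsv <- read.delim(file.path(d, "c.tsv"))
  expect_equal(tsv$breakpoint, calls$breakpoint + 1)
  vcf <- readLines(file.path(d, "c.vcf"))
  rec <- strsplit(vcf[length(vcf)], "\t")[[1]]
  expect_equal(as.integer(rec[2]), calls$breakpoint + 1)
  expect_identical(rec[5], "<INS>")
})
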