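# Amplicon prediction and band-pattern genotype calls.

test_that("end-to-end amplicon arithmetic", {
  teunmask:::with_seed(41, {
    tmpl <- rand_dna(100)
    fwd <- primer("F", substr(tmpl, 1, 20))
    rev <- primer("R", rc_chr(substr(tmpl, 81, 100)))
    prim <- rbind(fwd, rev)
    amp <- amplify(c(t1 = tmpl), prim, cbind("F", "R"))
    expect_equal(nrow(amp), 1)
    expect_equal(amp$length, 100)
    expect_equal(amp$start, 0)
    expect_equal(amp$end, 100)
  })
})

test_that("adding bases between the primer sites grows the product equally", {
  teunmask:::with_seed(42, {
    left <- rand_dna(60)
    right <- rand_dna(60)
    fwd <- primer("F", substr(left, 1, 20))
    rev <- primer("R", rc_chr(substr(right, 41, 60)))
    prim <- rbind(fwd, rev)
    for (extra in c(0, 17, 123)) {
      tmpl <- paste0(left, rand_dna(extra), right)
      amp <- amplify(c(t = tmpl), prim, cbind("F", "R"))
      expect_equal(amp$length, 120 + extra)
    }
  })
})

test_that("insertion-specific primers do not amplify the insertion-free allele", {
  truth <- build_locus("62H2", seed = 3)
  hM <- truth$haplotypes[[1]]
  hR <- truth$haplotypes[[2]]
  b <- hM$insertion$breakpoint
  # forward primer spanning the flank/insert junction binds only the
  # insertion allele
  mt_f <- primer("MT_F", substr(hM$seq, b - 9, b + 10))
  rev <- primer("Rev", rc_chr(substr(truth$reference, b + 181, b + 200)))
  prim <- rbind(mt_f, rev)
  amp_m <- amplify(c(M = hM$seq), prim, cbind("MT_F", "Rev"),
                   max_amplicon = 5000)
  amp_r <- amplify(c(R = hR$seq), prim, cbind("MT_F", "Rev"),
                   max_amplicon = 5000)
  expect_equal(nrow(amp_m), 1)
  expect_equal(amp_m$length, 10 + 2076 + 200)  # flank + insert + flank
  expect_equal(nrow(amp_r), 0)
})

test_that("mismatch budget and 3' anchor agree with the sliding oracle", {
  teunmask:::with_seed(43, {
    for (i in 1:20) {
      tmpl <- rand_dna(800)
      at <- sample(50:700, 1)
      p_seq <- strsplit(substr(tmpl, at + 1, at + 22), "")[[1]]
      where <- sample(c("inside", "anchor"), 1)
      mut_at <- if (where == "inside") sample(1:19, 1) else sample(20:22, 1)
      p_seq[mut_at] <- setdiff(c("A", "C", "G", "T"), p_seq[mut_at])[1]
      p <- primer("P", paste(p_seq, collapse = ""),
                  allowed_mismatches = 1, three_prime_anchor = 3)
      got <- teunmask:::primer_sites(p, tmpl, "+")
      want <- oracle_primer_sites(paste(p_seq, collapse = ""), tmpl,
                                  budget = 1, anchor = 3,
                                  anchor_end = "right")
      expect_equal(sort(got), sort(want))
      if (where == "anchor") expect_false(at %in% got)
      else expect_true(at %in% got)
    }
  })
})

test_that("reverse-strand anchor sits at the left edge of the plus-strand site", {
  teunmask:::with_seed(44, {
    tmpl <- rand_dna(300)
    site <- substr(tmpl, 101, 125)             # plus-strand binding site
    rev_seq <- strsplit(rc_chr(site), "")[[1]] # primer 5'->3' on minus
    # mutate the primer's 3'-terminal base = first base of the site
    rev_seq[25] <- setdiff(c("A", "C", "G", "T"), rev_seq[25])[1]
    p <- primer("R", paste(rev_seq, collapse = ""),
                allowed_mismatches = 1, three_prime_anchor = 3)
    expect_false(100 %in% teunmask:::primer_sites(p, tmpl, "-"))
    # a mutation at the primer's 5' end (right edge of the site) is fine
    rev_seq2 <- strsplit(rc_chr(site), "")[[1]]
    rev_seq2[1] <- setdiff(c("A", "C", "G", "T"), rev_seq2[1])[1]
    p2 <- primer("R2", paste(rev_seq2, collapse = ""),
                 allowed_mismatches = 1, three_prime_anchor = 3)
    expect_true(100 %in% teunmask:::primer_sites(p2, tmpl, "-"))
  })
})

test_that("band patterns call insertion presence, absence and failure", {
  rx <- data.frame(forward = c("MT_F2", "MT_F2", "WT_F1"),
                   reverse = c("R1", "R2", "R1"),
                   allele_class = c("mule", "mule", "wt"),
                   expected_size = c(326, 276, 327))
  scheme <- pcr_scheme(rx)
  expect_identical(call_genotype(list("MT_F2+R1" = 326, "MT_F2+R2" = 276,
                                      "WT_F1+R1" = 327), scheme), "present")
  expect_identical(call_genotype(list("WT_F1+R1" = 327), scheme), "absent")
  expect_identical(call_genotype(list(), scheme), "invalid")
  # a band off by more than the tolerance does not count
  expect_identical(call_genotype(list("WT_F1+R1" = 340), scheme), "invalid")
  expect_identical(call_genotype(list("WT_F1+R1" = 330), scheme), "absent")
})

# Diagnostic scheme construction mirroring the published product sizes:
# primers are taken from the simulated haplotypes so that the mule-specific
# reactions give 326 and 276 nt products and the wild-type reaction 327 nt.
build_diagnostic <- function(truth) {
  hM <- NULL
  for (h in truth$haplotypes) if (h$insert_length > 0) hM <- h
  b <- hM$insertion$breakpoint
  ilen <- hM$insert_length
  ref <- truth$reference
  # reverse sites downstream of the breakpoint on the reference
  r1_end <- b + 270
  r1 <- primer("R1", rc_chr(substr(ref, r1_end - 19, r1_end)))
  # MT_F2 binds inside the element's 3' region: product on the insertion
  # haplotype = 326 nt ending at r1_end (+ilen in insertion coordinates)
  mt_start <- (r1_end + ilen) - 326   # 0-based start on the M haplotype
  mt_f2 <- primer("MT_F2", substr(hM$seq, mt_start + 1, mt_start + 20))
  # WT_F1 binds upstream of the breakpoint on both alleles, but only the
  # insertion-free allele yields the correct-size (327 nt) product
  wt_start <- r1_end - 327
  wt_f1 <- primer("WT_F1", substr(ref, wt_start + 1, wt_start + 20))
  # R2: second mule-specific reverse, product 276 nt with MT_F2
  r2_end <- mt_start + 276 - ilen
  r2 <- primer("R2", rc_chr(substr(ref, r2_end - 19, r2_end)))
  list(primers = rbind(mt_f2, wt_f1, r1, r2),
       scheme = pcr_scheme(data.frame(
         forward = c("MT_F2", "MT_F2", "WT_F1"),
         reverse = c("R1", "R2", "R1"),
         allele_class = c("mule", "mule", "wt"),
         expected_size = c(326, 276, 327))))
}

test_that("the allele-specific diagnostic recovers archetype truth", {
  hap_templates <- function(truth) {
    s <- vapply(truth$haplotypes, `[[`, character(1), "seq")
    names(s) <- paste0("hap_", vapply(truth$haplotypes, `[[`,
                                      character(1), "name"), "_", 1:2)
    s
  }
  for (s in 1:15) {
    t62 <- build_locus("62H2", seed = s)
    diag <- build_diagnostic(t62)
    res <- run_pcr_diagnostic(hap_templates(t62), diag$primers, diag$scheme)
    expect_identical(res$call, "present")
    expect_setequal(
      intersect(res$amplicons$length, c(326, 276, 327)), c(326, 276, 327))
    t1x <- build_locus("1X", seed = s)
    res0 <- run_pcr_diagnostic(hap_templates(t1x), diag$primers, diag$scheme)
    expect_identical(res0$call, "absent")
  }
})
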