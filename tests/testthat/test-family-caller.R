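# Brute-force family grouping oracle: pairwise key comparison.
oracle_partition_sizes <- function(reads, use_umi = FALSE) {
  n <- nrow(reads)
  assigned <- rep(NA_integer_, n)
  fam <- 0L
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) next
    fam <- fam + 1L
    assigned[i] <- fam
    if (i < n) for (j in (i + 1):n) {
      same <- reads$start[i] == reads$start[j] &&
        reads$end[i] == reads$end[j]
      if (use_umi) same <- same && identical(reads$umi[i], reads$umi[j])
      if (same) assigned[j] <- fam
    }
  }
  sort(as.integer(table(assigned)))
}

test_that("positional grouping is an exact-key partition of the reads", {
  reads <- rbind(mk_family(100, 180, 6, 6), mk_family(100, 181, 3, 3))
  fam <- group_positional_families(reads)
  expect_equal(sort(fam$size), c(3, 6))
  expect_equal(sum(fam$size), nrow(reads))

  expect_equal(nrow(group_positional_families(mk_reads(integer(0),
                                                       integer(0),
                                                       character(0)))), 0)
  expect_error(group_positional_families(
    rbind(mk_reads(1, 10, "ref", chrom = "chr1"),
          mk_reads(1, 10, "ref", chrom = "chr2"))), "chromosomes")
})

test_that("family grouping matches the brute-force pairwise oracle", {
  set.seed(101)
  for (rep in 1:5) {
    keys <- data.frame(start = sample(100:104, 5), end = sample(200:204, 5))
    pick <- sample(1:5, 50, replace = TRUE)
    reads <- mk_reads(keys$start[pick], keys$end[pick],
                      sample(c("ref", "alt"), 50, TRUE))
    fam <- group_positional_families(reads)
    expect_equal(sort(fam$size), oracle_partition_sizes(reads))
    expect_equal(sum(fam$size), 50)
  }
  # UMI grouping, randomized 200 reads
  reads <- mk_reads(sample(c(10L, 20L), 200, TRUE),
                    sample(c(110L, 120L), 200, TRUE),
                    sample(c("ref", "alt", "other"), 200, TRUE),
                    umi = sample(c("AAAA", "CCCC", "GGGG"), 200, TRUE))
  fam <- group_umi_families(reads)
  expect_equal(sort(fam$size), oracle_partition_sizes(reads, use_umi = TRUE))
})

test_that("UMI grouping keys on position and tag jointly", {
  two_umis <- rbind(mk_family(100, 180, 4, 4, umi = "AAAA"),
                    mk_family(100, 180, 3, 0, umi = "CCCC"))
  expect_equal(nrow(group_umi_families(two_umis)), 2)

  same_umi <- rbind(mk_family(100, 180, 4, 4, umi = "AAAA"),
                    mk_family(100, 190, 3, 3, umi = "AAAA"))
  expect_equal(nrow(group_umi_families(same_umi)), 2)

  missing <- mk_reads(c(1, 2), c(10, 20), "ref", umi = c("AAAA", NA))
  expect_error(group_umi_families(missing), "read 2 has no UMI")
})

test_that("positional caller needs two >=5-read families above strict 95%", {
  thr <- caller_thresholds()
  # exactly at both gates: two families of 5, all alt
  fam <- group_positional_families(rbind(mk_family(100, 180, 5, 5),
                                         mk_family(100, 181, 5, 5)))
  expect_true(call_dnaseq_positional(fam, thr)$detected)

  # one huge family is not enough
  one <- group_positional_families(mk_family(100, 180, 50, 50))
  res <- call_dnaseq_positional(one, thr)
  expect_false(res$detected)
  expect_identical(res$reason, "insufficient_families")
  expect_equal(res$supporting_families, 1L)

  # 19/20 = 95% exactly fails the strict > 95% rule
  fam <- group_positional_families(rbind(mk_family(100, 180, 20, 19),
                                         mk_family(100, 181, 5, 5)))
  expect_false(call_dnaseq_positional(fam, thr)$detected)
  # 20/21 > 95% passes
  fam <- group_positional_families(rbind(mk_family(100, 180, 21, 20),
                                         mk_family(100, 181, 5, 5)))
  expect_true(call_dnaseq_positional(fam, thr)$detected)

  # family size boundary: 4-read families never qualify
  fam <- group_positional_families(rbind(mk_family(100, 180, 4, 4),
                                         mk_family(100, 181, 4, 4),
                                         mk_family(100, 182, 4, 4)))
  expect_false(call_dnaseq_positional(fam, thr)$detected)

  empty <- group_positional_families(mk_reads(integer(0), integer(0),
                                              character(0)))
  expect_identical(call_dnaseq_positional(empty, thr)$reason, "no_families")
})

test_that("consensus collapse keeps strict majorities and drops ties", {
  fam <- group_umi_families(mk_family(100, 180, 3, 3, umi = "AAAA"))
  cons <- collapse_consensus(fam, min_size = 1)
  expect_equal(nrow(cons), 1)
  expect_identical(cons$allele, "alt")

  tie <- group_umi_families(mk_family(100, 180, 4, 2, umi = "AAAA"))
  cons <- collapse_consensus(tie, min_size = 1)
  expect_equal(nrow(cons), 0)
  expect_equal(attr(cons, "n_dropped_tie"), 1)

  small <- group_umi_families(mk_family(100, 180, 2, 2, umi = "AAAA"))
  cons <- collapse_consensus(small, min_size = 3)
  expect_equal(nrow(cons), 0)
  expect_equal(attr(cons, "n_dropped_small"), 1)
})

test_that("consensus collapsing suppresses read-level error", {
  p <- read_sim_params(n_molecules = 1000, maf_molecular = 0,
                       error_rate = 0.01, chemistry = "tagged_umi",
                       seed = 99)
  sim <- simulate_read_families(p)
  raw_err <- mean(sim$reads$allele != "ref")
  fam <- group_umi_families(sim$reads)
  cons <- collapse_consensus(fam, min_size = 3)
  cons_err <- mean(cons$allele != "ref")
  expect_gt(raw_err, 0)
  expect_lt(cons_err, raw_err)
})

test_that("check-known-variants thresholds: 0.4% SNV, 0.2% multi-base indel", {
  mk_cons <- function(n, n_alt)
    data.frame(chrom = "chr1", start = 1, end = 100, umi = "A",
               allele = c(rep("alt", n_alt), rep("ref", n - n_alt)),
               family_size = 3, stringsAsFactors = FALSE)
  thr <- caller_thresholds()
  expect_true(call_tagseq_ckv(mk_cons(2000, 9), "SNV", thr)$detected)   # 0.45%
  expect_false(call_tagseq_ckv(mk_cons(2000, 7), "SNV", thr)$detected)  # 0.35%
  expect_true(call_tagseq_ckv(mk_cons(2000, 8), "SNV", thr)$detected)   # 0.40% inclusive
  expect_true(call_tagseq_ckv(mk_cons(2000, 5),
                              "multi_base_indel", thr)$detected)        # 0.25%
  expect_true(call_tagseq_ckv(mk_cons(2000, 4),
                              "multi_base_indel", thr)$detected)        # 0.20% inclusive
  expect_false(call_tagseq_ckv(mk_cons(2000, 3),
                               "multi_base_indel", thr)$detected)       # 0.15%
  # single-base indels follow the indel threshold unless reconfigured
  expect_true(call_tagseq_ckv(mk_cons(2000, 5),
                              "single_base_indel", thr)$detected)
  thr2 <- caller_thresholds(single_base_indel_as_snv = TRUE)
  expect_false(call_tagseq_ckv(mk_cons(2000, 5),
                               "single_base_indel", thr2)$detected)
  empty <- mk_cons(2000, 0)[0, ]
  expect_identical(call_tagseq_ckv(empty, "SNV", thr)$reason, "no_depth")
})

test_that("UMI family-support gate needs two alt families of >= 3 reads", {
  thr <- caller_thresholds()
  fams <- function(sizes, alt_sizes) {
    reads <- do.call(rbind, lapply(seq_along(sizes), function(i)
      mk_family(100, 180 + i, sizes[i],
                if (i <= alt_sizes) sizes[i] else 0,
                umi = sprintf("U%02d", i))))
    group_umi_families(reads)
  }
  expect_true(call_generead(fams(c(3, 3), 2), thr)$detected)
  expect_false(call_generead(fams(c(3, 2), 2), thr)$detected)
  expect_false(call_generead(fams(c(3, 3), 1), thr)$detected)
  expect_true(call_generead(fams(c(10, 3, 2), 2), thr)$detected)

  # randomized family sets against direct evaluation of the rule
  set.seed(5)
  for (i in 1:20) {
    k <- sample(1:6, 1)
    sizes <- sample(1:6, k, replace = TRUE)
    n_alt_fams <- sample(0:k, 1)
    f <- fams(sizes, n_alt_fams)
    expected <- sum(sizes[seq_len(n_alt_fams)] >= 3) >= 2
    expect_identical(call_generead(f, thr)$detected, expected)
  }
})

test_that("amplicon caller gates: depth, variant reads, confidence, %SR", {
  thr <- caller_thresholds()
  amp <- function(n, n_alt) mk_reads(rep(100, n), rep(220, n),
                                     c(rep("alt", n_alt),
                                       rep("ref", n - n_alt)))
  r <- call_amplicon(amp(9, 9), "SNV", thresholds = thr)
  expect_false(r$detected); expect_identical(r$reason, "insufficient_depth")

  r <- call_amplicon(amp(1000, 1), "SNV", thresholds = thr)
  expect_false(r$detected); expect_identical(r$reason,
                                             "insufficient_var_reads")

  # 2/1000 = 0.2% is below the 0.3% SNV gate; for an indel it clears %SR
  # and proceeds to the confidence gate, which 2 reads cannot satisfy
  r <- call_amplicon(amp(1000, 2), "SNV", thresholds = thr)
  expect_false(r$detected); expect_identical(r$reason, "sr_below_threshold")
  r <- call_amplicon(amp(1000, 2), "multi_base_indel", thresholds = thr)
  expect_false(r$detected); expect_identical(r$reason, "low_confidence")

  # exactly 0.3% passes (inclusive) once the confidence gate is cleared
  expect_true(call_amplicon(amp(1000, 3), "SNV", error_rate_null = 1e-5,
                            thresholds = thr)$detected)

  # at the default 0.1% null error rate, 3/1000 clears %SR but not the
  # Phred-50 confidence gate
  r <- call_amplicon(amp(1000, 3), "SNV", thresholds = thr)
  expect_false(r$detected); expect_identical(r$reason, "low_confidence")

  # a clearly supported variant passes everything
  expect_true(call_amplicon(amp(1000, 12), "SNV", thresholds = thr)$detected)
})

test_that("confidence equals the brute-force binomial tail on the Phred scale", {
  tail_oracle <- function(k, n, p) {
    # direct summation of P(X >= k), terms assembled in log space
    sum(vapply(k:n, function(x)
      exp(lchoose(n, x) + x * log(p) + (n - x) * log(1 - p)), 0))
  }
  cases <- list(c(5, 1000), c(2, 50), c(10, 2000), c(3, 10))
  for (cs in cases) {
    k <- cs[1]; n <- cs[2]
    for (p0 in c(0.001, 0.005)) {
      expect_equal(binomial_confidence(k, n, p0),
                   -10 * log10(tail_oracle(k, n, p0)), tolerance = 1e-8)
    }
  }
  expect_equal(binomial_confidence(0, 100, 0.001), 0)
})

test_that("adding alt evidence never flips a detection off (monotonicity)", {
  thr <- caller_thresholds()
  set.seed(31)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    sizes <- sample(3:8, k, replace = TRUE)
    alts <- vapply(sizes, function(s) sample(0:s, 1), 0L)
    reads <- do.call(rbind, lapply(seq_len(k), function(j)
      mk_family(100, 180 + j, sizes[j], alts[j], umi = sprintf("U%d", j))))
    before <- call_dnaseq_positional(group_positional_families(reads), thr)
    more <- rbind(reads, mk_family(100, 300, 6, 6, umi = "UX"))
    after <- call_dnaseq_positional(group_positional_families(more), thr)
    if (before$detected) expect_true(after$detected)

    gr_before <- call_generead(group_umi_families(reads), thr)
    gr_after <- call_generead(group_umi_families(more), thr)
    if (gr_before$detected) expect_true(gr_after$detected)

    amp_before <- call_amplicon(reads, "SNV", thresholds = thr)
    amp_after <- call_amplicon(rbind(reads, mk_reads(100, 180, "alt")),
                               "SNV", thresholds = thr)
    if (amp_before$detected) expect_true(amp_after$detected)
  }
})

test_that("simulator + positional caller detect 0.5% MAF reliably", {
  # self-consistency of the simulator/caller pair, not an external claim
  hits <- vapply(1:10, function(s) {
    p <- read_sim_params(n_molecules = 10000, maf_molecular = 0.5,
                         error_rate = 0.001, chemistry = "positional",
                         seed = 700 + s)
    sim <- simulate_read_families(p)
    call_dnaseq_positional(group_positional_families(sim$reads))$detected
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
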