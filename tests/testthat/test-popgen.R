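test_that("allele frequencies are observed counts over genotyped chromosomes", {
  calls <- array(NA_character_, dim = c(3, 2, 2))
  calls[1, 1, ] <- c("A", "A"); calls[2, 1, ] <- c("A", "G")  # (A,A),(A,G)
  calls[1, 2, ] <- c("G", "G")                                 # others missing
  p <- haplotype_panel(calls, data.frame(chrom = "1", pos = c(1L, 2L),
                                         vid = c("v1", "v2"),
                                         alleles = I(list(c("A", "G"),
                                                          c("A", "G")))),
                       samples = c("a", "b", "c"))
  ft <- allele_frequencies(p, c(a = "X", b = "X", c = "X"))
  expect_equal(ft$freqs$X[1, ], c(0.75, 0.25))   # 3 A, 1 G of 4 chromosomes
  expect_equal(ft$freqs$X[2, ], c(0, 1))          # only sample a genotyped
  expect_equal(ft$counts$X[1, ], c(3, 1))
  # a second population with no genotyped sample at a locus is flagged absent
  ft2 <- allele_frequencies(p, c(a = "X", b = "Y", c = "Y"))
  expect_true(all(is.na(ft2$freqs$Y[2, ])))
  expect_error(allele_frequencies(p, c(a = "X", b = "X")),
               class = "grouping_error")
})

test_that("Reynolds distance reproduces hand-evaluated cases", {
  f <- matrix(c(0.8, 0.2), 1, 2)
  expect_equal(reynolds_distance(f, f), 0)
  # opposite fixation at one locus: numerator 2, denominator 2
  expect_equal(reynolds_distance(matrix(c(1, 0), 1), matrix(c(0, 1), 1)), 1)
  # (0.8,0.2) vs (0.6,0.4): 0.08 / 0.88
  expect_equal(reynolds_distance(matrix(c(0.8, 0.2), 1),
                                 matrix(c(0.6, 0.4), 1)), 0.08 / 0.88)
  # identical fixed populations: 0/0 handled as distance 0
  expect_equal(reynolds_distance(matrix(c(1, 0), 1), matrix(c(1, 0), 1)), 0)
})

test_that("Reynolds distance is symmetric and invariant to allele relabeling", {
  set.seed(40)
  for (rep in 1:20) {
    l <- sample(3:30, 1)
    fa <- matrix(runif(l), l); fa <- cbind(fa, 1 - fa)
    fb <- matrix(runif(l), l); fb <- cbind(fb, 1 - fb)
    th <- reynolds_distance(fa, fb)
    expect_identical(th, reynolds_distance(fb, fa))
    perm <- sample(2)
    expect_equal(reynolds_distance(fa[, perm, drop = FALSE],
                                   fb[, perm, drop = FALSE]), th)
    expect_gte(th, 0)
  }
})

test_that("monomorphic-in-both loci contribute nothing to the distance", {
  fa <- rbind(c(0.7, 0.3), c(1, 0))
  fb <- rbind(c(0.4, 0.6), c(1, 0))
  expect_equal(reynolds_distance(fa, fb),
               reynolds_distance(fa[1, , drop = FALSE], fb[1, , drop = FALSE]))
})

test_that("the distance matrix is symmetric with zero diagonal; duplicated populations at distance 0", {
  p <- rand_panel(12, 30, seed = 41)
  groups <- setNames(rep(c("X", "Y", "Xdup"), each = 4), p$samples)
  # make Xdup an exact copy of X
  p$calls[9:12, , ] <- p$calls[1:4, , ]
  m <- reynolds_matrix(allele_frequencies(p, groups))
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(diag(unclass(m)), setNames(rep(0, 3), rownames(m)))
  expect_equal(m["X", "Xdup"], 0)
  expect_gt(m["X", "Y"], 0)
})

test_that("frequency estimates recover Balding-Nichols generator truth", {
  sim <- simulate_populations(sim_config(n_ind = 200, n_loci = 300,
                                         n_pops = 2, F = c(0.05, 0.05),
                                         seed = 42))
  ft <- allele_frequencies(sim$panel, sim$groups)
  for (pop in c("pop1", "pop2")) {
    est <- ft$freqs[[pop]][, 1]
    tru <- sim$true_freqs$freqs[[pop]][, 1]
    se <- sqrt(pmax(tru * (1 - tru), 1e-6) / (2 * 200))
    expect_lt(mean(abs(est - tru) > 3 * se), 0.02)  # ~0.3% expected beyond 3 SE
  }
})

test_that("HWE exact test matches direct enumeration and normalizes", {
  expect_equal(hwe_exact_test(5, 0, 0), 1)
  set.seed(43)
  for (rep in 1:200) {
    n <- sample(1:50, 1)
    nAA <- sample(0:n, 1)
    nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    expect_equal(hwe_exact_test(nAA, nAa, naa), oracle_hwe(nAA, nAa, naa),
                 tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(-1, 0, 2), class = "argument_error")
  expect_error(hwe_exact_test(0, 0, 0), class = "argument_error")
})

test_that("variant filters remove exactly the planted violations, in order", {
  set.seed(44)
  n <- 40
  hw_col <- function(f) {   # Hardy-Weinberg column at allele-1 frequency f
    h1 <- ifelse(runif(n) < f, "A", "G"); h2 <- ifelse(runif(n) < f, "A", "G")
    cbind(h1, h2)
  }
  cols <- list(
    ok1 = hw_col(0.5),
    low_maf = cbind(c("A", rep("G", n - 1)), rep("G", n)),   # MAF ~ 0.0125 > 0.01? -> 1/80 = 0.0125
    ok2 = hw_col(0.3),
    hwe_bad = cbind(rep(c("A", "G"), n / 2), rep(c("G", "A"), n / 2)), # all het
    low_call = { m <- hw_col(0.4); m[1:20, ] <- NA; m },      # call rate 0.5
    dup_a = hw_col(0.5), dup_b = hw_col(0.5),
    no_rs = hw_col(0.4))
  l <- length(cols)
  calls <- array(NA_character_, dim = c(n, l, 2))
  for (j in seq_len(l)) calls[, j, ] <- cols[[j]]
  pos <- c(10L, 20L, 30L, 40L, 50L, 60L, 60L, 70L)   # dup_a/dup_b share pos
  vid <- c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6", "rs7", "snp8")
  p <- haplotype_panel(calls, data.frame(chrom = "1", pos = pos, vid = vid,
                                         alleles = I(replicate(l, c("A", "G"),
                                                               simplify = FALSE))))
  # a truly low-MAF column: single copy of A gives MAF 1/80 = 0.0125; use
  # threshold 0.02 to catch it
  out <- filter_variants(p, maf_min = 0.02, callrate_min = 0.95,
                         hwe_alpha = 1e-5, dedup_by_pos = TRUE,
                         id_regex = "rs")
  rep_tab <- attr(out, "filter_report")
  expect_equal(rep_tab$filter, c("maf", "hwe", "callrate", "dedup", "id"))
  expect_equal(rep_tab$removed, c(1, 1, 1, 2, 1))
  expect_equal(out$variants$vid, c("rs1", "rs3"))
  # keep-first spares one member of the duplicated-position pair
  out2 <- filter_variants(p, dedup_by_pos = TRUE, dedup_keep = "first")
  expect_equal(attr(out2, "filter_report")$removed,
               c(0, 0, 0, 1, 0))
  # no-op thresholds are the identity
  out3 <- filter_variants(p)
  expect_equal(n_variants(out3), l)
  expect_equal(sum(attr(out3, "filter_report")$removed), 0)
})
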