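test_that("major-allele imputer fills with the modal genotype, observed cells untouched", {
  # locus: 9 x (A,A), 1 x (A,G), 2 missing
  calls <- array(NA_character_, dim = c(12, 1, 2))
  for (i in 1:9) calls[i, 1, ] <- c("A", "A")
  calls[10, 1, ] <- c("A", "G")
  p <- haplotype_panel(calls, data.frame(chrom = "1", pos = 1L, vid = NA,
                                         alleles = I(list(c("A", "G")))))
  out <- impute_major_allele(p)
  expect_equal(out$calls[11, 1, ], c("A", "A"))
  expect_equal(out$calls[12, 1, ], c("A", "A"))
  expect_equal(out$calls[1:10, 1, ], p$calls[1:10, 1, ])
  expect_equal(sum(missing_matrix(out)), 0)
  # fully observed panel: identity
  q <- rand_panel(5, 5, seed = 60)
  expect_identical(impute_major_allele(q), q)
  # ties break lexicographically: 1 x (G,G), 1 x (A,A) -> A/A
  calls2 <- array(NA_character_, dim = c(3, 1, 2))
  calls2[1, 1, ] <- c("G", "G"); calls2[2, 1, ] <- c("A", "A")
  p2 <- haplotype_panel(calls2, data.frame(chrom = "1", pos = 1L, vid = NA,
                                           alleles = I(list(c("A", "G")))))
  expect_equal(impute_major_allele(p2)$calls[3, 1, ], c("A", "A"))
  # all-missing locus falls back to the first-listed allele, with a message
  calls3 <- array(NA_character_, dim = c(2, 1, 2))
  p3 <- haplotype_panel(calls3, data.frame(chrom = "1", pos = 1L, vid = NA,
                                           alleles = I(list(c("C", "T")))))
  expect_message(out3 <- impute_major_allele(p3), "no observed")
  expect_equal(out3$calls[1, 1, ], c("C", "C"))
})

test_that("frequency-sampling imputer is seeded, fills everything, and is monomorphic-safe", {
  p <- rand_panel(20, 30, miss = 0.2, seed = 61)
  a <- impute_frequency_sample(p, seed = 7)
  b <- impute_frequency_sample(p, seed = 7)
  c <- impute_frequency_sample(p, seed = 8)
  expect_identical(a$calls, b$calls)
  expect_false(identical(a$calls, c$calls))
  expect_equal(sum(missing_matrix(a)), 0)
  obs <- !missing_matrix(p)
  expect_identical(a$calls[, , 1][obs], p$calls[, , 1][obs])
  # monomorphic locus: all fills homozygous for the sole observed allele
  calls <- array(c("T", "T", NA, "T", "T", NA), dim = c(3, 1, 2))
  mono <- haplotype_panel(calls, data.frame(chrom = "1", pos = 1L, vid = NA,
                                            alleles = I(list("T"))))
  expect_equal(impute_frequency_sample(mono, 1)$calls[3, 1, ], c("T", "T"))
})

test_that("major-allele discordance on Hardy-Weinberg data matches 1 - f^2 within 3 SE", {
  # high major-allele frequency so the modal genotype is the major homozygote
  sim <- simulate_populations(sim_config(n_ind = 250, n_loci = 400, n_pops = 1,
                                         F = 0, freq_min = 0.75,
                                         freq_max = 0.92, seed = 62))
  p <- sim$panel
  f <- sim$true_freqs$freqs$pop1[, 1]
  ms <- generate_mask_set(p, 0.1, 2, seed = 63)
  imputed <- impute_builtin(imputer_spec("major_allele"),
                            lapply(ms$masks, function(m) apply_mask(p, m)))
  q <- estimate_quality(p, imputed, masks = ms)
  m_col <- round(0.1 * 250)
  exp_cell <- 1 - f^2                 # P(truth != major homozygote)
  expected <- mean(exp_cell)
  se <- sqrt(sum(m_col * exp_cell * (1 - exp_cell))) / (m_col * length(f))
  for (k in 1:2) expect_lt(abs(q$discordance[k] - expected), 3 * se)
})

test_that("frequency-sampling discordance matches its closed form within 3 SE", {
  sim <- simulate_populations(sim_config(n_ind = 250, n_loci = 400, n_pops = 1,
                                         F = 0, freq_min = 0.3, freq_max = 0.7,
                                         seed = 64))
  p <- sim$panel
  f <- sim$true_freqs$freqs$pop1[, 1]
  ms <- generate_mask_set(p, 0.1, 2, seed = 65)
  imputed <- impute_builtin(imputer_spec("freq_sample", seed = 66),
                            lapply(ms$masks, function(m) apply_mask(p, m)))
  q <- estimate_quality(p, imputed, masks = ms)
  # concordance = sum over genotypes g of P(truth = g) P(imputed = g)
  conc <- f^4 + (2 * f * (1 - f))^2 + (1 - f)^4
  expected <- mean(1 - conc)
  m_col <- round(0.1 * 250)
  se <- sqrt(sum(m_col * (1 - conc) * conc)) / (m_col * length(f))
  for (k in 1:2) expect_lt(abs(q$discordance[k] - expected), 3 * se)
})

test_that("imputer_spec validates external command templates", {
  expect_error(imputer_spec("external"), class = "argument_error")
  expect_error(imputer_spec("external", "fastphase {input}"),
               class = "argument_error")
  expect_error(imputer_spec("external", "x {input} {output} {output}"),
               class = "argument_error")
  s <- imputer_spec("external", "cp {input} {output}",
                    params = list(K = 20, em = 25))
  expect_equal(s$params$K, 20)
})

test_that("run_external executes the template per input, preserving order", {
  dir <- withr::local_tempdir()
  inputs <- file.path(dir, paste0("in", 1:5, ".txt"))
  for (i in 1:5) writeLines(paste("payload", i), inputs[i])
  spec <- imputer_spec("external", "cp {input} {output}")
  outs <- run_external(spec, inputs, workdir = file.path(dir, "w"))
  expect_length(outs, 5)
  for (i in 1:5) expect_equal(readLines(outs[i]), paste("payload", i))
  # failure surfaces the log tail
  bad <- imputer_spec("external", "cat {input} > {output}; echo boom; false")
  expect_error(run_external(bad, inputs[1], workdir = dir),
               "boom", class = "run_error")
  # missing output is its own error
  silent <- imputer_spec("external", "cat {input} >/dev/null; : {output}")
  expect_error(run_external(silent, inputs[1], workdir = file.path(dir, "s")),
               class = "output_error")
})

test_that("a mock imputer that fills ? with a constant yields the oracle discordance", {
  p <- rand_panel(8, 10, seed = 67, alleles = c("0", "1"))
  ms <- generate_mask_set(p, 0.2, 2, seed = 68)
  dir <- withr::local_tempdir()
  masked_paths <- write_masked_files(p, ms, file.path(dir, "t"), "inp")
  # sed-based imputer: every ? becomes 0
  spec <- imputer_spec("external", "sed 's/?/0/g' {input} > {output}")
  outs <- run_external(spec, masked_paths, workdir = dir)
  imputed <- lapply(paste0(outs), function(f) {
    file.copy(f, sub("\\.imputed$", ".done.inp", f))
    read_inp(sub("\\.imputed$", ".done.inp", f))
  })
  q <- estimate_quality(p, imputed, masks = ms)
  for (k in 1:2) {
    cells <- which(ms$masks[[k]], arr.ind = TRUE)
    wrong <- sum(apply(cells, 1, function(rc)
      !identical(sort(p$calls[rc[1], rc[2], ]), c("0", "0"))))
    expect_equal(q$n_wrong[k], wrong)
  }
})
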