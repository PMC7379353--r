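# Fixture builders shared across test files. rand_panel() is deliberately
# independent of the package's own simulator so that round-trip and counting
# oracles do not share code with the paths they check.

rand_panel <- function(n = 6, l = 10, miss = 0, seed = NULL,
                       alleles = c("A", "G"), phased = TRUE,
                       with_pos = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  calls <- array(sample(alleles, n * l * 2, replace = TRUE), dim = c(n, l, 2))
  if (miss > 0) {
    hide <- matrix(runif(n * l) < miss, n, l)
    # keep at least one observed genotype per variant so allele lists and
    # VCF REF/ALT stay well defined
    for (j in which(colSums(!hide) == 0)) hide[1, j] <- FALSE
    calls[, , 1][hide] <- NA
    calls[, , 2][hide] <- NA
  }
  variants <- data.frame(
    chrom = if (with_pos) "1" else NA_character_,
    pos = if (with_pos) sort(sample.int(l * 50, l)) else NA_integer_,
    vid = sprintf("rs%04d", seq_len(l)),
    alleles = I(replicate(l, alleles, simplify = FALSE)))
  haplotype_panel(calls, variants,
                  samples = paste0("ind", seq_len(n)), phased = phased)
}

# independent brute-force discordance count over an explicit cell set
oracle_discordance <- function(truth, imputed, cells) {
  wrong <- 0L
  for (r in seq_len(nrow(cells))) {
    i <- cells[r, 1]; j <- cells[r, 2]
    tg <- sort(truth$calls[i, j, ])
    ig <- imputed$calls[i, j, ]
    if (anyNA(ig) || !identical(tg, sort(ig))) wrong <- wrong + 1L
  }
  list(n = nrow(cells), wrong = wrong, disc = wrong / nrow(cells))
}

# exact HWE p-value by direct enumeration with choose()-based probabilities
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  rare <- min(nA, 2 * n - nA)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  pr <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    # multinomial count of genotype configurations x 2^h phase factor,
    # over the total count of allele arrangements
    exp(lfactorial(n) - lfactorial(h) - lfactorial(hr) - lfactorial(hc) +
          h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) -
          lfactorial(2 * n))
  }, 1)
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# brute-force elbow: maximize perpendicular distance below the chord after
# min-max normalization, computed from the line equation (not the package's
# cross-product form)
oracle_elbow <- function(param, med) {
  nx <- (param - min(param)) / (max(param) - min(param))
  ny <- if (max(med) > min(med)) (med - min(med)) / (max(med) - min(med))
        else rep(0, length(med))
  k <- length(nx)
  slope <- (ny[k] - ny[1]) / (nx[k] - nx[1])
  # vertical gap to the chord, projected perpendicular
  gap <- (ny[1] + slope * (nx - nx[1])) - ny
  d <- gap / sqrt(1 + slope^2)
  if (max(d) <= 1e-12) return(param[1])
  param[which.max(d)]
}
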