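#' Simulation configuration
#'
#' Parameters for the synthetic panels used to exercise the whole masked-data
#' workflow without external genotype data. Defaults emulate a SNP-array
#' panel: biallelic loci, ancestral minor-allele frequencies uniform on
#' (0.05, 0.5), Balding-Nichols population divergence, and (for mosaic
#' panels) individuals copied from a small founder-haplotype pool with rare
#' template switches and copy errors.
#'
#' @param n_ind diploid samples per population.
#' @param n_loci number of biallelic loci.
#' @param n_pops number of populations.
#' @param F divergence parameter per population (recycled), in `[0, 1)`;
#'   `F = 0` means the population sits exactly at the ancestral frequencies.
#' @param freq_min,freq_max bounds of the uniform law for the ancestral
#'   allele-1 frequency.
#' @param n_founders founder haplotypes for mosaic panels.
#' @param switch_rate per-locus probability of switching founder template.
#' @param mut_rate per-site copy-error probability.
#' @param missing_rate fraction of genotype cells set missing by
#'   [inject_missing()].
#' @param seed RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_ind = 60, n_loci = 500, n_pops = 1, F = 0.05,
                       freq_min = 0.05, freq_max = 0.5, n_founders = 8,
                       switch_rate = 0.02, mut_rate = 0.005,
                       missing_rate = 0.05, seed = 1L) {
  stopifnot(n_ind >= 1, n_loci >= 1, n_pops >= 1, all(F >= 0 & F < 1),
            freq_min >= 0, freq_max <= 1, freq_min <= freq_max,
            n_founders >= 2, switch_rate >= 0, switch_rate <= 1,
            mut_rate >= 0, mut_rate <= 1, missing_rate >= 0, missing_rate < 1)
  structure(list(n_ind = n_ind, n_loci = n_loci, n_pops = n_pops,
                 F = rep_len(F, n_pops), freq_min = freq_min,
                 freq_max = freq_max, n_founders = n_founders,
                 switch_rate = switch_rate, mut_rate = mut_rate,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

sim_variants <- function(n_loci) {
  data.frame(chrom = "1", pos = seq_len(n_loci) * 100L,
             vid = sprintf("rs%06d", seq_len(n_loci)),
             alleles = I(replicate(n_loci, c("A", "B"), simplify = FALSE)))
}

#' Simulate structured populations (Balding-Nichols model)
#'
#' Per locus, an ancestral allele-1 frequency is drawn uniformly from the
#' configured bounds; each population's frequency is then drawn from a Beta
#' distribution with that mean and shape parameters `p(1-F)/F` and
#' `(1-p)(1-F)/F`, so populations with larger divergence `F` scatter further
#' from the ancestral frequency (`F = 0` is handled as a point mass). Each
#' haplotype allele is then an independent Bernoulli draw, giving
#' Hardy-Weinberg genotypes within populations. The generator's true
#' frequencies are returned so estimators can be checked against them.
#'
#' @param cfg a [sim_config()].
#' @return A list with `panel` (phased [haplotype_panel()] over alleles
#'   A/B), `true_freqs` (a `freq_table` holding the generator frequencies),
#'   and `groups` (named population assignment).
#' @export
simulate_populations <- function(cfg) {
  local_seed(cfg$seed, {
    l <- cfg$n_loci
    anc <- stats::runif(l, cfg$freq_min, cfg$freq_max)
    pops <- paste0("pop", seq_len(cfg$n_pops))
    pf <- matrix(NA_real_, l, cfg$n_pops, dimnames = list(NULL, pops))
    for (k in seq_len(cfg$n_pops)) {
      Fk <- cfg$F[k]
      pf[, k] <- if (Fk == 0) anc else
        stats::rbeta(l, anc * (1 - Fk) / Fk, (1 - anc) * (1 - Fk) / Fk)
    }
    n_total <- cfg$n_ind * cfg$n_pops
    calls <- array(NA_character_, dim = c(n_total, l, 2))
    groups <- character(n_total)
    for (k in seq_len(cfg$n_pops)) {
      rows <- (k - 1L) * cfg$n_ind + seq_len(cfg$n_ind)
      groups[rows] <- pops[k]
      for (h in 1:2) {
        hap <- matrix(stats::rbinom(length(rows) * l, 1, rep(pf[, k], each = length(rows))),
                      length(rows), l)
        calls[rows, , h] <- ifelse(hap == 1, "A", "B")
      }
    }
    samples <- paste0(rep(pops, each = cfg$n_ind), "_ind",
                      rep(seq_len(cfg$n_ind), cfg$n_pops))
    panel <- haplotype_panel(calls, sim_variants(l), samples = samples,
                             phased = TRUE, coding = "letters")
    freqs <- lapply(pops, function(p)
      cbind(pf[, p], 1 - pf[, p]))
    names(freqs) <- pops
    tf <- structure(list(populations = pops, loci = panel$variants,
                         freqs = freqs, counts = NULL),
                    class = "freq_table")
    list(panel = panel, true_freqs = tf,
         groups = stats::setNames(groups, samples))
  })
}

#' Simulate a haplotype-mosaic panel
#'
#' Emulates the haplotype-cluster structure that cluster-based imputers
#' assume: a small pool of founder haplotypes is drawn site-wise from the
#' ancestral frequencies, and every sampled haplotype copies a founder,
#' switching to a uniformly chosen founder with probability `switch_rate` at
#' each locus after the first and miscopying each allele with probability
#' `mut_rate`. Low switch and mutation rates give strong local linkage
#' disequilibrium, which is what makes the panel imputable.
#'
#' @param cfg a [sim_config()].
#' @return A phased [haplotype_panel()], with the founder haplotype matrix in
#'   attribute `"founders"` and the per-haplotype founder index paths in
#'   attribute `"paths"` (an `n_ind x n_loci x 2` integer array) so template
#'   switches can be audited.
#' @export
simulate_mosaic_panel <- function(cfg) {
  local_seed(cfg$seed, {
    l <- cfg$n_loci; nf <- cfg$n_founders
    anc <- stats::runif(l, cfg$freq_min, cfg$freq_max)
    founders <- matrix(ifelse(stats::rbinom(nf * l, 1, rep(anc, each = nf)) == 1,
                              "A", "B"), nf, l)
    n <- cfg$n_ind
    calls <- array(NA_character_, dim = c(n, l, 2))
    paths <- array(NA_integer_, dim = c(n, l, 2))
    for (i in seq_len(n)) for (h in 1:2) {
      f <- sample.int(nf, 1)
      hap <- character(l)
      for (j in seq_len(l)) {
        if (j > 1 && stats::runif(1) < cfg$switch_rate) f <- sample.int(nf, 1)
        hap[j] <- founders[f, j]
        paths[i, j, h] <- f
      }
      flip <- stats::runif(l) < cfg$mut_rate
      hap[flip] <- ifelse(hap[flip] == "A", "B", "A")
      calls[i, , h] <- hap
    }
    panel <- haplotype_panel(calls, sim_variants(l), phased = TRUE,
                             coding = "letters")
    attr(panel, "founders") <- founders
    attr(panel, "paths") <- paths
    panel
  })
}

#' Inject missingness at random
#'
#' Sets each genotype cell missing independently with the given rate and
#' returns the exact injected cell set, so downstream missingness accounting
#' can be checked against the generator.
#'
#' @param panel a [haplotype_panel()].
#' @param rate per-cell missingness probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return A list with `panel` (the degraded panel) and `injected` (logical
#'   cell matrix of the newly missing cells).
#' @export
inject_missing <- function(panel, rate, seed = 1L) {
  if (!is_fraction(rate, 0, 1, open_hi = TRUE))
    stop_fmt("argument_error", "rate must lie in [0, 1)")
  nn <- n_samples(panel); l <- n_variants(panel)
  injected <- local_seed(seed,
    matrix(stats::runif(nn * l) < rate, nn, l)) & !missing_matrix(panel)
  list(panel = apply_mask(panel, injected), injected = injected)
}
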