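#' Per-population allele frequencies
#'
#' For every population and locus, the frequency of each allele is its
#' observed count divided by twice the number of genotyped samples of that
#' population at that locus; missing genotypes are excluded from both
#' numerator and denominator. A locus with no genotyped sample in a
#' population gets an all-`NA` frequency row (flagged absent).
#'
#' @param panel a [haplotype_panel()].
#' @param groups sample-to-population assignment: a named character vector
#'   (names = sample ids), or a two-column data frame `(sample_id,
#'   population)`.
#' @return An object of class `freq_table`: list with `populations`, `loci`
#'   (the panel's variant table), and per population a `freqs` and a `counts`
#'   matrix of dimension `n_loci x max_alleles` (columns follow each locus's
#'   allele list, `NA`-padded).
#' @export
allele_frequencies <- function(panel, groups) {
  groups <- as_group_map(groups, panel)
  pops <- unique(unname(groups))
  if (any(!nzchar(pops))) stop_fmt("grouping_error", "empty population label")
  l <- n_variants(panel)
  amax <- max(lengths(panel$variants$alleles), 1L)
  freqs <- counts <- stats::setNames(vector("list", length(pops)), pops)
  for (pop in pops) {
    rows <- which(groups == pop)
    if (length(rows) == 0) stop_fmt("grouping_error", "population %s is empty", pop)
    fr <- cn <- matrix(NA_real_, l, amax)
    for (j in seq_len(l)) {
      al <- panel$variants$alleles[[j]]
      if (length(al) == 0) next
      obs <- c(panel$calls[rows, j, 1], panel$calls[rows, j, 2])
      obs <- obs[!is.na(obs)]
      cnt <- vapply(al, function(a) sum(obs == a), 1)
      cn[j, seq_along(al)] <- cnt
      if (length(obs) > 0) fr[j, seq_along(al)] <- cnt / length(obs)
    }
    freqs[[pop]] <- fr; counts[[pop]] <- cn
  }
  structure(list(populations = pops, loci = panel$variants,
                 freqs = freqs, counts = counts),
            class = "freq_table")
}

as_group_map <- function(groups, panel) {
  if (is.data.frame(groups)) {
    g <- stats::setNames(as.character(groups[[2]]), as.character(groups[[1]]))
  } else if (!is.null(names(groups))) {
    g <- groups
  } else if (length(groups) == n_samples(panel)) {
    g <- stats::setNames(as.character(groups), panel$samples)
  } else {
    stop_fmt("grouping_error", "groups must be named by sample id")
  }
  miss <- setdiff(panel$samples, names(g))
  if (length(miss))
    stop_fmt("grouping_error", "sample(s) not assigned to a population: %s",
             paste(utils::head(miss, 3), collapse = ", "))
  g[panel$samples]
}

#' Reynolds genetic distance between two populations
#'
#' Computes
#' \deqn{\Theta = \frac{\sum_j \sum_i (p_{ij} - q_{ij})^2}
#'                     {2 \sum_j (1 - \sum_i p_{ij} q_{ij})}}
#' where \eqn{p_{ij}} and \eqn{q_{ij}} are the frequencies of the i-th allele
#' at the j-th locus in the two populations: the ratio of the locus-summed
#' squared frequency differences to twice the locus-summed one-minus-shared
#' homozygosity. Loci with an absent frequency on either side are dropped.
#' When the denominator is zero (every usable locus fixed for the same allele
#' in both populations) the distance is 0, with a warning.
#'
#' @param fa,fb numeric matrices (loci in rows, alleles in columns, `NA`
#'   padding allowed) of per-locus allele frequencies, with identical locus
#'   and allele ordering.
#' @return The Reynolds distance, a single nonnegative number.
#' @export
reynolds_distance <- function(fa, fb) {
  fa <- as.matrix(fa); fb <- as.matrix(fb)
  if (!all(dim(fa) == dim(fb)))
    stop_fmt("argument_error", "frequency matrices differ in shape")
  usable <- !apply(is.na(fa), 1, all) & !apply(is.na(fb), 1, all)
  # a locus must be absent as a whole, not allele-by-allele
  if (!any(usable)) stop_fmt("degenerate_error", "zero usable loci")
  fa <- fa[usable, , drop = FALSE]; fb <- fb[usable, , drop = FALSE]
  num <- sum((fa - fb)^2, na.rm = TRUE)
  den <- 2 * sum(1 - rowSums(fa * fb, na.rm = TRUE))
  if (den == 0) {
    if (num > 0) warn_fmt("Reynolds denominator is 0 with nonzero numerator")
    return(0)
  }
  num / den
}

#' Pairwise Reynolds distance matrix
#'
#' Applies [reynolds_distance()] to every pair of populations in a frequency
#' table. Loci absent in one population of a pair are excluded for that pair
#' only.
#'
#' @param ft a `freq_table` from [allele_frequencies()].
#' @return A symmetric matrix of class `reynolds_matrix` with zero diagonal,
#'   labeled by population.
#' @export
reynolds_matrix <- function(ft) {
  pops <- ft$populations
  if (length(pops) < 2)
    stop_fmt("argument_error", ">= 2 populations required")
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (a in seq_along(pops)) for (b in seq_len(a - 1L)) {
    th <- reynolds_distance(ft$freqs[[pops[a]]], ft$freqs[[pops[b]]])
    m[a, b] <- m[b, a] <- th
  }
  structure(m, class = c("reynolds_matrix", "matrix", "array"))
}

#' @export
print.reynolds_matrix <- function(x, digits = 4, ...) {
  cat("Reynolds distances (Theta):\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test for a biallelic locus: conditional on the observed
#' allele counts, the probability of each admissible heterozygote count is
#' computed and the p-value is the sum of the probabilities of all
#' configurations no more likely than the observed one (the standard exact
#' HWE test of the kind Plink applies).
#'
#' @param n_AA,n_Aa,n_aa observed genotype counts.
#' @return The p-value.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop_fmt("argument_error", "negative counts")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop_fmt("argument_error", "at least one genotype required")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  rare <- min(nA, na)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)  # parity of the rare allele count
  # log conditional probability of each heterozygote count given allele counts
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) + lfactorial(n) - lfactorial(h) - lfactorial(hom_r) -
      lfactorial(hom_c) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, 1)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- match(n_Aa, hets)
  if (is.na(obs))
    stop_fmt("argument_error", "heterozygote count %d incompatible with allele counts", n_Aa)
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Plink-style variant filtering
#'
#' Applies, in order: minor-allele-frequency, Hardy-Weinberg, call-rate,
#' positional-duplicate and id-pattern filters, and reports how many variants
#' each step removed. MAF and HWE are computed over all samples; HWE is only
#' applied to biallelic variants. The duplicate filter removes, by default,
#' *all* variants sharing a (chrom, pos) with another (set `dedup_keep =
#' "first"` to keep the first of each group).
#'
#' @param panel a [haplotype_panel()].
#' @param maf_min drop variants with minor allele frequency below this.
#' @param callrate_min drop variants whose fraction of genotyped samples is
#'   below this.
#' @param hwe_alpha drop variants with exact HWE p-value below this.
#' @param dedup_by_pos drop positional duplicates.
#' @param dedup_keep `"none"` (drop all members of a duplicated group) or
#'   `"first"`.
#' @param id_regex when given, keep only variants whose id matches this
#'   regular expression (e.g. `"rs"`).
#' @return The filtered panel, with a `filter_report` attribute: a data frame
#'   of per-filter removal counts in application order.
#' @export
filter_variants <- function(panel, maf_min = 0, callrate_min = 0,
                            hwe_alpha = 0, dedup_by_pos = FALSE,
                            dedup_keep = c("none", "first"), id_regex = NULL) {
  dedup_keep <- match.arg(dedup_keep)
  for (th in c(maf_min, callrate_min, hwe_alpha))
    if (!is_fraction(th)) stop_fmt("argument_error", "thresholds must lie in [0, 1]")
  keep <- rep(TRUE, n_variants(panel))
  report <- data.frame(filter = character(), removed = integer())
  note <- function(name, removed_now) {
    report <<- rbind(report, data.frame(filter = name, removed = removed_now))
  }
  stats_of <- function(j) {
    obs <- c(panel$calls[, j, 1], panel$calls[, j, 2])
    obs[!is.na(obs)]
  }
  # MAF
  if (maf_min > 0) {
    maf <- vapply(seq_len(n_variants(panel)), function(j) {
      obs <- stats_of(j)
      if (length(obs) == 0) return(0)
      f <- table(obs) / length(obs)
      if (length(f) < 2) 0 else min(f)
    }, 1)
    drop <- keep & maf < maf_min
    keep[drop] <- FALSE
    note("maf", sum(drop))
  } else note("maf", 0L)
  # HWE (biallelic only)
  if (hwe_alpha > 0) {
    pv <- vapply(seq_len(n_variants(panel)), function(j) {
      if (!keep[j]) return(1)
      al <- panel$variants$alleles[[j]]
      if (length(al) != 2) return(1)
      g <- genotype_keys(panel, j)
      g <- g[!is.na(g)]
      if (length(g) == 0) return(1)
      hwe_exact_test(sum(g == paste(al[1], al[1], sep = "/")),
                     sum(g == paste(min(al), max(al), sep = "/")),
                     sum(g == paste(al[2], al[2], sep = "/")))
    }, 1)
    drop <- keep & pv < hwe_alpha
    keep[drop] <- FALSE
    note("hwe", sum(drop))
  } else note("hwe", 0L)
  # call rate
  if (callrate_min > 0) {
    cr <- 1 - colMeans(missing_matrix(panel))
    drop <- keep & cr < callrate_min
    keep[drop] <- FALSE
    note("callrate", sum(drop))
  } else note("callrate", 0L)
  # positional duplicates
  if (dedup_by_pos) {
    key <- paste(panel$variants$chrom, panel$variants$pos)
    key[is.na(panel$variants$pos)] <- NA
    kidx <- which(keep & !is.na(key))
    kk <- key[kidx]
    in_dup_group <- kk %in% kk[duplicated(kk)]
    drop_idx <- if (dedup_keep == "first") kidx[in_dup_group & duplicated(kk)]
                else kidx[in_dup_group]
    keep[drop_idx] <- FALSE
    note("dedup", length(drop_idx))
  } else note("dedup", 0L)
  # id pattern
  if (!is.null(id_regex)) {
    hit <- !is.na(panel$variants$vid) & grepl(id_regex, panel$variants$vid)
    drop <- keep & !hit
    keep[drop] <- FALSE
    note("id", sum(drop))
  } else note("id", 0L)
  out <- subset_variants(panel, which(keep))
  attr(out, "filter_report") <- report
  out
}

#' Keep a subset of variants
#' @param panel a [haplotype_panel()].
#' @param idx integer indices of the variants to keep, in order.
#' @return A [haplotype_panel()].
#' @export
subset_variants <- function(panel, idx) {
  panel$calls <- panel$calls[, idx, , drop = FALSE]
  panel$variants <- panel$variants[idx, ]
  rownames(panel$variants) <- NULL
  panel
}

#' Read a two-column sample-to-population map
#' @param path TSV with columns `sample_id` and `population` (header
#'   optional).
#' @return Named character vector, names = sample ids.
#' @export
read_population_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (identical(tolower(tab[1, 1]), "sample_id")) tab <- tab[-1, , drop = FALSE]
  stats::setNames(tab[[2]], tab[[1]])
}

#' Write a labeled distance matrix as TSV
#' @param m a `reynolds_matrix`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  utils::write.table(cbind(population = rownames(m), as.data.frame(unclass(m))),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
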