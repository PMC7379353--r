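#' Haplotype panel
#'
#' The in-memory representation shared by all readers, writers, maskers and
#' imputers: a diploid allele matrix with per-variant metadata. Calls are held
#' as an `n_samples x n_variants x 2` character array of allele codes; a
#' missing genotype has both slots `NA` (a genotype is treated as a unit:
#' half-missing input genotypes are stored fully missing).
#'
#' @param calls character array of dimension `c(n_samples, n_variants, 2)`;
#'   `NA` marks a missing allele slot.
#' @param variants data frame with columns `chrom` (character), `pos`
#'   (integer, `NA` allowed), `vid` (character, `NA` allowed) and `alleles`
#'   (list column of character vectors, the ordered allele codes per variant;
#'   for VCF sources REF first).
#' @param samples character vector of sample identifiers.
#' @param phased logical flag: `TRUE` when the source encodes haplotypes
#'   (fastPHASE `.inp` lines, or `|`-separated VCF genotypes throughout).
#' @param coding `"letters"` or `"numeric"`, as in the source file.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(calls, variants, samples = NULL, phased = FALSE,
                            coding = c("letters", "numeric")) {
  coding <- match.arg(coding)
  if (!is.array(calls) || length(dim(calls)) != 3 || dim(calls)[3] != 2)
    stop_fmt("panel_error", "calls must be an N x L x 2 array")
  n <- dim(calls)[1]; l <- dim(calls)[2]
  if (is.null(samples)) samples <- paste0("sample_", seq_len(n))
  if (length(samples) != n)
    stop_fmt("panel_error", "%d sample ids for %d samples", length(samples), n)
  if (anyDuplicated(samples))
    stop_fmt("panel_error", "duplicated sample ids")
  if (!is.data.frame(variants) || nrow(variants) != l)
    stop_fmt("panel_error", "variants table has %d rows for %d variants",
             NROW(variants), l)
  need <- c("chrom", "pos", "vid", "alleles")
  for (col in setdiff(need, names(variants))) {
    variants[[col]] <- if (col == "alleles") replicate(l, character(), FALSE)
                       else rep(NA, l)
  }
  variants <- variants[need]
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$vid <- as.character(variants$vid)
  if (any(!is.na(variants$pos) & variants$pos < 1))
    stop_fmt("panel_error", "variant positions must be >= 1")
  # enforce the genotype-level missingness convention
  miss <- is.na(calls[, , 1, drop = FALSE]) | is.na(calls[, , 2, drop = FALSE])
  if (any(miss)) {
    idx <- which(array(miss, dim = c(n, l)))
    calls[, , 1][idx] <- NA_character_
    calls[, , 2][idx] <- NA_character_
  }
  dimnames(calls) <- list(samples, NULL, NULL)
  # every non-missing slot must be listed in the variant's alleles
  for (j in seq_len(l)) {
    seen <- unique(stats::na.omit(c(calls[, j, ])))
    al <- variants$alleles[[j]]
    if (anyDuplicated(al))
      stop_fmt("panel_error", "duplicated allele codes at variant %d", j)
    if (length(al) == 0) {
      variants$alleles[[j]] <- sort(seen)
    } else if (!all(seen %in% al)) {
      stop_fmt("panel_error",
               "variant %d carries allele code(s) %s absent from its allele list",
               j, paste(setdiff(seen, al), collapse = ","))
    }
  }
  structure(list(calls = calls, variants = variants, samples = samples,
                 phased = isTRUE(phased), coding = coding),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d samples x %d variants (%s, %s coding)\n",
              n_samples(x), n_variants(x),
              if (x$phased) "phased" else "unphased", x$coding))
  nm <- sum(missing_matrix(x))
  cat(sprintf("  missing genotypes: %d / %d (%.2f%%)\n", nm,
              n_samples(x) * n_variants(x),
              100 * nm / max(1, n_samples(x) * n_variants(x))))
  invisible(x)
}

#' Panel dimensions
#' @param panel a [haplotype_panel()].
#' @return integer count.
#' @export
n_samples <- function(panel) dim(panel$calls)[1]

#' @rdname n_samples
#' @export
n_variants <- function(panel) dim(panel$calls)[2]

#' Missingness matrix
#'
#' Logical `n_samples x n_variants` matrix, `TRUE` where the genotype is
#' missing.
#'
#' @param panel a [haplotype_panel()].
#' @return logical matrix.
#' @export
missing_matrix <- function(panel) {
  m <- is.na(panel$calls[, , 1])
  if (is.null(dim(m))) m <- matrix(m, n_samples(panel), n_variants(panel))
  dimnames(m) <- list(panel$samples, NULL)
  m
}

#' Read a haplotype panel, dispatching on file extension
#'
#' `.inp` goes to [read_inp()], `.vcf` and `.vcf.gz` to [read_vcf()].
#'
#' @param path input file.
#' @return A [haplotype_panel()].
#' @export
read_panel <- function(path) {
  if (grepl("\\.inp$", path)) return(read_inp(path))
  if (grepl("\\.vcf(\\.gz)?$", path)) return(read_vcf(path))
  stop_fmt("usage_error", "unrecognized panel extension: %s (want .inp/.vcf/.vcf.gz)",
           basename(path))
}

#' Write a haplotype panel, dispatching on file extension
#' @param panel a [haplotype_panel()].
#' @param path output file (`.inp`, `.vcf` or `.vcf.gz`).
#' @param ... passed to [write_inp()] or [write_vcf()].
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, ...) {
  if (grepl("\\.inp$", path)) return(write_inp(panel, path, ...))
  if (grepl("\\.vcf(\\.gz)?$", path)) return(write_vcf(panel, path))
  stop_fmt("usage_error", "unrecognized panel extension: %s", basename(path))
}

# unordered genotype string per cell ("A/G", sorted), NA when missing
genotype_keys <- function(panel, j) {
  a <- panel$calls[, j, 1]; b <- panel$calls[, j, 2]
  ifelse(is.na(a), NA_character_,
         paste(pmin(a, b), pmax(a, b), sep = "/"))
}
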