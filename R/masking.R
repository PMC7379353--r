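#' Locate already-missing genotypes
#'
#' Returns the cells whose genotype is missing in the source panel, as a
#' two-column matrix of (sample index, variant index). Mask generation
#' excludes these cells so that masked-then-recovered missingness identifies
#' the mask exactly.
#'
#' @param panel a [haplotype_panel()].
#' @return integer matrix with columns `sample` and `variant`.
#' @export
find_missing <- function(panel) {
  idx <- which(missing_matrix(panel), arr.ind = TRUE)
  colnames(idx) <- c("sample", "variant")
  rownames(idx) <- NULL
  idx
}

#' Generate a set of non-repeating masks
#'
#' Draws `n` pairwise-disjoint masks over the panel. In `"genotype"` mode
#' each mask hides, at every variant, exactly `m = round(p * N)` genotype
#' cells (rounding half away from zero), sampled uniformly without
#' replacement from the cells of that column that are neither missing in the
#' source nor claimed by an earlier mask; this is the per-locus masking used
#' to benchmark "hole-filling" imputation, and it requires
#' `n * m + pre-missing(column) <= N` at every column. In `"snp"` mode each
#' mask hides `m_s = round(p * L)` whole variant columns, drawn without
#' replacement across the whole set (`n * m_s <= L`); pre-existing
#' missingness does not constrain which columns may be chosen.
#'
#' Because masks never overlap each other or the source's missing cells, the
#' set explores the space of possible missingness patterns like a
#' cross-validation partition with a free number of folds. Note that masked
#' outputs therefore carry overall missingness above `p` whenever the source
#' already has missing genotypes.
#'
#' @param panel a [haplotype_panel()].
#' @param p masking proportion, `0 < p < 1`.
#' @param n number of masks.
#' @param mode `"genotype"` or `"snp"`.
#' @param seed RNG seed; identical arguments give an identical mask set.
#' @return An object of class `mask_set`: a list with `masks` (list of `n`
#'   logical `N x L` matrices), `mode`, `p`, `n`, `seed`, `pre_missing`
#'   (logical matrix) and, in snp mode, `snp_columns` (list of masked column
#'   indices per mask).
#' @export
generate_mask_set <- function(panel, p, n, mode = c("genotype", "snp"), seed = 1L) {
  mode <- match.arg(mode)
  if (!is_fraction(p, 0, 1, open_lo = TRUE, open_hi = TRUE))
    stop_fmt("argument_error", "p must be a fraction in (0, 1), got %s", format(p))
  if (!is_count(n)) stop_fmt("argument_error", "n must be a positive integer")
  n <- as.integer(n)
  nn <- n_samples(panel); l <- n_variants(panel)
  pre <- missing_matrix(panel)
  masks <- replicate(n, matrix(FALSE, nn, l), simplify = FALSE)
  snp_columns <- NULL
  if (mode == "genotype") {
    m <- as.integer(round_half_up(p * nn))
    if (m < 1) stop_fmt("argument_error", "p = %s masks 0 cells per column", format(p))
    pre_col <- colSums(pre)
    bad <- which(n * m + pre_col > nn)
    if (length(bad)) {
      worst <- bad[which.max(pre_col[bad])]
      stop_fmt("capacity_error",
               "cannot draw %d masks of %d cells per column: column %d has only %d maskable cells",
               n, m, worst, nn - pre_col[worst])
    }
    local_seed(seed, {
      # draw order fixed: columns outer, masks inner
      for (j in seq_len(l)) {
        avail <- which(!pre[, j])
        for (k in seq_len(n)) {
          pick <- if (length(avail) == 1) avail else sample(avail, m)
          masks[[k]][pick, j] <- TRUE
          avail <- setdiff(avail, pick)
        }
      }
    })
  } else {
    ms <- as.integer(round_half_up(p * l))
    if (ms < 1) stop_fmt("argument_error", "p = %s masks 0 variants per mask", format(p))
    if (n * ms > l)
      stop_fmt("capacity_error",
               "cannot draw %d masks of %d variants from %d variants without replacement",
               n, ms, l)
    local_seed(seed, {
      cols <- sample(seq_len(l), n * ms)
      snp_columns <- split(cols, rep(seq_len(n), each = ms))
      names(snp_columns) <- NULL
      for (k in seq_len(n)) {
        masks[[k]][, snp_columns[[k]]] <- TRUE
        masks[[k]][pre] <- FALSE  # a pre-missing cell is nobody's mask cell
      }
    })
  }
  structure(list(masks = masks, mode = mode, p = p, n = n,
                 seed = as.integer(seed), pre_missing = pre,
                 snp_columns = snp_columns),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("mask_set: %d %s-mode masks, p = %s, seed = %d\n",
              x$n, x$mode, format(x$p), x$seed))
  cat(sprintf("  cells per mask: %s\n",
              paste(vapply(x$masks, sum, 1), collapse = ", ")))
  invisible(x)
}

#' Apply one mask to a panel
#'
#' Returns a copy of the panel in which every masked cell has both allele
#' slots missing; all other cells are untouched.
#'
#' @param panel a [haplotype_panel()].
#' @param mask a logical `N x L` matrix, or a two-column (sample, variant)
#'   index matrix as returned by [find_missing()].
#' @return A [haplotype_panel()].
#' @export
apply_mask <- function(panel, mask) {
  nn <- n_samples(panel); l <- n_variants(panel)
  if (is.matrix(mask) && is.logical(mask)) {
    if (!all(dim(mask) == c(nn, l)))
      stop_fmt("index_error", "mask is %dx%d for a %dx%d panel",
               nrow(mask), ncol(mask), nn, l)
    idx <- which(mask)
  } else {
    mask <- as.matrix(mask)
    if (nrow(mask) > 0 &&
        (any(mask[, 1] < 1 | mask[, 1] > nn) || any(mask[, 2] < 1 | mask[, 2] > l)))
      stop_fmt("index_error", "mask cell outside the %dx%d panel", nn, l)
    idx <- (mask[, 2] - 1L) * nn + mask[, 1]
  }
  panel$calls[, , 1][idx] <- NA_character_
  panel$calls[, , 2][idx] <- NA_character_
  panel
}

#' Write the masked test files for a mask set
#'
#' Produces one data file per mask, named `<out_prefix>.mask<k>.<ext>`, plus
#' a sidecar manifest `<out_prefix>.masks.tsv` recording every masked cell,
#' so discordance can later be computed in a separate process. The files are
#' ready to be handed to an imputation program.
#'
#' @param panel a [haplotype_panel()].
#' @param maskset a `mask_set` from [generate_mask_set()].
#' @param out_prefix output path prefix.
#' @param format `"inp"`, `"vcf"` or `"vcf.gz"`.
#' @param include_ids for `.inp` output, write sample id lines.
#' @return Character vector of the data file paths, in mask order, with the
#'   manifest path in attribute `"manifest"`.
#' @export
write_masked_files <- function(panel, maskset, out_prefix,
                               format = c("inp", "vcf", "vcf.gz"),
                               include_ids = FALSE) {
  format <- match.arg(format)
  if (!all(dim(maskset$pre_missing) == c(n_samples(panel), n_variants(panel))))
    stop_fmt("argument_error", "mask set was generated for a different panel shape")
  paths <- character(maskset$n)
  for (k in seq_len(maskset$n)) {
    paths[k] <- paste0(out_prefix, ".mask", k, ".", format)
    masked <- apply_mask(panel, maskset$masks[[k]])
    if (format == "inp") write_inp(masked, paths[k], include_ids = include_ids)
    else write_vcf(masked, paths[k])
  }
  manifest <- paste0(out_prefix, ".masks.tsv")
  write_mask_manifest(maskset, panel, manifest)
  attr(paths, "manifest") <- manifest
  paths
}

#' Write / read a mask manifest
#'
#' The manifest is a TSV with columns `mask_index`, `sample_id`, `chrom`,
#' `pos`, `variant_index`, one row per masked cell, preceded by comment lines
#' recording the generation parameters (mode, p, n, seed, RNG algorithm).
#'
#' @param maskset a `mask_set`.
#' @param panel the panel the masks were drawn on (for sample ids and
#'   positions).
#' @param path manifest path (gzip when ending `.gz`).
#' @return `path` invisibly for the writer; for the reader, a `mask_set`-like
#'   object with logical mask matrices (and `pre_missing` of all-`FALSE`,
#'   since the manifest does not record the source's own missingness).
#' @export
write_mask_manifest <- function(maskset, panel, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# haplomask mask manifest"),
    sprintf("# mode=%s p=%s n=%d seed=%d rng=%s", maskset$mode,
            format(maskset$p), maskset$n, maskset$seed, RNGkind()[1]),
    sprintf("# samples=%d variants=%d", n_samples(panel), n_variants(panel)),
    paste(c("mask_index", "sample_id", "chrom", "pos", "variant_index"),
          collapse = "\t")), con)
  for (k in seq_along(maskset$masks)) {
    cells <- which(maskset$masks[[k]], arr.ind = TRUE)
    if (nrow(cells) == 0) next
    cells <- cells[order(cells[, 2], cells[, 1]), , drop = FALSE]
    writeLines(paste(k, panel$samples[cells[, 1]],
                     ifelse(is.na(panel$variants$chrom[cells[, 2]]), ".",
                            panel$variants$chrom[cells[, 2]]),
                     ifelse(is.na(panel$variants$pos[cells[, 2]]), ".",
                            panel$variants$pos[cells[, 2]]),
                     cells[, 2], sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_mask_manifest
#' @export
read_mask_manifest <- function(path, panel) {
  lines <- readLines(path)
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)], sep = "\t",
                           colClasses = c("integer", "character", "character",
                                          "character", "integer"))
  si <- match(tab$sample_id, panel$samples)
  if (anyNA(si))
    stop_fmt("alignment_error", "%s: manifest sample '%s' absent from the panel",
             path, tab$sample_id[which(is.na(si))[1]])
  if (nrow(tab) > 0 && max(tab$variant_index) > n_variants(panel))
    stop_fmt("alignment_error", "%s: manifest variant index %d exceeds panel (%d variants)",
             path, max(tab$variant_index), n_variants(panel))
  nmask <- if (nrow(tab)) max(tab$mask_index) else 0L
  masks <- lapply(seq_len(nmask), function(k) {
    m <- matrix(FALSE, n_samples(panel), n_variants(panel))
    rows <- tab$mask_index == k
    m[cbind(si[rows], tab$variant_index[rows])] <- TRUE
    m
  })
  structure(list(masks = masks, mode = NA_character_, p = NA_real_,
                 n = nmask, seed = NA_integer_,
                 pre_missing = missing_matrix(panel), snp_columns = NULL),
            class = "mask_set")
}
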