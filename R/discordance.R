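#' Compare one true genotype with its imputed value
#'
#' Genotypes are compared as unordered allele pairs: the imputed cell is
#' concordant when its two alleles, regardless of phase, coincide with the
#' true ones, and discordant when one or both alleles differ. An imputed
#' genotype that is still missing counts as discordant.
#'
#' @param truth character vector of length 2, the true alleles (non-missing).
#' @param imputed character vector of length 2; `NA` slots mean the imputer
#'   left the cell missing.
#' @return `TRUE` when concordant, `FALSE` when discordant.
#' @export
compare_genotypes <- function(truth, imputed) {
  if (anyNA(truth)) stop_fmt("argument_error", "truth genotype must be non-missing")
  if (anyNA(imputed)) return(FALSE)
  all(sort(truth) == sort(imputed))
}

#' Estimate imputation quality over masked cells
#'
#' The central statistic of masked data analysis: the proportion of masked
#' genotypes imputed wrongly, where "wrongly" means one or both alleles
#' differ from the original (phase ignored). One record is produced per
#' imputed file/panel. The evaluated cell set for the k-th record is
#' `masks[[k]]` when a mask set (or manifest) is supplied; otherwise it is
#' recovered by diffing missingness between the k-th *masked* input and the
#' truth, which requires `masked` to be given. Cells missing in the truth
#' itself are never evaluated.
#'
#' @param truth the original [haplotype_panel()] (or a path to one).
#' @param imputed list of imputed panels or file paths, in mask order.
#' @param masks a `mask_set`, a manifest path, or `NULL`.
#' @param masked list of masked input panels/paths, needed only when
#'   `masks` is `NULL`.
#' @param id free-form label copied into every record (e.g. the K value of
#'   the imputation run).
#' @return A data frame of class `discordance_table` with columns `id`,
#'   `mask_index`, `n_masked`, `n_wrong`, `discordance`.
#' @export
estimate_quality <- function(truth, imputed, masks = NULL, masked = NULL,
                             id = NA_character_) {
  if (is.character(truth) && length(truth) == 1) truth <- read_panel(truth)
  if (!is.list(imputed) || inherits(imputed, "haplotype_panel"))
    imputed <- list(imputed)
  imputed <- lapply(imputed, function(x)
    if (is.character(x)) read_panel(x) else x)
  if (is.character(masks) && length(masks) == 1)
    masks <- read_mask_manifest(masks, truth)
  if (is.null(masks)) {
    if (is.null(masked))
      stop_fmt("argument_error",
               "either a mask set/manifest or the masked input files are required")
    if (!is.list(masked) || inherits(masked, "haplotype_panel"))
      masked <- list(masked)
    masked <- lapply(masked, function(x)
      if (is.character(x)) read_panel(x) else x)
    if (length(masked) != length(imputed))
      stop_fmt("usage_error", "%d masked files for %d imputed files",
               length(masked), length(imputed))
  } else if (length(masks$masks) != length(imputed)) {
    stop_fmt("usage_error", "%d masks for %d imputed files",
             length(masks$masks), length(imputed))
  }
  truth_miss <- missing_matrix(truth)
  out <- vector("list", length(imputed))
  still_missing <- 0L
  for (k in seq_along(imputed)) {
    imp <- align_panels(truth, imputed[[k]], what = sprintf("imputed file %d", k))
    eval_mask <- if (!is.null(masks)) {
      masks$masks[[k]] & !truth_miss
    } else {
      msk <- align_panels(truth, masked[[k]], what = sprintf("masked file %d", k))
      missing_matrix(msk) & !truth_miss
    }
    cells <- which(eval_mask, arr.ind = TRUE)
    if (nrow(cells) == 0)
      stop_fmt("degenerate_error", "mask %d evaluates zero genotype cells", k)
    idx <- (cells[, 2] - 1L) * n_samples(truth) + cells[, 1]
    t1 <- truth$calls[, , 1][idx]; t2 <- truth$calls[, , 2][idx]
    i1 <- imp$calls[, , 1][idx];   i2 <- imp$calls[, , 2][idx]
    conc <- (pmin(t1, t2) == pmin(i1, i2)) & (pmax(t1, t2) == pmax(i1, i2))
    nm <- is.na(conc)  # imputer left the cell missing -> discordant
    still_missing <- still_missing + sum(nm)
    n_wrong <- sum(!conc, na.rm = TRUE) + sum(nm)
    out[[k]] <- data.frame(id = id, mask_index = k,
                           n_masked = nrow(cells), n_wrong = n_wrong,
                           discordance = n_wrong / nrow(cells))
  }
  if (still_missing > 0)
    warn_fmt("%d masked genotype(s) were still missing after imputation; counted as discordant",
             still_missing)
  res <- do.call(rbind, out)
  class(res) <- c("discordance_table", "data.frame")
  res
}

#' @export
print.discordance_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, ...)
  if (nrow(x) > 1)
    cat(sprintf("median (SD): %.4g (%.2g)\n",
                stats::median(x$discordance), stats::sd(x$discordance)))
  invisible(x)
}

#' Write / read the discordance TSV consumed by model selection
#' @param x a `discordance_table` (or rbind of several).
#' @param path TSV path.
#' @return `path` (writer) or the table (reader), invisibly/visibly.
#' @export
write_discordance <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_discordance
#' @export
read_discordance <- function(path) {
  res <- utils::read.delim(path, sep = "\t",
                           colClasses = c("character", "integer", "integer",
                                          "integer", "numeric"))
  class(res) <- c("discordance_table", "data.frame")
  res
}

# reorder `other` to truth's sample and variant order; strict checks
align_panels <- function(truth, other, what = "panel") {
  if (!inherits(other, "haplotype_panel"))
    stop_fmt("argument_error", "%s is not a haplotype panel", what)
  # samples: match by id when both sides look like real ids, else by index
  if (n_samples(other) != n_samples(truth))
    stop_fmt("alignment_error", "%s has %d samples, truth has %d",
             what, n_samples(other), n_samples(truth))
  if (!setequal(truth$samples, other$samples)) {
    auto <- function(s) all(grepl("^sample_[0-9]+$", s))
    if (!auto(truth$samples) && !auto(other$samples))
      stop_fmt("alignment_error", "%s: sample ids diverge (first: %s vs %s)",
               what, setdiff(truth$samples, other$samples)[1],
               setdiff(other$samples, truth$samples)[1])
    # auto-generated ids on one side: trust the ordering
  } else if (!identical(truth$samples, other$samples)) {
    perm <- match(truth$samples, other$samples)
    other$calls <- other$calls[perm, , , drop = FALSE]
    other$samples <- truth$samples
  }
  if (n_variants(other) != n_variants(truth))
    stop_fmt("alignment_error", "%s has %d variants, truth has %d",
             what, n_variants(other), n_variants(truth))
  tp <- truth$variants$pos; op <- other$variants$pos
  if (!anyNA(tp) && !anyNA(op)) {
    # .inp files carry positions but no chromosome; key on position alone
    # unless both sides have chromosome labels
    with_chrom <- !anyNA(truth$variants$chrom) && !anyNA(other$variants$chrom)
    tk <- if (with_chrom) paste(truth$variants$chrom, tp) else as.character(tp)
    ok <- if (with_chrom) paste(other$variants$chrom, op) else as.character(op)
    if (!identical(tk, ok)) {
      perm <- match(tk, ok)
      if (anyNA(perm))
        stop_fmt("alignment_error", "%s: variant %s not found",
                 what, tk[which(is.na(perm))[1]])
      other$calls <- other$calls[, perm, , drop = FALSE]
      other$variants <- other$variants[perm, ]
    }
  }
  other
}
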