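#' Read a VCF file into a haplotype panel
#'
#' Parsing is done with \pkg{vcfR}; only the GT subfield is used. Allele
#' indices are mapped to the REF/ALT codes, so the panel stores actual allele
#' strings. A genotype containing any `.` allele (including half-missing
#' calls like `0/.`) becomes fully missing. The panel is flagged phased only
#' when every non-missing genotype uses the `|` separator; a mix of `|` and
#' `/` yields an unphased panel with a warning. Non-diploid genotypes are an
#' error.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @return A [haplotype_panel()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop_fmt("io_error", "no such file: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  l <- nrow(fix)
  if (is.null(gt) || ncol(gt) < 2)
    stop_fmt("format_error", "%s: no genotype columns", path)
  samples <- colnames(gt)[-1]
  n <- length(samples)
  alleles <- lapply(seq_len(l), function(j) {
    alt <- fix[j, "ALT"]
    c(fix[j, "REF"],
      if (!is.na(alt) && alt != ".") strsplit(alt, ",", fixed = TRUE)[[1]])
  })
  # GT position within FORMAT, per record
  fmt <- strsplit(gt[, 1], ":", fixed = TRUE)
  gt_idx <- vapply(fmt, function(f) match("GT", f), 1L)
  if (anyNA(gt_idx))
    stop_fmt("format_error", "%s: record %d lacks GT in FORMAT",
             path, which(is.na(gt_idx))[1])
  calls <- array(NA_character_, dim = c(n, l, 2))
  n_pipe <- 0L; n_slash <- 0L
  for (j in seq_len(l)) {
    raw <- gt[j, -1]
    g <- if (gt_idx[j] == 1L) sub(":.*$", "", raw)
         else vapply(strsplit(raw, ":", fixed = TRUE), `[`, "", gt_idx[j])
    g[is.na(g)] <- "."
    for (i in seq_len(n)) {
      toks <- strsplit(g[i], "[/|]")[[1]]
      if (length(toks) == 1 && toks[1] == ".") next  # fully missing, no ploidy
      if (length(toks) != 2)
        stop_fmt("ploidy_error",
                 "%s: non-diploid genotype '%s' for sample %s at %s:%s",
                 path, g[i], samples[i], fix[j, "CHROM"], fix[j, "POS"])
      if (grepl("|", g[i], fixed = TRUE)) n_pipe <- n_pipe + 1L
      else n_slash <- n_slash + 1L
      if (any(toks == ".")) next
      calls[i, j, ] <- alleles[[j]][as.integer(toks) + 1L]
    }
  }
  if (n_pipe > 0L && n_slash > 0L)
    warn_fmt("%s: mixed '|' and '/' separators; panel treated as unphased", path)
  coding <- if (all(grepl("^[0-9]+$", unlist(alleles)))) "numeric" else "letters"
  haplotype_panel(
    calls,
    data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
               vid = ifelse(fix[, "ID"] == ".", NA_character_, fix[, "ID"]),
               alleles = I(alleles)),
    samples = samples, phased = n_pipe > 0L && n_slash == 0L, coding = coding)
}

#' Write a haplotype panel as a minimal GT-only VCF
#'
#' Every variant must carry a chromosome and position. Genotypes are written
#' as allele indices into the variant's allele list, `|`-separated when the
#' panel is phased and `/`-separated otherwise; missing genotypes become
#' `./.`. The output is gzip-compressed when `path` ends in `.gz`.
#'
#' @param panel a [haplotype_panel()].
#' @param path output path (`.vcf` or `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  vt <- panel$variants
  if (anyNA(vt$chrom) || anyNA(vt$pos))
    stop_fmt("metadata_error",
             "VCF output requires chrom and pos on every variant (variant %d lacks them)",
             which(is.na(vt$chrom) | is.na(vt$pos))[1])
  if (any(lengths(vt$alleles) < 1))
    stop_fmt("metadata_error", "VCF output requires >= 1 allele per variant")
  sep <- if (panel$phased) "|" else "/"
  n <- n_samples(panel); l <- n_variants(panel)
  rows <- character(l)
  for (j in seq_len(l)) {
    al <- vt$alleles[[j]]
    i1 <- match(panel$calls[, j, 1], al) - 1L
    i2 <- match(panel$calls[, j, 2], al) - 1L
    g <- ifelse(is.na(i1), "./.", paste0(i1, sep, i2))
    rows[j] <- paste(c(vt$chrom[j], vt$pos[j],
                       ifelse(is.na(vt$vid[j]), ".", vt$vid[j]),
                       al[1],
                       if (length(al) > 1) paste(al[-1], collapse = ",") else ".",
                       ".", ".", ".", "GT", g), collapse = "\t")
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=haplomask",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$samples), collapse = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}
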