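#' Read a fastPHASE `.inp` haplotype file
#'
#' The format: line 1 holds the number of individuals N, line 2 the number of
#' sites L, then an optional positions line starting with `P`, then either
#' three lines per individual (an id line followed by two haplotype strings)
#' or two haplotype strings per individual. The dialect is auto-detected from
#' the line count: 3N remaining lines means ids are present, 2N means they are
#' not; anything else is a format error. Alleles may be letters or digits;
#' `?` marks a missing allele and missingness is promoted to the whole
#' genotype.
#'
#' @param path path to the `.inp` file.
#' @return A phased [haplotype_panel()].
#' @export
read_inp <- function(path) {
  if (!file.exists(path)) stop_fmt("io_error", "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) < 2)
    stop_fmt("format_error", "%s: need at least N and L header lines", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  l <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n <= 0 || is.na(l) || l <= 0)
    stop_fmt("format_error", "%s: header must be two positive integers (N, L)", path)
  body <- lines[-(1:2)]
  pos <- rep(NA_integer_, l)
  has_pos <- length(body) > 0 && grepl("^P($|[ \t])", body[1])
  if (has_pos) {
    toks <- strsplit(trimws(body[1]), "[ \t]+")[[1]][-1]
    if (length(toks) != l)
      stop_fmt("format_error", "%s: P line has %d positions, expected %d",
               path, length(toks), l)
    pos <- as.integer(toks)
    body <- body[-1]
  }
  with_ids <- if (length(body) == 3L * n) TRUE
              else if (length(body) == 2L * n) FALSE
              else stop_fmt("format_error",
                "%s: %d body lines fit neither the id dialect (%d) nor the plain dialect (%d)",
                path, length(body), 3L * n, 2L * n)
  per <- if (with_ids) 3L else 2L
  samples <- character(n)
  calls <- array(NA_character_, dim = c(n, l, 2))
  hdr_offset <- 2L + has_pos
  for (i in seq_len(n)) {
    block <- body[(i - 1L) * per + seq_len(per)]
    if (with_ids) {
      samples[i] <- sub("^#\\s*", "", trimws(block[1]))
      block <- block[-1]
    }
    for (h in 1:2) {
      hap <- trimws(block[h])
      if (nchar(hap) != l)
        stop_fmt("format_error",
                 "%s line %d: haplotype has %d sites, expected %d",
                 path, hdr_offset + (i - 1L) * per + (if (with_ids) 1L else 0L) + h,
                 nchar(hap), l)
      calls[i, , h] <- strsplit(hap, "")[[1]]
    }
  }
  calls[calls == "?"] <- NA_character_
  if (!with_ids) samples <- paste0("sample_", seq_len(n))
  alleles <- lapply(seq_len(l), function(j)
    sort(unique(stats::na.omit(c(calls[, j, ])))))
  coding <- if (all(grepl("^[0-9]*$", unlist(alleles)))) "numeric" else "letters"
  haplotype_panel(
    calls,
    data.frame(chrom = NA_character_, pos = pos, vid = NA_character_,
               alleles = I(alleles)),
    samples = samples, phased = TRUE, coding = coding)
}

#' Write a haplotype panel as a fastPHASE `.inp` file
#'
#' Emits the N and L header lines, a `P` positions line when every variant
#' carries a position, then per sample (optionally) a `# id` line and the two
#' haplotype strings with `?` at missing slots. The format is one character
#' per site; panels whose allele codes are longer (multiallelic VCF indels,
#' say) are recoded to digits `0..9` when each variant has at most ten
#' alleles, and rejected otherwise.
#'
#' @param panel a [haplotype_panel()].
#' @param path output path.
#' @param include_ids write `# <sample id>` lines before each haplotype pair.
#' @return `path`, invisibly.
#' @export
write_inp <- function(panel, path, include_ids = FALSE) {
  n <- n_samples(panel); l <- n_variants(panel)
  if (n == 0 || l == 0) stop_fmt("panel_error", "cannot write an empty panel")
  calls <- panel$calls
  wide <- vapply(panel$variants$alleles, function(a) any(nchar(a) > 1), TRUE)
  if (any(wide)) {
    sizes <- lengths(panel$variants$alleles)
    if (any(wide & sizes > 10))
      stop_fmt("coding_error",
               ".inp is one character per site; variant %d has %d multi-character alleles",
               which(wide & sizes > 10)[1], sizes[which(wide & sizes > 10)[1]])
    for (j in which(wide)) {
      al <- panel$variants$alleles[[j]]
      calls[, j, ] <- as.character(match(calls[, j, ], al) - 1L)
    }
  }
  calls[is.na(calls)] <- "?"
  out <- c(as.character(n), as.character(l))
  if (l > 0 && !anyNA(panel$variants$pos))
    out <- c(out, paste("P", paste(panel$variants$pos, collapse = " ")))
  for (i in seq_len(n)) {
    if (include_ids) out <- c(out, paste("#", panel$samples[i]))
    out <- c(out, paste(calls[i, , 1], collapse = ""),
                  paste(calls[i, , 2], collapse = ""))
  }
  writeLines(out, path)
  invisible(path)
}
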