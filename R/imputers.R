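#' Baseline imputer: modal genotype per locus
#'
#' Fills every missing genotype at a locus with the most frequent observed
#' unordered genotype of that locus; ties are broken by lexicographic order
#' of the sorted genotype string. A locus with no observed genotype at all is
#' filled homozygous for the variant's first-listed allele (and a message is
#' emitted). Deliberately naive: its error has a closed form on
#' Hardy-Weinberg data, which makes it a truth oracle for the discordance
#' machinery rather than a competitive imputer.
#'
#' @param masked a [haplotype_panel()] with missing genotypes.
#' @return A fully observed [haplotype_panel()].
#' @export
impute_major_allele <- function(masked) {
  miss <- missing_matrix(masked)
  degenerate <- 0L
  for (j in which(colSums(miss) > 0)) {
    g <- genotype_keys(masked, j)
    g <- g[!is.na(g)]
    fill <- if (length(g) == 0) {
      degenerate <- degenerate + 1L
      al <- masked$variants$alleles[[j]]
      if (length(al) == 0) stop_fmt("degenerate_error",
        "variant %d has no observed genotypes and no allele list", j)
      c(al[1], al[1])
    } else {
      tab <- table(g)
      best <- sort(names(tab)[tab == max(tab)])[1]
      strsplit(best, "/", fixed = TRUE)[[1]]
    }
    rows <- which(miss[, j])
    masked$calls[rows, j, 1] <- fill[1]
    masked$calls[rows, j, 2] <- fill[2]
  }
  if (degenerate > 0)
    message(sprintf("%d locus/loci had no observed genotypes; filled with the first-listed allele",
                    degenerate))
  masked
}

#' Baseline imputer: sample from observed allele frequencies
#'
#' Each missing genotype's two alleles are drawn independently from the
#' locus's observed allele frequencies. Seeded and reproducible. Loci without
#' any observed allele are filled homozygous for the first-listed allele.
#'
#' @param masked a [haplotype_panel()] with missing genotypes.
#' @param seed RNG seed.
#' @return A fully observed [haplotype_panel()].
#' @export
impute_frequency_sample <- function(masked, seed = 1L) {
  miss <- missing_matrix(masked)
  local_seed(seed, {
    for (j in which(colSums(miss) > 0)) {
      obs <- c(masked$calls[, j, 1], masked$calls[, j, 2])
      obs <- obs[!is.na(obs)]
      rows <- which(miss[, j])
      if (length(obs) == 0) {
        al <- masked$variants$alleles[[j]]
        masked$calls[rows, j, ] <- al[1]
      } else {
        al <- sort(unique(obs))
        f <- vapply(al, function(a) mean(obs == a), 1)
        masked$calls[rows, j, 1] <- sample(al, length(rows), TRUE, prob = f)
        masked$calls[rows, j, 2] <- sample(al, length(rows), TRUE, prob = f)
      }
    }
  })
  masked
}

#' Specify an imputer
#'
#' @param kind `"major_allele"`, `"freq_sample"`, or `"external"` (a shell
#'   command template).
#' @param command_template for external imputers, a shell template containing
#'   the placeholders `{input}` and `{output}` exactly once each.
#' @param params free-form key-value list recorded for provenance (e.g. the
#'   haplotype-cluster count `K`, EM cycle count, EM starts).
#' @param seed seed for the `freq_sample` imputer.
#' @return An object of class `imputer_spec`.
#' @export
imputer_spec <- function(kind = c("major_allele", "freq_sample", "external"),
                         command_template = NULL, params = list(), seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "external") {
    if (is.null(command_template))
      stop_fmt("argument_error", "external imputers need a command template")
    for (ph in c("{input}", "{output}")) {
      cnt <- lengths(regmatches(command_template,
                                gregexpr(ph, command_template, fixed = TRUE)))
      if (cnt != 1)
        stop_fmt("argument_error",
                 "command template must contain %s exactly once (found %d)", ph, cnt)
    }
  }
  structure(list(kind = kind, command_template = command_template,
                 params = params, seed = as.integer(seed)),
            class = "imputer_spec")
}

#' Run an external imputation program over masked files
#'
#' Renders the command template once per input (substituting `{input}` and
#' `{output}`), executes the commands, and returns the output paths in input
#' order. Runs are sequential by default; since typical imputers use a single
#' CPU, several can be run in parallel with `workers > 1` (each run already
#' writes to its own output path, so runs share no state). Standard
#' output/error of each run is captured to `<output>.log`; a nonzero exit
#' status or a missing output file is an error reporting the log tail.
#'
#' @param spec an external [imputer_spec()].
#' @param inputs character vector of masked input files.
#' @param workdir directory for outputs and logs.
#' @param workers maximum concurrent runs.
#' @return Character vector of output file paths, in input order.
#' @export
run_external <- function(spec, inputs, workdir = ".", workers = 1L) {
  if (!inherits(spec, "imputer_spec") || spec$kind != "external")
    stop_fmt("argument_error", "spec must be an external imputer_spec")
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- file.path(workdir, paste0(basename(inputs), ".imputed"))
  run_one <- function(i) {
    cmd <- sub("{output}", outputs[i],
               sub("{input}", inputs[i], spec$command_template, fixed = TRUE),
               fixed = TRUE)
    log <- paste0(outputs[i], ".log")
    status <- system(paste0("(", cmd, ") > ", shQuote(log), " 2>&1"))
    list(status = status, log = log)
  }
  res <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(inputs), run_one, mc.cores = workers)
  } else {
    lapply(seq_along(inputs), run_one)
  }
  for (i in seq_along(inputs)) {
    if (res[[i]]$status != 0)
      stop_fmt("run_error", "imputer failed on %s (exit %d): %s", inputs[i],
               res[[i]]$status,
               paste(utils::tail(readLines(res[[i]]$log, warn = FALSE), 3),
                     collapse = " | "))
    if (!file.exists(outputs[i]))
      stop_fmt("output_error", "imputer produced no output for %s", inputs[i])
  }
  outputs
}

#' Impute a list of masked panels with a built-in imputer
#'
#' Convenience driver used by the CLI and the end-to-end workflow: applies
#' the requested built-in imputer to each masked panel (or file), never
#' touching observed cells.
#'
#' @param spec an [imputer_spec()] of kind `"major_allele"` or
#'   `"freq_sample"`.
#' @param masked list of masked [haplotype_panel()]s or file paths.
#' @return List of imputed panels, in input order.
#' @export
impute_builtin <- function(spec, masked) {
  if (!is.list(masked) || inherits(masked, "haplotype_panel")) masked <- list(masked)
  masked <- lapply(masked, function(x) if (is.character(x)) read_panel(x) else x)
  lapply(seq_along(masked), function(k) {
    switch(spec$kind,
           major_allele = impute_major_allele(masked[[k]]),
           freq_sample = impute_frequency_sample(masked[[k]],
                                                 seed = spec$seed + k - 1L),
           stop_fmt("argument_error", "not a built-in imputer: %s", spec$kind))
  })
}
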