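# internal helpers shared across modules

# round half away from zero (Plink-style count rounding); x >= 0 here
round_half_up <- function(x) floor(x + 0.5)

# run code with a locally seeded RNG, restoring the caller's RNG state
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_fmt <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(class, "haplomask_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == floor(x) && x >= 1

is_fraction <- function(x, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
}
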