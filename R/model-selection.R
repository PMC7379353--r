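#' Summarize discordance records into an error curve
#'
#' Groups discordance records by their (numeric) id — typically the value of
#' the model parameter being swept, such as the haplotype-cluster count K or
#' the number of EM cycles — and reports the median and sample standard
#' deviation of discordance per parameter value, sorted by parameter. This is
#' the "median (SD) from n imputations" summary conventionally reported for
#' masked data analysis.
#'
#' @param records a `discordance_table` (possibly rbind-ed across runs) whose
#'   `id` values all parse as numbers.
#' @return A data frame of class `error_curve` with columns `param`,
#'   `median`, `sd`, `n`.
#' @export
summarize_curve <- function(records) {
  params <- suppressWarnings(as.numeric(records$id))
  if (anyNA(params))
    stop_fmt("parse_error", "non-numeric id '%s' in record %d",
             records$id[which(is.na(params))[1]], which(is.na(params))[1])
  out <- do.call(rbind, lapply(split(records$discordance, params), function(d)
    data.frame(median = stats::median(d),
               sd = if (length(d) > 1) stats::sd(d) else 0,
               n = length(d))))
  out <- data.frame(param = as.numeric(rownames(out)), out, row.names = NULL)
  out <- out[order(out$param), ]
  rownames(out) <- NULL
  class(out) <- c("error_curve", "data.frame")
  out
}

#' Select the model parameter from an error curve
#'
#' Two selection rules. `"min"` returns the parameter with the smallest
#' median discordance — appropriate when the curve shows a clear interior
#' minimum, as the bias-variance trade-off produces for a single population.
#' `"elbow"` handles asymptotically decreasing curves (typical for pooled
#' populations, where the minimum lies beyond the swept range): both axes are
#' min-max normalized to \[0, 1\], a chord is drawn from the first to the
#' last normalized point, and the parameter of the point with the largest
#' perpendicular distance below the chord (the bend of the curve) is
#' returned. Ties go to the smallest parameter; an exactly collinear curve
#' returns the smallest parameter with a "no elbow" warning.
#'
#' @param curve an `error_curve` from [summarize_curve()].
#' @param rule `"elbow"` (default) or `"min"`.
#' @return The selected parameter value, with the full per-point chord
#'   distances in attribute `"distance"` for the elbow rule.
#' @export
select_param <- function(curve, rule = c("elbow", "min")) {
  rule <- match.arg(rule)
  if (rule == "min") {
    if (nrow(curve) < 1) stop_fmt("insufficient_data", "empty curve")
    return(curve$param[which.min(curve$median)])
  }
  if (nrow(curve) < 3)
    stop_fmt("insufficient_data",
             "elbow selection needs >= 3 parameter values, got %d", nrow(curve))
  d <- chord_distances(curve$param, curve$median)
  eps <- 1e-12
  if (max(d) <= eps) {
    warn_fmt("no elbow: curve is collinear; returning the smallest parameter")
    sel <- curve$param[1]
  } else {
    sel <- curve$param[which.max(d)]  # which.max takes the first = smallest param
  }
  attr(sel, "distance") <- d
  sel
}

# signed perpendicular distance below the chord, on min-max normalized axes
chord_distances <- function(x, y) {
  nx <- if (max(x) > min(x)) (x - min(x)) / (max(x) - min(x)) else rep(0, length(x))
  ny <- if (max(y) > min(y)) (y - min(y)) / (max(y) - min(y)) else rep(0, length(y))
  x1 <- nx[1]; y1 <- ny[1]; x2 <- nx[length(nx)]; y2 <- ny[length(ny)]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  if (len == 0) return(rep(0, length(x)))
  # positive when the point lies below the chord (the convex side of a
  # decreasing error curve)
  ((x2 - x1) * (y1 - ny) - (x1 - nx) * (y2 - y1)) / len
}

#' @export
print.error_curve <- function(x, ...) {
  cat("error curve (median discordance by parameter):\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' @export
plot.error_curve <- function(x, ..., xlab = "model parameter",
                             ylab = "discordance") {
  graphics::plot(x$param, x$median, type = "b", pch = 19,
                 xlab = xlab, ylab = ylab, ...)
  graphics::arrows(x$param, x$median - x$sd, x$param, x$median + x$sd,
                   angle = 90, code = 3, length = 0.03, col = "grey40")
  invisible(x)
}

#' Write / read an error-curve TSV
#' @param x an `error_curve`.
#' @param path TSV path (columns `param`, `median`, `sd`, `n`).
#' @return `path` (writer) or the curve (reader).
#' @export
write_curve <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  out <- utils::read.delim(path, sep = "\t")
  class(out) <- c("error_curve", "data.frame")
  out
}
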