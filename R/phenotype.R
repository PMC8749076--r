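## Cell-length phenotype statistics: the elongation statistic is the
## fraction of cells longer than the 95th percentile of the wild-type
## length distribution, with percentile-bootstrap confidence intervals.

#' Cell length sample
#'
#' @param strain strain label.
#' @param lengths numeric vector of per-cell lengths (micrometers), all > 0.
#' @param metadata optional free-form list (temperature, date, ...).
#' @param min_n protocol target sample size; a warning (not an error) is
#'   issued below it.
#' @return Object of class \code{cell_length_sample}.
#' @export
cell_length_sample <- function(strain, lengths, metadata = list(), min_n = 500) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 1 || any(!is.finite(lengths)) || any(lengths <= 0))
    stop("lengths must be a non-empty vector of positive numbers")
  if (length(lengths) < min_n)
    warning(sprintf("strain '%s': n = %d is below the protocol target of %d cells",
                    strain, length(lengths), min_n))
  structure(list(strain = strain, lengths = lengths, metadata = metadata),
            class = "cell_length_sample")
}

#' Read cell-length samples from CSV
#'
#' Expects columns \code{strain} and \code{length_um}; returns one sample
#' per strain.
#'
#' @param path CSV file path.
#' @return Named list of \code{cell_length_sample} objects.
#' @export
read_cell_lengths <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("strain", "length_um") %in% names(df)))
    stop("cell-length CSV needs columns: strain, length_um")
  out <- lapply(split(df$length_um, df$strain), function(x)
    suppressWarnings(cell_length_sample(strain = "", lengths = x)))
  for (s in names(out)) out[[s]]$strain <- s
  out
}

#' Elongation threshold: a percentile of the wild-type length distribution
#'
#' The empirical percentile uses linear interpolation between order
#' statistics (the default "type 7" definition: quantile at p sits at rank
#' 1 + (n-1)p, interpolated).
#'
#' @param wt a \code{cell_length_sample} (or numeric vector) of wild-type
#'   lengths.
#' @param percentile percentile in (0, 100); 95 by default.
#' @return Threshold length (micrometers).
#' @export
elongation_threshold <- function(wt, percentile = 95) {
  x <- if (inherits(wt, "cell_length_sample")) wt$lengths else as.numeric(wt)
  if (length(x) < 20)
    stop("need at least 20 cells to estimate a stable threshold")
  unname(stats::quantile(x, percentile / 100, type = 7))
}

#' Fraction of elongated cells
#'
#' Cells strictly longer than the threshold count as elongated.
#'
#' @param sample a \code{cell_length_sample} (or numeric vector).
#' @param threshold length threshold (micrometers), > 0.
#' @return Fraction in [0, 1].
#' @export
fraction_elongated <- function(sample, threshold) {
  x <- if (inherits(sample, "cell_length_sample")) sample$lengths else as.numeric(sample)
  if (length(x) == 0) stop("empty sample")
  if (threshold <= 0) stop("threshold must be > 0")
  mean(x > threshold)
}

#' Bootstrap confidence interval for the elongated fraction
#'
#' Resamples the sample with replacement \code{n_boot} times at a fixed
#' threshold and returns the percentile confidence interval of the
#' elongated fraction. Deterministic given \code{seed}.
#'
#' @param sample a \code{cell_length_sample} (or numeric vector).
#' @param threshold fixed length threshold (micrometers).
#' @param n_boot number of bootstrap replicates (1000 by default).
#' @param level confidence level (0.95 by default).
#' @param seed RNG seed.
#' @return Named numeric vector \code{c(lo, hi)}.
#' @export
bootstrap_ci <- function(sample, threshold, n_boot = 1000, level = 0.95,
                         seed = 1) {
  x <- if (inherits(sample, "cell_length_sample")) sample$lengths else as.numeric(sample)
  n <- length(x)
  if (n < 20) stop("need at least 20 cells for a bootstrap CI")
  set.seed(seed)
  elong <- x > threshold
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  fracs <- colMeans(matrix(elong[idx], nrow = n))
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(fracs, c(a, 1 - a), type = 7))
  c(lo = ci[1], hi = ci[2])
}

#' Compare strains against a wild-type reference
#'
#' Computes the elongation threshold from the wild type once, then for each
#' strain (wild type included first) the sample size, median length,
#' elongated fraction and its bootstrap confidence interval.
#'
#' @param wt wild-type \code{cell_length_sample}.
#' @param mutants list of \code{cell_length_sample} objects.
#' @param percentile threshold percentile (95 by default).
#' @param n_boot,level,seed bootstrap settings (see \code{\link{bootstrap_ci}}).
#' @return data frame with one row per strain: \code{strain}, \code{n},
#'   \code{median_um}, \code{threshold_um}, \code{fraction_elongated},
#'   \code{ci_lo}, \code{ci_hi}.
#' @export
compare_strains <- function(wt, mutants, percentile = 95, n_boot = 1000,
                            level = 0.95, seed = 1) {
  thr <- elongation_threshold(wt, percentile)
  strains <- c(list(wt), mutants)
  rows <- lapply(seq_along(strains), function(i) {
    s <- strains[[i]]
    ci <- bootstrap_ci(s, thr, n_boot = n_boot, level = level, seed = seed + i)
    data.frame(strain = s$strain, n = length(s$lengths),
               median_um = stats::median(s$lengths), threshold_um = thr,
               fraction_elongated = fraction_elongated(s, thr),
               ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
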