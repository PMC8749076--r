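## Thermal melting curves (CD ellipticity vs temperature) fitted to a
## two-state sigmoidal transition with linear pre- and post-transition
## baselines:
##
##   signal(T) = base1(T) + (base2(T) - base1(T)) / (1 + exp((Tm - T)/k))
##   base1(T) = a1 + b1*T,  base2(T) = a2 + b2*T
##
## Tm is the transition midpoint (degrees C) and k the transition width.
## No thermodynamic (van 't Hoff) parameterization is attempted: the fits
## report midpoints only, appropriate for irreversible transitions.

#' Melt curve container
#'
#' @param temperature vector of temperatures (degrees C), strictly
#'   increasing after sorting; duplicated temperatures are averaged with a
#'   warning.
#' @param signal ellipticity (arbitrary units), same length.
#' @param wavelength label, e.g. "224 nm".
#' @return Object of class \code{melt_curve}.
#' @export
melt_curve <- function(temperature, signal, wavelength = NA_character_) {
  if (length(temperature) != length(signal))
    stop("temperature and signal must have the same length")
  ord <- order(temperature)
  temperature <- temperature[ord]; signal <- signal[ord]
  if (anyDuplicated(temperature)) {
    warning("duplicate temperatures averaged")
    signal <- as.numeric(tapply(signal, temperature, mean))
    temperature <- sort(unique(temperature))
  }
  if (length(temperature) < 8)
    stop("need at least 8 points in a melt curve")
  structure(list(temperature = temperature, signal = signal,
                 wavelength = wavelength),
            class = "melt_curve")
}

#' Read a melt curve from a two-column CSV
#'
#' First column temperature (degrees C), second column signal; a header row
#' is expected. Rows are sorted by temperature on load.
#'
#' @param path CSV file path.
#' @param wavelength optional wavelength label.
#' @return A \code{melt_curve}.
#' @export
read_melt_csv <- function(path, wavelength = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("melt CSV needs two columns: temperature, signal")
  melt_curve(as.numeric(df[[1]]), as.numeric(df[[2]]), wavelength)
}

#' Fit a sigmoidal transition to a melt curve
#'
#' Least-squares fit (Levenberg-Marquardt) of a two-state sigmoid with
#' linear baselines. Initialization is multi-start over Tm guesses at the
#' 25/50/75 percent quantiles of the temperature range; the best residual
#' wins (ties: lowest Tm). A fit whose Tm falls outside the observed range,
#' that fails to converge, or whose transition amplitude is negligible
#' relative to the signal range is flagged \code{converged = FALSE} rather
#' than raising an error.
#'
#' @param curve a \code{melt_curve}.
#' @param width_init initial transition width (degrees C).
#' @return list of class \code{melt_fit}: \code{tm}, \code{width},
#'   \code{baseline1} (intercept, slope), \code{baseline2}, \code{amplitude}
#'   (signal change between baselines at Tm), \code{residual} (RMS),
#'   \code{converged}, \code{diagnostics}.
#' @export
fit_melt <- function(curve, width_init = 3) {
  stopifnot(inherits(curve, "melt_curve"))
  Tv <- curve$temperature; y <- curve$signal
  rng <- range(Tv)
  model <- function(p, Tx) {
    b1 <- p["a1"] + p["b1"] * Tx
    b2 <- p["a2"] + p["b2"] * Tx
    b1 + (b2 - b1) / (1 + exp((p["tm"] - Tx) / p["k"]))
  }
  starts <- rng[1] + c(0.25, 0.5, 0.75) * diff(rng)
  best <- NULL
  for (tm0 in starts) {
    lo <- y[Tv <= tm0]; hi <- y[Tv > tm0]
    p0 <- c(a1 = mean(lo), b1 = 0, a2 = mean(hi), b2 = 0, tm = tm0, k = width_init)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0,
                         fn = function(p) model(p, Tv) - y,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && fit$par[["tm"]] < best$par[["tm"]])) {
      best <- list(par = fit$par, rss = rss, info = fit$info)
    }
  }
  if (is.null(best)) {
    return(structure(list(tm = NA_real_, width = NA_real_,
                          baseline1 = c(NA, NA), baseline2 = c(NA, NA),
                          amplitude = NA_real_, residual = NA_real_,
                          converged = FALSE,
                          diagnostics = "all starts failed"),
                     class = "melt_fit"))
  }
  p <- best$par
  amp <- (p[["a2"]] + p[["b2"]] * p[["tm"]]) - (p[["a1"]] + p[["b1"]] * p[["tm"]])
  sig_range <- diff(range(y))
  in_range <- p[["tm"]] >= rng[1] && p[["tm"]] <= rng[2]
  has_transition <- sig_range > 0 && abs(amp) > 0.05 * sig_range
  diagnostics <- c(
    if (!in_range) "Tm outside the observed temperature range",
    if (!has_transition) "no significant transition (amplitude ~ 0)")
  structure(list(tm = unname(p[["tm"]]), width = unname(abs(p[["k"]])),
                 baseline1 = unname(c(p[["a1"]], p[["b1"]])),
                 baseline2 = unname(c(p[["a2"]], p[["b2"]])),
                 amplitude = unname(amp),
                 residual = sqrt(best$rss / length(y)),
                 converged = in_range && has_transition,
                 diagnostics = if (length(diagnostics)) diagnostics else "ok"),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("Melt fit: Tm = %.2f C (width %.2f C, amplitude %.3g, RMS %.3g)\n",
                x$tm, x$width, x$amplitude, x$residual))
  else
    cat("Melt fit did not converge:", paste(x$diagnostics, collapse = "; "), "\n")
  invisible(x)
}
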