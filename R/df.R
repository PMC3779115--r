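#' Power spectrum of a uniformly sampled voltage series
#'
#' Plain periodogram of the mean-removed signal (rectangular window):
#' `power[k] = |FFT(x - mean(x))[k]|^2 / n` at frequencies `k / duration`,
#' so the frequency resolution is the reciprocal of the record length.
#'
#' @param trace either a `cell_trace`-like list with `t` and `V`, or a
#'   numeric vector (then `fs` is required).
#' @param fs sampling frequency (Hz); inferred from `t` when a trace is
#'   given.
#' @return List with `freqs` (Hz) and `power` (one-sided, excluding DC).
#' @export
power_spectrum <- function(trace, fs = NULL) {
  if (is.list(trace)) {
    tt <- trace$t
    dtv <- diff(tt)
    if (max(dtv) - min(dtv) > 1e-6 * mean(dtv))
      stop("power_spectrum requires uniform sampling")
    fs <- 1000 / mean(dtv)             # t in ms
    x <- trace$V
  } else {
    if (is.null(fs)) stop("fs required for a bare numeric signal")
    x <- as.numeric(trace)
  }
  n <- length(x)
  if (n / fs < 2) stop("signal must cover at least 2 s")
  x <- x - mean(x)
  sp <- Mod(fft(x))^2 / n
  k <- seq_len(floor(n / 2))           # positive frequencies, excluding DC
  list(freqs = k * fs / n, power = sp[k + 1])
}

#' Dominant frequency of a power spectrum
#'
#' The frequency of the largest spectral peak within the physiological
#' band (default 0.1-20 Hz; components outside it are eliminated).
#' Secondary peaks that are not harmonics of the dominant frequency
#' (within +-5\% of an integer multiple) are reported alongside.
#'
#' @param spectrum result of [power_spectrum()].
#' @param band frequency band in Hz (default `c(0.1, 20)`).
#' @param n_secondary how many non-harmonic secondary peaks to report.
#' @return List with `df` (Hz, `NA` when no in-band power), `power`,
#'   `secondary` (non-harmonic peak frequencies) and `in_band` (logical).
#' @export
dominant_frequency <- function(spectrum, band = c(0.1, 20), n_secondary = 3) {
  if (band[2] <= band[1]) stop("empty frequency band")
  sel <- spectrum$freqs >= band[1] & spectrum$freqs <= band[2]
  if (!any(sel) || all(spectrum$power[sel] <= 0))
    return(list(df = NA_real_, power = NA_real_, secondary = numeric(0),
                in_band = FALSE))
  f <- spectrum$freqs[sel]; pw <- spectrum$power[sel]
  if (max(pw) < 1e-12 * sum(spectrum$power))
    return(list(df = NA_real_, power = NA_real_, secondary = numeric(0),
                in_band = FALSE))
  i <- which.max(pw)
  df <- f[i]
  # local maxima as candidate secondary peaks
  loc <- which(diff(sign(diff(pw))) == -2) + 1
  loc <- loc[order(pw[loc], decreasing = TRUE)]
  harmonic <- function(fr) {
    k <- round(fr / df)
    k >= 1 && abs(fr - k * df) <= 0.05 * k * df
  }
  sec <- f[loc]
  sec <- sec[!vapply(sec, harmonic, logical(1))]
  list(df = df, power = pw[i],
       secondary = utils::head(sec, n_secondary), in_band = TRUE)
}

#' Dominant-frequency map of a field history
#'
#' Applies [dominant_frequency()] to every recorded node of a tissue
#' simulation and summarises the map per region (mean and variance), the
#' standard read-out for distinguishing a single driving rotor (narrow,
#' unimodal DF distribution) from multiple wavelets (large DF variance).
#'
#' @param history a `field_history` with at least 2 s of recorded V.
#' @param band analysis band (Hz).
#' @return List with `df` (per recorded node), `regions` (per-node region
#'   labels) and `summary` (data frame: region, mean_df, var_df, n).
#' @export
df_map <- function(history, band = c(0.1, 20)) {
  stopifnot(inherits(history, "field_history"))
  if (!length(history$t) || max(history$t) - min(history$t) < 2000)
    stop("df_map requires at least 2 s of recorded history")
  fs <- 1000 / mean(diff(history$t))
  dfv <- apply(history$V, 1, function(x) {
    sp <- power_spectrum(x, fs = fs)
    dominant_frequency(sp, band)$df
  })
  regs <- history$geom$region[history$geom$inside][history$record_nodes]
  sm <- do.call(rbind, lapply(split(dfv, regs), function(v) {
    data.frame(mean_df = mean(v, na.rm = TRUE),
               var_df = stats::var(v[!is.na(v)]),
               n = sum(!is.na(v)))
  }))
  sm$region <- rownames(sm)
  rownames(sm) <- NULL
  list(df = dfv, regions = regs, summary = sm[, c("region", "mean_df",
                                                  "var_df", "n")])
}
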