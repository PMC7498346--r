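#' Imager-strand binding kinetics
#'
#' @param k_on Association constant of the imager strand in M^-1 s^-1
#'   (default 1.5e6).
#' @param c_M Imager-strand concentration in mol/L (typical working range
#'   0.5-2 nM, i.e. 5e-10 to 2e-9).
#' @param tau_bright_s Mean bright (bound) dwell time in seconds (default
#'   0.5; must be small against the per-site dark time for qPAINT to hold).
#' @return A list of class `kinetic_params`.
#' @export
kinetic_params <- function(k_on = 1.5e6, c_M = 1e-9, tau_bright_s = 0.5) {
  if (k_on <= 0 || tau_bright_s <= 0) stop("kinetic rates must be > 0", call. = FALSE)
  if (c_M <= 0) stop("imager concentration must be > 0", call. = FALSE)
  structure(list(k_on = k_on, c_M = c_M, tau_bright_s = tau_bright_s),
            class = "kinetic_params")
}

#' Imager influx rate
#'
#' The rate at which imager strands arrive at a single docking site:
#' `xi = k_on * c`. At the standard `k_on` of 1.5e6 M^-1 s^-1 and 1 nM
#' imager, `xi` is 1.5e-3 per second.
#'
#' @param k A [kinetic_params()].
#' @return Influx rate in s^-1.
#' @export
influx_rate <- function(k) {
  stopifnot(inherits(k, "kinetic_params"))
  k$k_on * k$c_M
}

#' Count binding sites from dark-time kinetics (qPAINT)
#'
#' With `n` independent docking sites in a pick, binding events arrive at
#' rate `n * xi`, so the mean dark time between events is `1/(n * xi)` and
#' `n = 1 / (xi * tau_dark)`. Two dark-time estimators are provided:
#' \describe{
#'   \item{mean}{`tau_dark` = arithmetic mean of the observed dark times
#'     (requires >= 5).}
#'   \item{cdf_fit}{`tau_dark` = least-squares fit of the empirical dark-time
#'     CDF to `1 - exp(-t/tau)` (requires >= 20), more robust to occasional
#'     long outliers.}
#' }
#'
#' @param dark Numeric vector of dark times in seconds (from
#'   [dark_times()]).
#' @param xi Influx rate in s^-1 (from [influx_rate()]).
#' @param estimator `"mean"` (default) or `"cdf_fit"`.
#' @param background Binding sites contributed by non-specific probe
#'   retention, subtracted (and clamped at zero) to give
#'   `n_sites_corrected`; default 0, the calibrated value for scrambled-LNA
#'   controls in tissue is around 5.12.
#' @param pick Optional [pick_region()] recorded in the result.
#' @return A list of class `qpaint_estimate`: `mean_dark_s`, `tau_fit_s`
#'   (NA for the mean estimator), `influx_per_s`, `n_dark`, `estimator`,
#'   `n_sites_raw`, `n_sites_corrected`, `pick`.
#' @export
binding_sites <- function(dark, xi, estimator = c("mean", "cdf_fit"),
                          background = 0, pick = NULL) {
  estimator <- match.arg(estimator)
  if (background < 0) stop("background must be >= 0", call. = FALSE)
  m <- length(dark)
  need <- if (estimator == "mean") 5L else 20L
  if (m < need) {
    stop(sprintf("insufficient dark times for %s estimator: %d observed, %d required",
                 estimator, m, need), call. = FALSE)
  }
  mean_dark <- mean(dark)
  tau_fit <- NA_real_
  if (estimator == "mean") {
    tau <- mean_dark
  } else {
    ts <- sort(dark)
    Femp <- seq_along(ts) / m
    sse <- function(tau) sum((Femp - (1 - exp(-ts / tau)))^2)
    tau_fit <- stats::optimize(sse, interval = c(mean_dark / 50, mean_dark * 50))$minimum
    tau <- tau_fit
  }
  n_raw <- 1 / (xi * tau)
  structure(list(mean_dark_s = mean_dark, tau_fit_s = tau_fit,
                 influx_per_s = xi, n_dark = m, estimator = estimator,
                 n_sites_raw = n_raw,
                 n_sites_corrected = subtract_background(n_raw, background),
                 pick = pick),
            class = "qpaint_estimate")
}

#' @export
print.qpaint_estimate <- function(x, ...) {
  cat(sprintf("qPAINT estimate (%s, %d dark times): mean dark %.2f s, xi %.3g /s\n",
              x$estimator, x$n_dark, x$mean_dark_s, x$influx_per_s))
  cat(sprintf("  binding sites: %.2f raw, %.2f background-corrected\n",
              x$n_sites_raw, x$n_sites_corrected))
  invisible(x)
}

#' Subtract non-specific background binding sites
#'
#' @param n_raw Raw binding-site count.
#' @param background Background site count measured with a scrambled control
#'   probe (default 5.12).
#' @return `max(0, n_raw - background)` — counts cannot be negative.
#' @export
subtract_background <- function(n_raw, background = 5.12) {
  if (background < 0) stop("background must be >= 0", call. = FALSE)
  pmax(0, n_raw - background)
}

#' Transcripts-per-ten-million normalization
#'
#' Normalizes a small-RNA read count by the library's total genome-matched
#' reads, scaled to ten million.
#'
#' @param count Read count(s) for the small RNA.
#' @param total_genome_matched Total genome-matched reads in the library
#'   (> 0).
#' @return `count * 1e7 / total_genome_matched`.
#' @export
tp10m <- function(count, total_genome_matched) {
  if (total_genome_matched <= 0) {
    stop("total_genome_matched must be > 0", call. = FALSE)
  }
  count * 1e7 / total_genome_matched
}

#' Quantify binding sites over a set of picks
#'
#' Convenience pipeline: for each pick, select the localizations
#' ([pick_circle()]), link them into binding events ([link_events()]),
#' measure dark times and estimate binding sites ([binding_sites()]).
#'
#' @param tab A drift-corrected, photon-filtered `loc_table`.
#' @param picks A list of [pick_region()]s.
#' @param k A [kinetic_params()].
#' @param estimator,background Passed to [binding_sites()].
#' @param ignore_gap Passed to [link_events()].
#' @return A data.frame, one row per pick: center, diameter, number of
#'   localizations and events, mean dark time, influx rate, raw and
#'   corrected site counts (NA rows where a pick had too few dark times).
#' @export
quantify_picks <- function(tab, picks, k = kinetic_params(),
                           estimator = "mean", background = 5.12,
                           ignore_gap = 1) {
  xi <- influx_rate(k)
  ft <- attr(tab, "frame_time_s")
  rows <- lapply(seq_along(picks), function(i) {
    sub <- pick_circle(tab, picks[[i]])
    ev <- link_events(sub, ignore_gap)
    dk <- dark_times(ev, ft)
    est <- tryCatch(binding_sites(dk, xi, estimator, background, picks[[i]]),
                    error = function(e) NULL)
    data.frame(pick = i,
               x = picks[[i]]$center[1], y = picks[[i]]$center[2],
               diameter_nm = picks[[i]]$diameter_nm,
               n_locs = nrow(sub), n_events = nrow(ev),
               mean_dark_s = if (is.null(est)) NA_real_ else est$mean_dark_s,
               influx_per_s = xi,
               n_sites_raw = if (is.null(est)) NA_real_ else est$n_sites_raw,
               n_sites_corrected = if (is.null(est)) NA_real_ else est$n_sites_corrected)
  })
  do.call(rbind, rows)
}
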