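#' Simulation configuration
#'
#' Conditions for the blink-kinetics simulator, with defaults matching a
#' typical sRNA-PAINT acquisition: 20000 frames at 100 ms exposure, ~8 nm
#' localization noise (sub-20 nm resolution regime), imager association
#' constant 1.5e6 M^-1 s^-1 with a nanomolar imager concentration, 0.5 s
#' mean bright dwell, and log-normal photon counts (median 2000, sdlog 0.5)
#' so the 420-10000 photon filter is exercised with realistic tails.
#'
#' @param n_sites Number of docking sites.
#' @param layout `"cluster"` (sites at `center` plus `cluster_sd_nm`
#'   scatter) or `"uniform-circle"` (uniform over a disc of `radius_nm`).
#' @param center Site layout center (nm).
#' @param radius_nm Disc radius for `"uniform-circle"` (default 500).
#' @param cluster_sd_nm Gaussian scatter for `"cluster"` (default 20).
#' @param kinetics A [kinetic_params()].
#' @param n_frames,frame_time_s Acquisition length and frame time.
#' @param loc_sigma_nm Gaussian localization noise (nm).
#' @param drift_nm_per_frame Length-2 drift rate `(dx, dy)` in nm/frame.
#' @param photons_meanlog,photons_sdlog Log-normal photon parameters.
#' @param seed Integer seed; every generator in the package is reproducible
#'   under it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites, layout = c("cluster", "uniform-circle"),
                       center = c(0, 0), radius_nm = 500, cluster_sd_nm = 20,
                       kinetics = kinetic_params(k_on = 1.5e6, c_M = 5e-9),
                       n_frames = 20000, frame_time_s = 0.1,
                       loc_sigma_nm = 8, drift_nm_per_frame = c(0, 0),
                       photons_meanlog = log(2000), photons_sdlog = 0.5,
                       seed = 1) {
  layout <- match.arg(layout)
  if (n_sites < 0) stop("n_sites must be >= 0", call. = FALSE)
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  structure(list(n_sites = as.integer(n_sites), layout = layout,
                 center = center, radius_nm = radius_nm,
                 cluster_sd_nm = cluster_sd_nm, kinetics = kinetics,
                 n_frames = as.integer(n_frames), frame_time_s = frame_time_s,
                 loc_sigma_nm = loc_sigma_nm,
                 drift_nm_per_frame = drift_nm_per_frame,
                 photons_meanlog = photons_meanlog,
                 photons_sdlog = photons_sdlog, seed = as.integer(seed)),
            class = "sim_config")
}

# draw alternating dark/bright dwell times for one site until total time T;
# returns matrix of bright intervals [t_on, t_off) in seconds
.site_intervals <- function(xi, tau_bright, T) {
  t <- 0
  on <- off <- numeric(0)
  repeat {
    t <- t + stats::rexp(1, rate = xi)          # dark dwell
    if (t >= T) break
    dur <- stats::rexp(1, rate = 1 / tau_bright)  # bright dwell
    on <- c(on, t)
    off <- c(off, min(t + dur, T))
    t <- t + dur
    if (t >= T) break
  }
  cbind(on = on, off = off)
}

# frames whose overlap with [t0, t1) is at least half a frame
.bright_frames <- function(t0, t1, dt, n_frames) {
  f <- floor(t0 / dt):min(floor(t1 / dt), n_frames - 1L)
  ov <- pmin(t1, (f + 1) * dt) - pmax(t0, f * dt)
  f[ov >= 0.5 * dt]
}

#' Simulate DNA-PAINT blinking at known docking sites
#'
#' Renders imager binding as an alternating renewal process per site: dark
#' dwell times are exponential with rate `xi = k_on * c`, bright dwells
#' exponential with mean `tau_bright_s`. Bright intervals are rasterized to
#' camera frames (a frame is bright when the interval covers at least half
#' of it); every bright frame yields one localization at the site position
#' plus Gaussian localization noise plus the cumulative stage drift at that
#' frame, with a log-normal photon count. Sites blink independently; nothing
#' is merged spatially.
#'
#' @param cfg A [sim_config()].
#' @return A list with `table` (a `loc_table`, sorted by frame) and `truth`
#'   (class `sim_truth`: `sites` matrix of true positions, `n_sites`,
#'   `intervals` per-site bright intervals, `kinetics`, `drift_nm_per_frame`,
#'   `seed`).
#' @export
simulate_blinking <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  .simulate_blinking_impl(cfg)
}

# internal: assumes RNG state is already positioned (no set.seed)
.simulate_blinking_impl <- function(cfg, sites = NULL) {
  xi <- influx_rate(cfg$kinetics)
  T <- cfg$n_frames * cfg$frame_time_s
  dt <- cfg$frame_time_s
  if (is.null(sites)) {
    sites <- .layout_sites(cfg)
  }
  frame <- integer(0); sx <- sy <- numeric(0); site_id <- integer(0)
  intervals <- vector("list", cfg$n_sites)
  for (s in seq_len(cfg$n_sites)) {
    iv <- .site_intervals(xi, cfg$kinetics$tau_bright_s, T)
    intervals[[s]] <- iv
    for (r in seq_len(nrow(iv))) {
      f <- .bright_frames(iv[r, 1], iv[r, 2], dt, cfg$n_frames)
      frame <- c(frame, f)
      site_id <- c(site_id, rep(s, length(f)))
    }
  }
  n <- length(frame)
  if (n) {
    sx <- sites[site_id, 1] + cfg$drift_nm_per_frame[1] * frame +
      stats::rnorm(n, 0, cfg$loc_sigma_nm)
    sy <- sites[site_id, 2] + cfg$drift_nm_per_frame[2] * frame +
      stats::rnorm(n, 0, cfg$loc_sigma_nm)
    ph <- stats::rlnorm(n, cfg$photons_meanlog, cfg$photons_sdlog)
  } else {
    ph <- numeric(0)
  }
  ord <- order(frame, site_id)
  tab <- localization_table(frame[ord], sx[ord], sy[ord], ph[ord],
                            precision = rep(cfg$loc_sigma_nm, n),
                            frame_time_s = dt, n_frames = cfg$n_frames)
  truth <- structure(list(sites = sites, n_sites = cfg$n_sites,
                          intervals = intervals, kinetics = cfg$kinetics,
                          drift_nm_per_frame = cfg$drift_nm_per_frame,
                          seed = cfg$seed),
                     class = "sim_truth")
  list(table = tab, truth = truth)
}

.layout_sites <- function(cfg) {
  k <- cfg$n_sites
  if (k == 0) return(matrix(numeric(0), 0, 2))
  if (cfg$layout == "cluster") {
    cbind(cfg$center[1] + stats::rnorm(k, 0, cfg$cluster_sd_nm),
          cfg$center[2] + stats::rnorm(k, 0, cfg$cluster_sd_nm))
  } else {
    r <- cfg$radius_nm * sqrt(stats::runif(k))
    th <- stats::runif(k, 0, 2 * pi)
    cbind(cfg$center[1] + r * cos(th), cfg$center[2] + r * sin(th))
  }
}

#' Simulate fiducial marker tracks
#'
#' Each fiducial is localized in every frame at a fixed position plus the
#' cumulative stage drift plus Gaussian localization noise, emulating the
#' bright gold particles used for drift correction.
#'
#' @param n Number of fiducials (>= 1).
#' @param drift_nm_per_frame Length-2 drift rate `(dx, dy)` in nm/frame.
#' @param noise_nm Per-frame localization noise (nm).
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param positions Optional n x 2 matrix of fiducial positions; defaults to
#'   uniform over a 20 x 20 um field.
#' @return A list of `loc_table`s, one per fiducial.
#' @export
simulate_fiducials <- function(n, drift_nm_per_frame = c(0, 0), noise_nm = 5,
                               n_frames = 20000, seed = 1, positions = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  if (is.null(positions)) {
    positions <- matrix(stats::runif(2 * n, 0, 20000), n, 2)
  }
  frames <- 0:(n_frames - 1)
  lapply(seq_len(n), function(i) {
    localization_table(
      frames,
      positions[i, 1] + drift_nm_per_frame[1] * frames +
        stats::rnorm(n_frames, 0, noise_nm),
      positions[i, 2] + drift_nm_per_frame[2] * frames +
        stats::rnorm(n_frames, 0, noise_nm),
      photons = rep(30000, n_frames),   # fiducials are far brighter than blinks
      n_frames = n_frames)
  })
}

#' Simulate a multi-region scene
#'
#' Generates one localization table covering several disjoint circular
#' regions, each with its own number of uniformly placed docking sites —
#' the layered-tissue situation where per-region qPAINT counts are compared.
#'
#' @param regions List of `list(pick = pick_region(), n_sites = k)` entries;
#'   regions must be pairwise disjoint.
#' @param cfg A [sim_config()] providing kinetics, frames, noise, drift and
#'   seed (its `n_sites`/layout fields are ignored).
#' @return A list with `table` (combined `loc_table`) and `truth`
#'   (`sim_truth` with an extra `region_sites` integer vector of true
#'   per-region counts).
#' @export
simulate_scene <- function(regions, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(regions) == 0) {
    empty <- sim_config(0, kinetics = cfg$kinetics, n_frames = cfg$n_frames,
                        frame_time_s = cfg$frame_time_s, seed = cfg$seed)
    return(.simulate_blinking_impl(empty))
  }
  for (i in seq_along(regions)) {
    for (j in seq_len(i - 1)) {
      pi <- regions[[i]]$pick; pj <- regions[[j]]$pick
      d <- sqrt(sum((pi$center - pj$center)^2))
      if (d < (pi$diameter_nm + pj$diameter_nm) / 2) {
        stop(sprintf("regions %d and %d overlap", j, i), call. = FALSE)
      }
    }
  }
  set.seed(cfg$seed)
  tabs <- list(); truths <- list()
  for (i in seq_along(regions)) {
    reg <- regions[[i]]
    rcfg <- cfg
    rcfg$n_sites <- as.integer(reg$n_sites)
    rcfg$layout <- "uniform-circle"
    rcfg$center <- reg$pick$center
    rcfg$radius_nm <- reg$pick$diameter_nm / 2
    out <- .simulate_blinking_impl(rcfg)
    tabs[[i]] <- out$table
    truths[[i]] <- out$truth
  }
  all_sites <- do.call(rbind, lapply(truths, `[[`, "sites"))
  df <- do.call(rbind, lapply(tabs, as.data.frame))
  ord <- order(df$frame)
  tab <- localization_table(df$frame[ord], df$x[ord], df$y[ord],
                            df$photons[ord], precision = df$precision[ord],
                            frame_time_s = cfg$frame_time_s,
                            n_frames = cfg$n_frames)
  truth <- structure(list(sites = all_sites,
                          n_sites = sum(vapply(regions, `[[`, numeric(1), "n_sites")),
                          region_sites = vapply(regions, function(r) as.integer(r$n_sites), integer(1)),
                          intervals = unlist(lapply(truths, `[[`, "intervals"), recursive = FALSE),
                          kinetics = cfg$kinetics,
                          drift_nm_per_frame = cfg$drift_nm_per_frame,
                          seed = cfg$seed),
                     class = "sim_truth")
  list(table = tab, truth = truth)
}

#' Random small-RNA sequence
#'
#' Generates an RNA-alphabet sequence of the requested length with the
#' requested expected GC fraction (G and C equiprobable within the GC draw,
#' A and U within the AU draw). Useful as design-pipeline input.
#'
#' @param length Sequence length (typically 21-24).
#' @param gc_fraction Expected GC fraction in \[0, 1\] (default 0.5).
#' @param seed Integer seed.
#' @return An RNA string.
#' @export
random_srna <- function(length, gc_fraction = 0.5, seed = 1) {
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must be in [0, 1]",
                                               call. = FALSE)
  set.seed(seed)
  paste(sample(c("G", "C", "A", "U"), length, replace = TRUE,
               prob = c(gc_fraction / 2, gc_fraction / 2,
                        (1 - gc_fraction) / 2, (1 - gc_fraction) / 2)),
        collapse = "")
}
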