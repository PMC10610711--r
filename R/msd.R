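# Mean-squared displacement, Fickian-window detection, and Einstein-relation
# self-diffusion estimation.
#
# MSD(tau) = < |r_com(t0 + tau) - r_com(t0)|^2 >, averaged over molecules and
# multiple time origins. In three dimensions the Einstein relation gives
# D = slope / 6 on the linear (Fickian) part of the curve; with coordinates
# in Angstrom and times in ps, 1 A^2/ps = 1e-8 m^2/s.

A2PS_TO_M2S <- 1e-8

#' Multi-origin mean-squared displacement
#'
#' Computes, for each lag tau on the frame grid, the average over molecules
#' and over time origins (spaced `origin_stride` frames) of the squared
#' centre-of-mass displacement. The trajectory must be unwrapped: wrapped
#' coordinates would fold displacements back into the box and destroy the
#' long-time behaviour.
#'
#' @param traj An unwrapped `trajectory`.
#' @param top The matching `topology`.
#' @param mol_ids Molecule ids to average over (default: all water molecules;
#'   if the topology has no water, all molecules).
#' @param max_lag Largest lag in ps (default: 10% of the trajectory span,
#'   longer lags being statistically starved).
#' @param origin_stride Spacing between time origins, in frames (default 1,
#'   i.e. all origins).
#' @return An object of class `"msd_curve"`: a data frame with columns
#'   `lag_ps`, `msd_A2` and `n_samples` (the number of (molecule, origin)
#'   pairs averaged at each lag), with the molecule count in
#'   `attr(, "n_molecules")`.
#' @export
compute_msd <- function(traj, top, mol_ids = NULL, max_lag = NULL,
                        origin_stride = 1L) {
  if (traj$wrapped) {
    stop("compute_msd() needs continuous coordinates: unwrap the trajectory first")
  }
  if (is.null(mol_ids)) {
    w <- unique(top$atoms$mol_id[top$atoms$species == "water"])
    mol_ids <- if (length(w)) sort(w) else sort(unique(top$atoms$mol_id))
  }
  if (length(mol_ids) == 0L) stop("empty molecule selection")
  dt <- frame_dt(traj)
  nf <- n_frames(traj)
  span <- traj$times[nf] - traj$times[1]
  if (is.null(max_lag)) max_lag <- 0.1 * span
  if (max_lag >= span + dt / 2 && nf > 2L) {
    stop("max_lag must be smaller than the trajectory time span")
  }
  kmax <- max(1L, min(nf - 1L, floor(max_lag / dt + 1e-9)))
  com <- com_trajectory(traj, top, mol_ids)
  msd_from_com(com, dt, kmax, origin_stride, length(mol_ids))
}

# Shared core: MSD of a frames x molecules x 3 path array.
msd_from_com <- function(com, dt, kmax, origin_stride, n_molecules) {
  nf <- dim(com)[1]
  nm <- dim(com)[2]
  vals <- numeric(kmax)
  nsamp <- integer(kmax)
  for (k in seq_len(kmax)) {
    origins <- seq.int(1L, nf - k, by = origin_stride)
    d2 <- (com[origins + k, , 1, drop = FALSE] - com[origins, , 1, drop = FALSE])^2 +
      (com[origins + k, , 2, drop = FALSE] - com[origins, , 2, drop = FALSE])^2 +
      (com[origins + k, , 3, drop = FALSE] - com[origins, , 3, drop = FALSE])^2
    vals[k] <- mean(d2)
    nsamp[k] <- length(origins) * nm
  }
  out <- data.frame(lag_ps = seq_len(kmax) * dt, msd_A2 = vals,
                    n_samples = nsamp)
  class(out) <- c("msd_curve", "data.frame")
  attr(out, "n_molecules") <- n_molecules
  out
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d lags, %g..%g ps, %d molecules\n",
              nrow(x), x$lag_ps[1], x$lag_ps[nrow(x)],
              attr(x, "n_molecules") %||% NA_integer_))
  invisible(x)
}

#' Local double-logarithmic slope of an MSD curve
#'
#' Least-squares slope of `log10(MSD)` against `log10(lag)` in a centred
#' moving window of `2 * half_window + 1` points (truncated at the ends).
#' A slope of 1 marks Fickian diffusion, 2 ballistic motion, and 0 a
#' confinement plateau. Lags with non-positive MSD are skipped with a
#' warning (their slope is `NA`).
#'
#' @param msd An `msd_curve`.
#' @param half_window Half-width of the moving window in points (default 3).
#' @return Numeric vector of local slopes, one per lag.
#' @export
loglog_slope <- function(msd, half_window = 3L) {
  n <- nrow(msd)
  if (n < 2L * half_window + 1L) {
    stop("need at least 2 * half_window + 1 lags")
  }
  ok <- msd$msd_A2 > 0
  if (!all(ok)) warning("skipping ", sum(!ok), " lag(s) with non-positive MSD")
  lx <- log10(msd$lag_ps)
  ly <- ifelse(ok, log10(pmax(msd$msd_A2, .Machine$double.xmin)), NA_real_)
  slopes <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- max(1L, i - half_window):min(n, i + half_window)
    w <- w[ok[w]]
    if (length(w) < 2L) next
    x <- lx[w]; y <- ly[w]
    slopes[i] <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  }
  slopes
}

#' Detect the Fickian (linear-MSD) lag window
#'
#' Finds the longest contiguous lag interval whose local log-log slopes all
#' lie inside `slope_band` and which spans at least `min_span` decades of
#' lag. Ties are broken in favour of the earliest interval. Used to confirm
#' the `MSD ~ tau` regime before an Einstein fit; on ballistic or fully
#' confined input no window qualifies and an error asks for a manual window.
#'
#' @param msd An `msd_curve`.
#' @param slope_band Numeric length-2 interval for admissible local slopes
#'   (default `c(0.9, 1.1)`).
#' @param min_span Minimum window span in decades of lag (default 0.5).
#' @param half_window Passed to [loglog_slope()].
#' @return Numeric `c(t_min, t_max)` in ps.
#' @export
detect_linear_window <- function(msd, slope_band = c(0.9, 1.1),
                                 min_span = 0.5, half_window = 3L) {
  slopes <- loglog_slope(msd, half_window)
  inband <- !is.na(slopes) & slopes >= slope_band[1] & slopes <= slope_band[2]
  r <- rle(inband)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- NULL; best_len <- -1
  for (g in which(r$values)) {
    i0 <- starts[g]; i1 <- ends[g]
    span <- log10(msd$lag_ps[i1] / msd$lag_ps[i0])
    if (span >= min_span && (i1 - i0) > best_len) {
      best <- c(msd$lag_ps[i0], msd$lag_ps[i1])
      best_len <- i1 - i0
    }
  }
  if (is.null(best)) {
    stop("no lag window with log-log slope in [", slope_band[1], ", ",
         slope_band[2], "] spanning ", min_span,
         " decades; supply a fit window manually")
  }
  best
}

#' Einstein-relation diffusion fit on an MSD window
#'
#' Ordinary least squares (with intercept, which absorbs any short-time
#' ballistic or cage offset) of MSD against lag over the given window. The
#' diffusion coefficient is `slope / 6` converted from A^2/ps to m^2/s.
#'
#' @param msd An `msd_curve`.
#' @param window Numeric `c(t_min, t_max)` in ps; must contain at least 5
#'   lag points.
#' @param n_molecules Number of molecules averaged (recorded in the result;
#'   defaults to the curve's own count).
#' @param stderr Optional standard error on D in m^2/s (from
#'   [block_stderr()]).
#' @return An object of class `"diffusion_estimate"`: list with `d` (m^2/s),
#'   `stderr`, `window` (ps), `slope` (A^2/ps), `intercept` (A^2),
#'   `r_squared` and `n_molecules`.
#' @export
fit_diffusion <- function(msd, window, n_molecules = NULL, stderr = NA_real_) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  sel <- msd$lag_ps >= window[1] & msd$lag_ps <= window[2]
  if (sum(sel) < 5L) stop("fit window must contain at least 5 lag points")
  fit <- stats::lm(msd_A2 ~ lag_ps, data = msd[sel, , drop = FALSE])
  slope <- unname(stats::coef(fit)[2])
  if (slope < 0) stop("fitted MSD slope is negative: the window is not diffusive")
  if (is.null(n_molecules)) n_molecules <- attr(msd, "n_molecules")
  y <- msd$msd_A2[sel]
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(d = slope / 6 * A2PS_TO_M2S,
                 stderr = stderr,
                 window = as.numeric(window),
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_molecules = n_molecules),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> D = %.4e m^2/s", x$d))
  if (is.finite(x$stderr)) cat(sprintf(" +/- %.2e", x$stderr))
  cat(sprintf("\n  window %g..%g ps, slope %.4e A^2/ps, R^2 %.5f, N = %d\n",
              x$window[1], x$window[2], x$slope, x$r_squared,
              x$n_molecules %||% NA_integer_))
  invisible(x)
}

#' Block standard error of the diffusion coefficient
#'
#' Partitions the molecules into `n_blocks` disjoint groups, fits D per
#' block over the same lag window, and returns the standard error of the
#' block mean. This is a molecule-resampling uncertainty, appropriate when
#' walkers are statistically independent.
#'
#' @param traj Unwrapped `trajectory`.
#' @param top The matching `topology`.
#' @param window Fit window in ps, `c(t_min, t_max)`.
#' @param mol_ids Molecule ids (default: water molecules).
#' @param n_blocks Number of blocks (default 5; needs >= 2 molecules per
#'   block).
#' @param origin_stride Passed to the per-block MSD.
#' @return Standard error of D in m^2/s.
#' @export
block_stderr <- function(traj, top, window, mol_ids = NULL, n_blocks = 5L,
                         origin_stride = 1L) {
  if (n_blocks < 2L) stop("n_blocks must be at least 2")
  if (is.null(mol_ids)) {
    w <- unique(top$atoms$mol_id[top$atoms$species == "water"])
    mol_ids <- if (length(w)) sort(w) else sort(unique(top$atoms$mol_id))
  }
  nm <- length(mol_ids)
  if (nm < n_blocks) stop("fewer molecules than blocks")
  if (nm < 2L * n_blocks) stop("need at least 2 molecules per block")
  dt <- frame_dt(traj)
  kmax <- min(n_frames(traj) - 1L, floor(window[2] / dt + 1e-9))
  com <- com_trajectory(traj, top, mol_ids)
  block_of <- rep(seq_len(n_blocks), length.out = nm)  # deterministic split
  d_blocks <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    idx <- which(block_of == b)
    curve <- msd_from_com(com[, idx, , drop = FALSE], dt, kmax,
                          origin_stride, length(idx))
    d_blocks[b] <- fit_diffusion(curve, window, length(idx))$d
  }
  stats::sd(d_blocks) / sqrt(n_blocks)
}

#' One-call diffusion estimate from an unwrapped trajectory
#'
#' Convenience chain: multi-origin MSD, automatic Fickian-window detection
#' (falling back to the stated window override), Einstein fit, and block
#' standard error.
#'
#' @param traj Unwrapped `trajectory`.
#' @param top The matching `topology`.
#' @param mol_ids Molecule ids (default: water molecules).
#' @param max_lag,origin_stride Passed to [compute_msd()].
#' @param window Optional manual fit window in ps; default is the detected
#'   Fickian window.
#' @param slope_band,min_span,half_window Passed to [detect_linear_window()].
#' @param n_blocks Passed to [block_stderr()]; set to `NA` to skip the
#'   uncertainty estimate.
#' @return A `diffusion_estimate` with the `msd_curve` attached as attribute
#'   `"msd"`.
#' @export
estimate_diffusion <- function(traj, top, mol_ids = NULL, max_lag = NULL,
                               origin_stride = 1L, window = NULL,
                               slope_band = c(0.9, 1.1), min_span = 0.5,
                               half_window = 3L, n_blocks = 5L) {
  curve <- compute_msd(traj, top, mol_ids, max_lag, origin_stride)
  if (is.null(window)) {
    window <- detect_linear_window(curve, slope_band, min_span, half_window)
  }
  se <- NA_real_
  if (!is.na(n_blocks)) {
    se <- tryCatch(block_stderr(traj, top, window, mol_ids, n_blocks,
                                origin_stride),
                   error = function(e) NA_real_)
  }
  est <- fit_diffusion(curve, window, stderr = se)
  attr(est, "msd") <- curve
  est
}

#' Export an MSD curve (and optional slope track) to CSV
#'
#' @param msd An `msd_curve`.
#' @param path Output CSV path.
#' @param slopes Optional local log-log slope vector to include.
#' @return `path`, invisibly.
#' @export
write_msd_csv <- function(msd, path, slopes = NULL) {
  out <- as.data.frame(msd)
  if (!is.null(slopes)) out$loglog_slope <- slopes
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a diffusion estimate as JSON
#'
#' @param est A `diffusion_estimate`.
#' @param path Output JSON path.
#' @param system Label for the system (e.g. the resin name).
#' @return `path`, invisibly.
#' @export
write_diffusion_json <- function(est, path, system = "system") {
  jsonlite::write_json(
    list(system = system, d_m2s = est$d, stderr_m2s = est$stderr,
         window_ps = est$window, slope_A2ps = est$slope,
         r_squared = est$r_squared, n_molecules = est$n_molecules),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
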