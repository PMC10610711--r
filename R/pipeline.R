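# Config-driven orchestration: read/generate -> equilibration check ->
# MSD/diffusion -> hydrogen bonds -> clusters -> density projection, with a
# manifest of every artifact written.

#' Equilibration drift check on a scalar time series
#'
#' Least-squares slope over the tail of a monitored quantity (potential or
#' kinetic energy, density, ...). The run is flagged equilibrated when the
#' total drift across the tail, `|slope| * tail span`, is at most 1% of the
#' tail mean. For (near-)zero-mean series the relative criterion is replaced
#' by an absolute drift threshold.
#'
#' @param times Numeric vector of times in ps (increasing).
#' @param values Numeric vector of the monitored quantity.
#' @param tail_fraction Fraction of the series (from the end) to analyse
#'   (default 0.5).
#' @param rel_tol Maximum tolerated |drift| / |tail mean| (default 0.01).
#' @param abs_threshold Absolute drift threshold used when the tail mean is
#'   zero (same units as `values`); required in that case.
#' @return A list with `slope_per_ns` (value units per ns), `drift_ratio`
#'   (|slope * span| / |mean|, `NA` when the absolute criterion is used) and
#'   `pass`.
#' @export
equilibration_drift <- function(times, values, tail_fraction = 0.5,
                                rel_tol = 0.01, abs_threshold = NULL) {
  stopifnot(length(times) == length(values), length(times) >= 10L,
            tail_fraction > 0, tail_fraction <= 1)
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  n <- length(times)
  tail_idx <- seq.int(n - ceiling(tail_fraction * n) + 1L, n)
  t <- times[tail_idx]; v <- values[tail_idx]
  slope <- sum((t - mean(t)) * (v - mean(v))) / sum((t - mean(t))^2)  # per ps
  span <- t[length(t)] - t[1]
  drift <- abs(slope) * span
  m <- mean(v)
  if (abs(m) < .Machine$double.eps * 100) {
    if (is.null(abs_threshold)) {
      stop("tail mean is zero: supply abs_threshold for the drift criterion")
    }
    list(slope_per_ns = slope * 1000, drift_ratio = NA_real_,
         pass = drift <= abs_threshold)
  } else {
    ratio <- drift / abs(m)
    list(slope_per_ns = slope * 1000, drift_ratio = ratio,
         pass = ratio <= rel_tol)
  }
}

#' Read a pipeline run configuration
#'
#' YAML or JSON, chosen by extension. See [run_pipeline()] for the accepted
#' fields.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return The configuration as a nested list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: .", ext)
  }
}

stage_try <- function(report, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE, value = conditionMessage(e)))
  if (res$ok) {
    report$stages[[name]] <- res$value
  } else {
    report$errors[[name]] <- res$value
    message("stage '", name, "' failed: ", res$value)
  }
  report
}

#' Run the full sorption-analysis pipeline from a configuration
#'
#' Stages (each can be disabled with `<stage>: enabled: false`):
#' `equilibration` (drift check on a two-column time/value CSV), `msd`
#' (diffusion estimate on the auto-detected Fickian window), `hbond`
#' (count profile and class summary), `clusters` (largest-cluster series)
#' and `density` (projection map and uniformity CV). Input is either a
#' trajectory/topology file pair (`input:`) or a synthetic walker spec
#' (`synth:` with the [synth_spec()] fields). Per-stage CSV/JSON artifacts,
#' a JSON summary and a checksummed manifest are written to `output_dir`.
#' Identical config + inputs + seed give identical outputs; a failing stage
#' is recorded and skipped while independent stages still run.
#'
#' @param config A config list or a path accepted by [read_run_config()].
#' @return The report (list with `stages`, `errors`, `outputs`), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- config$output_dir %||% stop("config needs an output_dir")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  report <- list(stages = list(), errors = list(), outputs = character(0))

  # --- input ------------------------------------------------------------
  if (!is.null(config$synth)) {
    sp <- config$synth
    spec <- synth_spec(mode = sp$mode %||% "brownian",
                       n_molecules = sp$n_molecules, n_frames = sp$n_frames,
                       dt = sp$dt %||% 5, d_true = sp$d_true,
                       speed = sp$speed, cavity_radius = sp$cavity_radius,
                       box = unlist(sp$box %||% c(50, 50, 50)),
                       seed = sp$seed %||% seed)
    gw <- gen_walkers(spec)
    traj <- gw$wrapped
    top <- gw$topology
  } else if (!is.null(config$input)) {
    traj <- read_trajectory(config$input$trajectory,
                            format = config$input$format %||% "auto",
                            dt = config$input$dt %||% 1)
    top <- if (!is.null(config$input$topology)) {
      read_topology(config$input$topology)
    } else {
      at <- attr(traj, "atoms")
      if (is.null(at)) stop("no topology file and none derivable from input")
      topology_from_residues(at$element, at$mol_id, at$resname)
    }
  } else {
    stop("config needs either an 'input' or a 'synth' block")
  }

  enabled <- function(stage) !isFALSE(config[[stage]]$enabled)

  # --- equilibration ----------------------------------------------------
  if (enabled("equilibration") && !is.null(config$equilibration$series_csv)) {
    report <- stage_try(report, "equilibration", {
      es <- utils::read.csv(config$equilibration$series_csv)
      equilibration_drift(es[[1]], es[[2]],
                          config$equilibration$tail_fraction %||% 0.5)
    })
  }

  # --- msd / diffusion --------------------------------------------------
  if (enabled("msd")) {
    report <- stage_try(report, "msd", {
      tu <- if (traj$wrapped) unwrap(traj) else traj
      mc <- config$msd %||% list()
      est <- estimate_diffusion(tu, top,
                                max_lag = mc$max_lag,
                                origin_stride = mc$origin_stride %||% 1L,
                                window = if (!is.null(mc$window)) unlist(mc$window),
                                slope_band = unlist(mc$slope_band %||% c(0.9, 1.1)),
                                min_span = mc$min_span %||% 0.5,
                                half_window = mc$half_window %||% 3L,
                                n_blocks = mc$n_blocks %||% 5L)
      curve <- attr(est, "msd")
      p1 <- file.path(outdir, "msd_curve.csv")
      write_msd_csv(curve, p1, loglog_slope(curve,
                                            mc$half_window %||% 3L))
      p2 <- file.path(outdir, "diffusion.json")
      write_diffusion_json(est, p2, system = config$name %||% "system")
      report$outputs <- c(report$outputs, p1, p2)
      est
    })
  }

  # --- hydrogen bonds ---------------------------------------------------
  if (enabled("hbond")) {
    report <- stage_try(report, "hbond", {
      hc <- config$hbond %||% list()
      crit <- hbond_criteria(hc$max_ha %||% 2.8,
                             hc$min_donor_angle %||% 120,
                             hc$min_acceptor_angle %||% 90)
      prof <- hbond_profile(traj, top, crit, stride = hc$stride %||% 1L)
      p1 <- file.path(outdir, "hbond_profile.csv")
      p2 <- file.path(outdir, "hbond_summary.json")
      write_hbond_profile(prof, p1, p2)
      report$outputs <- c(report$outputs, p1, p2)
      prof
    })
  }

  # --- clusters ---------------------------------------------------------
  if (enabled("clusters")) {
    report <- stage_try(report, "clusters", {
      cc <- config$clusters %||% list()
      cs <- cluster_series(traj, top, cutoff = cc$cutoff %||% 3.5,
                           stride = cc$stride %||% 1L)
      p1 <- file.path(outdir, "cluster_series.csv")
      write_cluster_csv(cs, p1)
      report$outputs <- c(report$outputs, p1)
      cs
    })
  }

  # --- density ----------------------------------------------------------
  if (enabled("density")) {
    report <- stage_try(report, "density", {
      dc <- config$density %||% list()
      map <- project_density(traj, top,
                             species = dc$species %||% "water",
                             axes = unlist(dc$axes %||% c(1, 2)),
                             bin_width = dc$bin_width %||% 1,
                             mode = dc$mode %||% "number")
      p1 <- file.path(outdir, "density_map.csv")
      write_density_csv(map, p1)
      report$outputs <- c(report$outputs, p1)
      list(map = map, uniformity_cv = uniformity_cv(map))
    })
  }

  # --- summary and manifest --------------------------------------------
  summary <- list(
    seed = seed,
    diffusion = if (!is.null(report$stages$msd)) {
      e <- report$stages$msd
      list(d_m2s = e$d, stderr_m2s = e$stderr, window_ps = e$window,
           n_molecules = e$n_molecules, r_squared = e$r_squared)
    },
    hbond = if (!is.null(report$stages$hbond)) report$stages$hbond$summary,
    clusters = if (!is.null(report$stages$clusters)) report$stages$clusters$summary,
    density_cv = if (!is.null(report$stages$density))
      report$stages$density$uniformity_cv,
    equilibration = report$stages$equilibration,
    errors = report$errors)
  ps <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, ps, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  report$outputs <- c(report$outputs, ps)
  manifest <- data.frame(file = basename(report$outputs),
                         md5 = unname(tools::md5sum(report$outputs)))
  pm <- file.path(outdir, "manifest.json")
  jsonlite::write_json(list(config_hash = config_hash(config),
                            seed = seed,
                            package_version = as.character(
                              utils::packageVersion("sorbtrack")),
                            files = manifest),
                       pm, auto_unbox = TRUE, dataframe = "rows")
  report$outputs <- c(report$outputs, pm)
  invisible(report)
}

# Stable hash of the configuration list.
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
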