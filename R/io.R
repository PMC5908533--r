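#' @rdname load_config
#' @param config a [circuit_config()].
#' @export
config_to_list <- function(config) {
  stopifnot(inherits(config, "wp_config"))
  out <- list(
    geometry = list(N = config$geometry$N, spacing = config$geometry$spacing,
                    periodic = config$geometry$periodic),
    params = unclass(config$params),
    protocol = unclass(config$protocol),
    run = list(duration = config$duration, burn_in = config$burn_in)
  )
  # canonical numeric representation so digests are storage-type invariant
  rapply(out, function(x) if (is.numeric(x)) as.numeric(x) else x,
         how = "replace")
}

check_keys <- function(given, allowed, section) {
  unknown <- setdiff(given, allowed)
  if (length(unknown))
    stop(sprintf("unknown key(s) in '%s': %s", section,
                 paste(unknown, collapse = ", ")))
}

#' Load, validate and save circuit configurations
#'
#' Configurations are stored as YAML with four sections — `geometry`,
#' `params`, `protocol`, `run` — mirroring [lattice_geometry()],
#' [model_params()], [stimulus_protocol()] and the trial timing. Unknown
#' keys are rejected with the offending name. Every omitted parameter is
#' filled with its documented default, with one exception: `sigma_E` has no
#' published value and must be stated explicitly (the package's calibrated
#' default is 5 gridpoints; see [model_params()]).
#'
#' @param path file path of the YAML configuration.
#' @return `load_config()` returns a validated [circuit_config()];
#'   `save_config()` writes `config` and returns `path` invisibly;
#'   `config_to_list()` returns the plain-list form used for
#'   serialization.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  check_keys(names(raw), c("geometry", "params", "protocol", "run"), "config")

  g <- raw$geometry %||% list()
  check_keys(names(g), c("N", "spacing", "periodic"), "geometry")
  geometry <- lattice_geometry(N = g$N %||% 300L, spacing = g$spacing %||% 40,
                               periodic = g$periodic %||% TRUE)

  p <- raw$params %||% list()
  check_keys(names(p), c("g_L", "C", "V_L", "V_E", "V_I", "V_th", "V_R",
                         "tau_ref", "tau_E", "tau_I", "W_E", "W_I",
                         "sigma_E", "D", "dt", "jump_convention"), "params")
  if (is.null(p$sigma_E))
    stop("config omits 'sigma_E', which has no published value and must be ",
         "set explicitly; the package's calibrated default is sigma_E: 4 ",
         "(gridpoints, see ?model_params)")
  params <- do.call(model_params, p)

  s <- raw$protocol %||% list()
  check_keys(names(s), c("I_0", "W_S", "t_on", "center", "sigma_S",
                         "roi_radius"), "protocol")
  if (!is.null(s$center)) s$center <- as.numeric(unlist(s$center))
  protocol <- do.call(stimulus_protocol, s)

  r <- raw$run %||% list()
  check_keys(names(r), c("duration", "burn_in"), "run")
  circuit_config(geometry, params, protocol,
                 duration = r$duration %||% 3500,
                 burn_in = r$burn_in %||% 1000)
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  writeLines(yaml::as.yaml(config_to_list(config)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and read trial recordings
#'
#' A recording is stored as a directory of plain-text files: `spikes.csv`
#' (`time_ms,x,y`), `meta.yaml` (seed, configuration, digest), and — when
#' probes were recorded — `probe_coords.csv` plus one CSV per probe field
#' (`probe_V.csv`, `probe_gE.csv`, `probe_gI.csv`; rows = sample times,
#' first column `time_ms`, remaining columns one per probe neuron). State
#' movies are not serialized (recompute them; they are bulky and cheap to
#' regenerate from the seed).
#'
#' @param rec a `wp_recording`.
#' @param dir output directory (created if needed).
#' @return `write_recording()` returns `dir` invisibly; `read_recording()`
#'   returns the `wp_recording` (without movie frames). The configuration
#'   digest is verified on load.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "wp_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(rec$spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  meta <- list(seed = rec$seed, digest = rec$digest,
               config = config_to_list(rec$config),
               has_probes = !is.null(rec$probes))
  writeLines(yaml::as.yaml(meta), file.path(dir, "meta.yaml"))
  if (!is.null(rec$probes)) {
    write.csv(rec$probes$coords, file.path(dir, "probe_coords.csv"),
              row.names = FALSE)
    nm <- paste0("n", rec$probes$coords$x, "_", rec$probes$coords$y)
    for (f in c("V", "g_E", "g_I")) {
      df <- as.data.frame(t(rec$probes[[f]]))
      names(df) <- nm
      df <- cbind(time_ms = rec$probes$times, df)
      write.csv(df, file.path(dir, paste0(
        "probe_", sub("g_", "g", f), ".csv")), row.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  cfgl <- meta$config
  f <- tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(cfgl), f)
  config <- load_config(f)
  unlink(f)
  if (config_digest(config) != meta$digest)
    stop("configuration digest mismatch in ", dir)
  spikes <- read.csv(file.path(dir, "spikes.csv"))
  probes <- NULL
  if (isTRUE(meta$has_probes)) {
    coords <- read.csv(file.path(dir, "probe_coords.csv"))
    rd <- function(nm) {
      df <- read.csv(file.path(dir, nm))
      list(times = df$time_ms, mat = t(as.matrix(df[, -1, drop = FALSE])))
    }
    v <- rd("probe_V.csv"); ge <- rd("probe_gE.csv"); gi <- rd("probe_gI.csv")
    probes <- list(coords = coords, times = v$times,
                   V = unname(v$mat), g_E = unname(ge$mat),
                   g_I = unname(gi$mat))
  }
  structure(list(spikes = spikes, probes = probes, movie = NULL,
                 config = config, seed = as.integer(meta$seed),
                 digest = meta$digest),
            class = "wp_recording")
}

#' Write and read a sweep of recordings with a manifest
#'
#' The manifest (`manifest.csv`) maps every `(strength, trial)` pair to its
#' seed and recording subdirectory; on load every referenced directory must
#' exist and its stored digest must match its configuration.
#'
#' @param sweep a `wp_sweep` from [run_sweep()].
#' @param dir output directory.
#' @return `write_sweep()` returns `dir` invisibly; `read_sweep()` the
#'   reassembled `wp_sweep`.
#' @export
write_sweep <- function(sweep, dir) {
  stopifnot(inherits(sweep, "wp_sweep"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- sweep$manifest
  man$path <- sprintf("ws%g_trial%03d", man$strength, man$trial)
  if (anyDuplicated(man$path)) stop("duplicate output paths in manifest")
  for (k in seq_len(nrow(man)))
    write_recording(sweep$recordings[[k]], file.path(dir, man$path[k]))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"))
  recs <- lapply(man$path, function(p) {
    d <- file.path(dir, p)
    if (!dir.exists(d)) stop("manifest references missing recording: ", p)
    read_recording(d)
  })
  structure(list(manifest = man[, c("strength", "trial", "seed")],
                 recordings = recs),
            class = "wp_sweep")
}
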