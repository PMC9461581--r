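# Configuration and dataset serialisation: YAML configs for model +
# settings, tab-separated departure tables with a YAML sidecar carrying
# full provenance (generating model, seed, package version, config
# fingerprint).

# FNV-style 31-bit fingerprint of a string (provenance stamp, not crypto)
config_fingerprint <- function(txt) {
  h <- 216613626
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(h %% 2147483648, b)
    h <- (h * 16777619) %% 2147483648
  }
  sprintf("%08x", h)
}

model_to_list <- function(model) {
  list(mode = model$mode,
       noise_scale = model$noise_scale,
       env = list(rho = model$env$rho, tau = model$env$tau,
                  alpha = model$env$alpha,
                  travel_time = model$env$travel_time),
       agents = lapply(model$agents, function(a)
         list(theta = a$theta, kappa = a$kappa)))
}

model_from_list <- function(x) {
  env <- patch_env(x$env$rho, x$env$tau, x$env$alpha,
                   x$env$travel_time %||% 0)
  agents <- lapply(x$agents, function(a) agent_strategy(a$theta, a$kappa %||% 0))
  group_model(x$mode, env, agents = agents, noise_scale = x$noise_scale)
}

settings_to_list <- function(s) {
  list(dt = s$dt, t_max = s$t_max, n_trials = s$n_trials, seed = s$seed)
}

settings_from_list <- function(x) {
  sim_settings(dt = x$dt %||% 0.01, t_max = x$t_max %||% 150,
               n_trials = x$n_trials %||% 1, seed = x$seed %||% 1)
}

#' Write / read a group model + settings configuration
#'
#' Flat YAML with an `env` section, per-agent subsections and a `settings`
#' section; see the packaged example under `inst/extdata`.
#'
#' @param model A [group_model()].
#' @param settings A [sim_settings()] (optional on write).
#' @param path File path.
#' @return `read_group_config()` returns `list(model, settings)`.
#' @export
write_group_config <- function(model, settings = NULL, path) {
  x <- model_to_list(model)
  if (!is.null(settings)) x$settings <- settings_to_list(settings)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_group_config
#' @export
read_group_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- yaml::read_yaml(path)
  bad <- setdiff(c("mode", "noise_scale", "env", "agents"), names(x))
  if (length(bad))
    stop("config schema error; missing keys: ", paste(bad, collapse = ", "))
  list(model = model_from_list(x),
       settings = if (!is.null(x$settings)) settings_from_list(x$settings))
}

#' Write / read a departure-time dataset
#'
#' Tab-separated table (`trial`, `agent`, `decision_time`, `decision_rank`,
#' `simultaneous`) plus a YAML sidecar `<path>.yml` recording the
#' generating model, settings, seed, package version and a config
#' fingerprint.
#'
#' @param dataset A `departure_dataset`.
#' @param path Output path for the table.
#' @return `read_departures()` restores the dataset with its generating
#'   model/settings attributes when the sidecar is present.
#' @export
write_departures <- function(dataset, path) {
  stopifnot(inherits(dataset, "data.frame"))
  write.table(dataset, path, sep = "\t", quote = FALSE, row.names = FALSE)
  model <- attr(dataset, "model")
  settings <- attr(dataset, "settings")
  if (!is.null(model)) {
    side <- list(model = model_to_list(model),
                 settings = if (!is.null(settings)) settings_to_list(settings),
                 package_version = as.character(utils::packageVersion("socforage")))
    side$fingerprint <- config_fingerprint(yaml::as.yaml(side))
    yaml::write_yaml(side, paste0(path, ".yml"))
  }
  invisible(path)
}

#' @rdname write_departures
#' @export
read_departures <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  out <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("trial", "agent", "decision_time", "decision_rank", "simultaneous")
  bad <- setdiff(need, names(out))
  if (length(bad))
    stop("dataset parse error; missing columns: ", paste(bad, collapse = ", "))
  out$simultaneous <- as.logical(out$simultaneous)
  class(out) <- c("departure_dataset", "data.frame")
  side_path <- paste0(path, ".yml")
  if (file.exists(side_path)) {
    side <- yaml::read_yaml(side_path)
    if (!is.null(side$model)) attr(out, "model") <- model_from_list(side$model)
    if (!is.null(side$settings))
      attr(out, "settings") <- settings_from_list(side$settings)
  }
  out
}

#' Serialise a first-passage density
#'
#' Two-column table (time, density) with survival, plus metadata lines
#' (captured mass, atom) as `#`-prefixed header comments.
#' @param x An [fpt_density()].
#' @param path Output path.
#' @export
write_fpt_density <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# captured_mass: %.8f", attr(x, "captured")), con)
  writeLines(sprintf("# atom_mass: %.8f", x$atom_mass), con)
  writeLines(sprintf("# atom_time: %g", x$atom_time), con)
  write.table(data.frame(time = x$time, density = x$density,
                         survival = x$survival),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
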