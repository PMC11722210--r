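# Run configuration: one YAML file drives simulation, selection and
# bootstrap. CLI flags override config keys, which override the
# package defaults below (documented precedence: flags > file >
# defaults).

#' Default run configuration
#'
#' @return a `run_config` list with the package defaults for every
#'   stage: scenario settings (cells, lognormal parameters, time, true
#'   rates), GMM settings (moment blocks, weight mode, starts, bounds,
#'   search subsample), density settings (bandwidth rule, cdf clip),
#'   selection settings (bootstrap size, reestimate flag), the output
#'   directory, master seed and log level.
#' @export
default_run_config <- function() {
  structure(list(
    scenario = list(
      name = "LARGE",
      n_cells = 8000L,
      t = 1.5,
      mu = nk_lognormal_parameters()$mu,
      sigma2 = nk_lognormal_parameters()$sigma2,
      true_rates = NULL  # NULL = default_true_rates(name)
    ),
    network = NULL,      # NULL = built-in minimal NK network
    gmm = list(moments = c("means", "variances", "covariances"),
               weights = "invvar", n_starts = 8L,
               lower = 1e-8, upper = 1e2, search_size = 500L),
    density = list(bandwidth = "silverman", cdf_clip = 1e-6),
    selection = list(B = 200L, reestimate = FALSE),
    output_dir = ".",
    seed = 1L,
    log_level = "info"
  ), class = "run_config")
}

#' Read a run configuration
#'
#' Missing keys fall back to [default_run_config()]; `overrides`
#' (e.g. from CLI flags) take precedence over the file.
#'
#' @param path YAML config path, or `NULL` for pure defaults.
#' @param overrides named list of overriding keys (nested lists merge).
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- unclass(default_run_config())
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config("config file not found: ", path)
    cfg <- modifyList(cfg, yaml::read_yaml(path))
  }
  if (length(overrides)) cfg <- modifyList(cfg, overrides)
  # YAML sequences arrive as lists; flatten the numeric/character vectors
  for (key in c("mu", "sigma2", "true_rates")) {
    if (!is.null(cfg$scenario[[key]])) {
      cfg$scenario[[key]] <- unlist(cfg$scenario[[key]])
    }
  }
  cfg$gmm$moments <- unlist(cfg$gmm$moments)
  cfg$scenario$name <- match.arg(cfg$scenario$name,
                                 c("LARGE", "MEDIUM", "SMALL"))
  if (is.null(cfg$scenario$true_rates)) {
    cfg$scenario$true_rates <- unname(default_true_rates(cfg$scenario$name))
  }
  if (!is.null(cfg$network) && !file.exists(cfg$network)) {
    stop_config("network config not found: ", cfg$network)
  }
  if (cfg$scenario$n_cells %% 2 != 0) {
    stop_config("scenario n_cells must be even")
  }
  if (cfg$selection$B < 1) stop_config("selection B must be >= 1")
  if (!cfg$density$cdf_clip > 0 || !cfg$density$cdf_clip < 0.5) {
    stop_config("density cdf_clip must lie in (0, 0.5)")
  }
  structure(cfg, class = "run_config")
}

#' Stable hash of a run configuration
#'
#' FNV-1a over the canonical YAML serialization; embedded in every
#' output manifest so artifacts can be traced to their exact settings.
#'
#' @param config a `run_config`.
#' @return an 8-hex-digit string.
#' @export
config_hash <- function(config) {
  txt <- yaml::as.yaml(unclass(config))
  h <- 2166136261
  for (code in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), code)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

tss_log <- function(config, level, ...) {
  want <- .log_levels[[if (is.null(config$log_level)) "info" else
    config$log_level]]
  if (.log_levels[[level]] >= want) {
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
  }
  invisible(NULL)
}

# Run a stage, logging its wall time.
timed_stage <- function(config, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- force(expr)
  tss_log(config, "info", "stage '", name, "' finished in ",
          sprintf("%.1f", proc.time()[["elapsed"]] - t0), " s")
  out
}
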