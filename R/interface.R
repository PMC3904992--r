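#' Load a run configuration from a YAML or JSON file
#'
#' Reads a structured config file, rejects unknown keys, applies defaults
#' for everything omitted (R = 1, b = 3, s = 2, p = 0.2, 100 x 100 Moore
#' radius-1 lattice, best rule, 500 rounds, 50% random start) and returns
#' a validated [sh_config()] together with the optional `experiment`
#' block (sweep grids, `n_runs`, output paths, snapshot rounds).
#'
#' An empty file yields the full default configuration. Files ending in
#' `.json` are parsed as JSON, everything else as YAML (JSON being a YAML
#' subset, either works).
#'
#' @param path path to the config file.
#' @return A list with elements `config` (an `sh_config`) and
#'   `experiment` (a list, possibly empty).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  known_top <- c("params", "rows", "cols", "topology", "rule", "q", "K",
                 "rounds", "init", "seed", "experiment")
  unknown <- setdiff(names(raw), known_top)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  pr <- raw$params %||% list()
  unknown_p <- setdiff(names(pr), c("R", "b", "s", "p", "p_hd", "p_dd"))
  if (length(unknown_p))
    stop("unknown params keys: ", paste(unknown_p, collapse = ", "),
         call. = FALSE)
  p_shared <- pr$p %||% 0.2
  params <- sh_params(R = pr$R %||% 1, b = pr$b %||% 3, s = pr$s %||% 2,
                      p_hd = pr$p_hd %||% p_shared,
                      p_dd = pr$p_dd %||% p_shared)

  top <- raw$topology %||% list()
  unknown_t <- setdiff(names(top), c("kind", "radius", "m"))
  if (length(unknown_t))
    stop("unknown topology keys: ", paste(unknown_t, collapse = ", "),
         call. = FALSE)

  init <- raw$init %||% list(type = "random", h_fraction = 0.5)
  if (is.null(init$type)) init$type <- "random"
  if (init$type == "random" && is.null(init$h_fraction))
    init$h_fraction <- 0.5

  cfg <- sh_config(
    params = params,
    rows = raw$rows %||% 100L, cols = raw$cols %||% 100L,
    topology = list(kind = top$kind %||% "moore",
                    radius = top$radius %||% 1L, m = top$m %||% 4L),
    rule = raw$rule %||% "best",
    q = raw$q %||% 0.9, K = raw$K %||% 0.1,
    rounds = raw$rounds %||% 500L,
    init = init,
    seed = raw$seed %||% 1L
  )
  list(config = cfg, experiment = raw$experiment %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a simulation time series as CSV
#'
#' Columns `round` (0 = initial state) and `h_rate`. Values round-trip
#' exactly (full double precision).
#'
#' @param ts an `sh_timeseries`.
#' @param path output path.
#' @export
write_timeseries_csv <- function(ts, path) {
  h <- ts$h_rate
  df <- data.frame(round = seq_along(h) - 1L, h_rate = h)
  df <- df[!is.na(df$h_rate), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_csv
#' @export
read_timeseries_csv <- function(path) {
  utils::read.csv(path)
}

#' Serialize sweep results
#'
#' `write_sweep_json` stores the grid, per-value mean final rates and the
#' full per-run rate matrix; `write_sweep_csv` writes the long table
#' `param_value, run_index, final_h_rate`.
#'
#' @param sweep an `sh_sweep`.
#' @param path output path.
#' @export
write_sweep_json <- function(sweep, path) {
  obj <- list(param = sweep$param, grid = sweep$grid,
              mean_rate = sweep$mean_rate,
              final_rates = sweep$final_rates,
              n_runs = sweep$n_runs)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sweep_json
#' @export
write_sweep_csv <- function(sweep, path) {
  df <- data.frame(
    param_value = rep(sweep$grid, each = sweep$n_runs),
    run_index = rep(seq_len(sweep$n_runs), times = length(sweep$grid)),
    final_h_rate = as.vector(sweep$final_rates)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a transition interval to JSON
#'
#' @param interval an `sh_transition_interval`.
#' @param path output path.
#' @export
write_interval_json <- function(interval, path) {
  obj <- interval
  class(obj) <- NULL
  if (is.infinite(obj$lower)) obj$lower <- "-Inf"
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
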