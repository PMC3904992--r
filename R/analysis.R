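#' Row-scan cluster granularity
#'
#' Measures how clustered a lattice state is by counting, for every row,
#' the positions where adjacent cells (no wrap-around) hold different
#' strategies. The count is averaged over rows, normalized by `cols - 1`
#' and subtracted from 1:
#' `granularity = 1 - mean_rows(changes) / (cols - 1)`.
#' A value near 1 indicates few large clusters, a perfect checkerboard
#' gives 0, and a uniformly random 50% mixture is about 0.5 in
#' expectation.
#'
#' @param state an `sh_state` with at least 2 columns.
#' @return Granularity in \[0, 1\].
#' @examples
#' granularity(single_dissident_state(9, 9, "H"))
#' @export
granularity <- function(state) {
  nc <- ncol(state)
  if (nc < 2L) stop("granularity needs at least 2 columns", call. = FALSE)
  m <- unclass(state)
  changes <- rowSums(m[, -1L, drop = FALSE] != m[, -nc, drop = FALSE])
  1 - mean(changes) / (nc - 1L)
}

#' Sweep a punishment parameter across seeded replicate runs
#'
#' For each value of the swept parameter (`p`, the shared punishment
#' probability, or `s`, the severity) runs `n_runs` independent
#' simulations and records the honest rate at the final round. Replicate
#' `k` at every grid value uses the counter-derived seed
#' `child_seed(base_config$seed, k)`, so results are deterministic given
#' the master seed.
#'
#' @param base_config an [sh_config()]; the swept parameter overrides its
#'   `params` entry (sweeping `p` sets both `p_hd` and `p_dd`).
#' @param param `"p"` or `"s"`.
#' @param grid strictly increasing parameter values.
#' @param n_runs replicate simulations per grid value.
#' @return An `sh_sweep`: list with `param`, `grid`, `final_rates`
#'   (`n_runs` x `length(grid)` matrix), `mean_rate` per grid value, and
#'   the configuration.
#' @export
sweep_param <- function(base_config, param = c("p", "s"), grid,
                        n_runs = 100L) {
  param <- match.arg(param)
  if (length(grid) == 0L) stop("empty sweep grid", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE))
    stop("sweep grid must be strictly increasing", call. = FALSE)
  if (n_runs < 1L) stop("n_runs must be >= 1", call. = FALSE)

  final_rates <- matrix(NA_real_, nrow = n_runs, ncol = length(grid))
  for (gi in seq_along(grid)) {
    cfg <- base_config
    if (param == "p") {
      cfg$params$p_hd <- grid[gi]
      cfg$params$p_dd <- grid[gi]
    } else {
      cfg$params$s <- grid[gi]
    }
    validate_params(cfg$params)
    for (k in seq_len(n_runs)) {
      cfg$seed <- child_seed(base_config$seed, k)
      ts <- run_simulation(cfg)
      final_rates[k, gi] <- ts$h_rate[cfg$rounds + 1L]
    }
  }
  structure(
    list(param = param, grid = grid, final_rates = final_rates,
         mean_rate = colMeans(final_rates), config = base_config,
         n_runs = as.integer(n_runs)),
    class = "sh_sweep"
  )
}

#' Phase-transition interval of a sweep
#'
#' Locates the interval of the swept parameter over which the population
#' shifts from average dishonest domination to honest domination. The
#' lower bound is the largest grid value whose mean final honest rate is
#' at most `eps_low`; the upper bound is the smallest grid value where
#' the domination criterion holds (`"full_fixation"`: every replicate
#' ends at honest rate 1; `"mean_ge_threshold"`: mean rate >=
#' `1 - eps_low`). When even the first grid value dominates, the lower
#' bound is reported as `-Inf`.
#'
#' @param sweep an `sh_sweep`.
#' @param eps_low mean-rate threshold defining dishonest domination.
#' @param domination upper-bound criterion.
#' @return An `sh_transition_interval`: list with `lower`, `upper`,
#'   `eps_low`, `domination`, `param`. Warns if mean rates drop by more
#'   than 0.2 after the first domination crossing (non-monotone sweep).
#' @export
transition_interval <- function(sweep, eps_low = 0.01,
                                domination = c("full_fixation",
                                               "mean_ge_threshold")) {
  domination <- match.arg(domination)
  means <- sweep$mean_rate
  dominated <- switch(domination,
    full_fixation = apply(sweep$final_rates == 1, 2, all),
    mean_ge_threshold = means >= 1 - eps_low
  )
  if (!any(dominated))
    stop("no grid value reaches honest domination", call. = FALSE)
  ui <- which(dominated)[1]
  low_idx <- which(means <= eps_low & seq_along(means) < ui)
  lower <- if (length(low_idx)) sweep$grid[max(low_idx)] else -Inf
  after <- means[ui:length(means)]
  if (length(after) > 1 && any(cummax(after) - after > 0.2))
    warning("sweep means decrease by > 0.2 after the domination crossing",
            call. = FALSE)
  structure(
    list(lower = lower, upper = sweep$grid[ui], eps_low = eps_low,
         domination = domination, param = sweep$param),
    class = "sh_transition_interval"
  )
}

#' Critical punishment probability
#'
#' Smallest punishment probability at which every replicate fixates to
#' all-honest by the final round. Scans `p` upward from `p_lo` to `p_hi`
#' in increments of `step`; after the first grid value where full
#' fixation holds, refines once with step `step / 5` over the preceding
#' coarse interval and returns the first refined hit.
#'
#' @param base_config an [sh_config()].
#' @param p_lo,p_hi scan bounds, `p_lo < p_hi`.
#' @param step coarse scan increment, > 0.
#' @param n_runs replicates per probed value.
#' @param runner evaluation function `p -> vector of final honest rates`;
#'   the default runs the simulation engine. Injectable for testing.
#' @return The critical probability (refined to `step / 5`).
#' @export
critical_probability <- function(base_config, p_lo = 0, p_hi = 1,
                                 step = 0.025, n_runs = 25L,
                                 runner = NULL) {
  if (p_lo >= p_hi) stop("p_lo must be < p_hi", call. = FALSE)
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  if (is.null(runner)) {
    runner <- function(p) {
      cfg <- base_config
      cfg$params$p_hd <- p
      cfg$params$p_dd <- p
      vapply(seq_len(n_runs), function(k) {
        cfg$seed <- child_seed(base_config$seed, k)
        run_simulation(cfg)$h_rate[cfg$rounds + 1L]
      }, numeric(1))
    }
  }
  dominates <- function(p) all(runner(p) == 1)
  grid <- seq(p_lo, p_hi, by = step)
  hit <- NA_real_
  for (p in grid) {
    if (dominates(p)) { hit <- p; break }
  }
  if (is.na(hit)) stop("no fixation found on the scanned grid", call. = FALSE)
  if (hit == grid[1]) return(hit)
  fine <- seq(hit - step + step / 5, hit, by = step / 5)
  for (p in fine) {
    if (dominates(p)) return(p)
  }
  hit
}

#' Two-state transition color grid
#'
#' Classifies every cell by its (previous, current) strategy pair using
#' the fixed palette: blue = is honest / was honest; red = is dishonest /
#' was dishonest; green = is honest / was dishonest; yellow = is
#' dishonest / was honest.
#'
#' @param prev,curr `sh_state` objects of the same shape.
#' @return Character matrix of labels in
#'   `{"blue", "red", "green", "yellow"}`.
#' @export
transition_color_grid <- function(prev, curr) {
  if (!all(dim(prev) == dim(curr)))
    stop("states have different shapes", call. = FALSE)
  code <- unclass(prev) * 2L + unclass(curr)  # was*2 + is
  labels <- c("red", "green", "yellow", "blue")  # codes 0,1,2,3
  matrix(labels[code + 1L], nrow = nrow(prev), ncol = ncol(prev))
}

#' Render a transition color grid to PNG
#'
#' @param prev,curr `sh_state` objects of the same shape.
#' @param path output PNG path.
#' @param scale integer pixel size per cell.
#' @return `path`, invisibly.
#' @export
render_transition_png <- function(prev, curr, path, scale = 4L) {
  grid <- transition_color_grid(prev, curr)
  pal <- list(blue = c(0, 0, 1), red = c(1, 0, 0),
              green = c(0, 0.8, 0), yellow = c(1, 1, 0))
  img <- array(0, dim = c(nrow(grid), ncol(grid), 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(vapply(grid, function(l) pal[[l]][ch], numeric(1)),
                          nrow(grid), ncol(grid))
  if (scale > 1L) {
    img <- img[rep(seq_len(nrow(grid)), each = scale),
               rep(seq_len(ncol(grid)), each = scale), , drop = FALSE]
  }
  png::writePNG(img, path)
  invisible(path)
}

#' @export
print.sh_sweep <- function(x, ...) {
  cat("SH parameter sweep over", x$param, "-", length(x$grid),
      "values x", x$n_runs, "runs\n")
  print(data.frame(value = x$grid, mean_final_h_rate = round(x$mean_rate, 4)))
  invisible(x)
}

#' @export
print.sh_transition_interval <- function(x, ...) {
  cat(sprintf("%s-transition interval: (%s, %s) [%s]\n", x$param,
              format(x$lower), format(x$upper), x$domination))
  invisible(x)
}
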