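#' Simulation run configuration
#'
#' Collects everything a simulation needs: game parameters, interaction
#' topology, lattice dimensions, the strategy update rule, round count,
#' initial-state specification and the master seed. Defaults reproduce the
#' baseline setting used throughout the analyses: a 100 x 100 torus with
#' Moore radius-1 neighborhoods, best-neighbor imitation, a 50% random
#' initial mixture and 500 rounds.
#'
#' @param params an [sh_params()] object.
#' @param rows,cols lattice dimensions.
#' @param topology list with `kind` in `"moore"`, `"von_neumann"`,
#'   `"well_mixed"`, `"scale_free"`; `radius` (lattice kinds); `m`
#'   (scale-free attachment count).
#' @param rule update rule: `"best"`, `"best_myopic"` or `"best_fermi"`.
#' @param q probability of following the best-neighbor decision under the
#'   myopic rule (otherwise a random neighbor is copied), in \[0, 1\].
#' @param K Fermi temperature (> 0): the best neighbor is imitated with
#'   probability `1 / (1 + exp((pi_self - pi_best) / K))`.
#' @param include_self whether a player's own payoff competes in the
#'   best-neighbor comparison (with keep-own tie-breaking). `FALSE` makes
#'   players always copy the best neighbor. See the methods vignette for
#'   the rationale behind the default.
#' @param rounds number of game rounds, >= 1.
#' @param init initial-state spec: `list(type = "random", h_fraction = )`,
#'   `list(type = "single_dissident", center = )`, or
#'   `list(type = "state", state = <sh_state>)`.
#' @param seed master seed controlling all randomness of the run.
#' @return An `sh_config` object.
#' @examples
#' cfg <- sh_config(params = sh_params(p = 0.3), rows = 50, cols = 50,
#'                  rounds = 100, seed = 7)
#' @export
sh_config <- function(params = sh_params(),
                      rows = 100L, cols = 100L,
                      topology = list(kind = "moore", radius = 1L, m = 4L),
                      rule = c("best", "best_myopic", "best_fermi"),
                      q = 0.9, K = 0.1,
                      include_self = TRUE,
                      rounds = 500L,
                      init = list(type = "random", h_fraction = 0.5),
                      seed = 1L) {
  rule <- match.arg(rule)
  validate_params(params)
  if (is.null(topology$kind)) topology$kind <- "moore"
  if (is.null(topology$radius)) topology$radius <- 1L
  if (is.null(topology$m)) topology$m <- 4L
  cfg <- structure(
    list(params = params, rows = as.integer(rows), cols = as.integer(cols),
         topology = topology, rule = rule, q = q, K = K,
         include_self = isTRUE(include_self),
         rounds = as.integer(rounds), init = init, seed = as.integer(seed)),
    class = "sh_config"
  )
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$rounds < 1L) stop("rounds must be >= 1", call. = FALSE)
  if (cfg$q < 0 || cfg$q > 1) stop("q out of [0,1]", call. = FALSE)
  if (cfg$K <= 0) stop("K must be > 0", call. = FALSE)
  if (!cfg$topology$kind %in% c("moore", "von_neumann", "well_mixed",
                                "scale_free"))
    stop("unknown topology kind: ", cfg$topology$kind, call. = FALSE)
  if (!cfg$init$type %in% c("random", "single_dissident", "state"))
    stop("unknown init type: ", cfg$init$type, call. = FALSE)
  cfg
}

#' Derive a child seed from a master seed
#'
#' Counter-based derivation: run `k` of a batch always receives the same
#' seed regardless of how many runs the batch has, so enlarging `n_runs`
#' never perturbs earlier runs' random streams.
#'
#' @param master master seed (integer).
#' @param k counter, 0-based.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master, k) {
  m <- as.numeric(master) %% 2147483647
  as.integer((m + (as.numeric(k) + 1) * 507468114) %% 2147483646 + 1)
}

build_topology <- function(cfg) {
  top <- cfg$topology
  switch(top$kind,
    moore = lattice_neighbors(cfg$rows, cfg$cols, "moore", top$radius),
    von_neumann = lattice_neighbors(cfg$rows, cfg$cols, "von_neumann",
                                    top$radius),
    well_mixed = well_mixed_neighbors(cfg$rows * cfg$cols),
    scale_free = scale_free_neighbors(cfg$rows * cfg$cols, m = top$m,
                                      seed = child_seed(cfg$seed, 0),
                                      shape = c(cfg$rows, cfg$cols))
  )
}

build_initial_state <- function(cfg) {
  init <- cfg$init
  switch(init$type,
    random = random_state(cfg$rows, cfg$cols, init$h_fraction,
                          seed = child_seed(cfg$seed, 1)),
    single_dissident = single_dissident_state(cfg$rows, cfg$cols,
                                              init$center),
    state = {
      st <- if (is.character(init$state)) read_state(init$state) else init$state
      if (!all(dim(st) == c(cfg$rows, cfg$cols)))
        stop("initial state shape does not match config", call. = FALSE)
      new_sh_state(unclass(st)[, , drop = FALSE])
    }
  )
}

# matrix state (row-major lattice) <-> flat player vector used by the engine
state_to_vec <- function(state) as.integer(t(unclass(state)))
vec_to_state <- function(v, rows, cols) {
  new_sh_state(matrix(as.integer(v), nrow = rows, ncol = cols, byrow = TRUE))
}

rule_code <- function(rule) {
  match(rule, c("best", "best_myopic", "best_fermi")) - 1L
}

#' Play one round of pairwise interactions
#'
#' Every adjacent (unordered) pair interacts exactly once; a player's
#' round payoff is the sum of the payoffs obtained in each of its
#' interactions. Uses the global RNG stream (seed with [set.seed()]).
#'
#' @param state an `sh_state` whose cell count matches the graph.
#' @param graph an `sh_graph`.
#' @param params an [sh_params()] object.
#' @return Numeric matrix of per-player round payoffs, shaped like the
#'   lattice.
#' @examples
#' g <- lattice_neighbors(5, 5, "moore", 1)
#' st <- random_state(5, 5, 0.5, seed = 1)
#' set.seed(1)
#' pay <- play_round(st, g, sh_params())
#' @export
play_round <- function(state, graph, params) {
  validate_params(params)
  if (length(state) != graph$n)
    stop("state size does not match graph", call. = FALSE)
  csr <- as_csr(graph)
  pay <- cpp_play_round(state_to_vec(state), csr$adj, csr$ptr,
                        params$R, params$b, params$s,
                        params$p_hd, params$p_dd)
  matrix(pay, nrow = nrow(state), ncol = ncol(state), byrow = TRUE)
}

#' Synchronous imitation updates
#'
#' All players revise simultaneously from the same `(state, payoffs)`
#' snapshot.
#'
#' * `imitate_best`: adopt the strategy of the highest-payoff member of
#'   self + neighbors; on a tie the player keeps its own strategy if it
#'   attains the maximum, else picks uniformly among maximal neighbors.
#' * `imitate_best_myopic`: with probability `q` apply the best-neighbor
#'   decision, otherwise copy a uniformly random neighbor's current
#'   strategy.
#' * `imitate_best_fermi`: adopt the best neighbor's strategy with
#'   probability `1 / (1 + exp((pi_self - pi_best) / K))`, else keep own.
#'
#' @param state an `sh_state`.
#' @param payoffs payoff matrix from [play_round()] computed on `state`.
#' @param graph the `sh_graph` used for the round.
#' @param q myopic mixing probability in \[0, 1\].
#' @param K Fermi temperature, > 0.
#' @param include_self whether the player's own payoff competes in the
#'   best-neighbor comparison (keep-own tie-breaking when it does).
#' @return The next `sh_state`.
#' @export
imitate_best <- function(state, payoffs, graph, include_self = TRUE) {
  csr <- as_csr(graph)
  v <- cpp_imitate_best(state_to_vec(state), as.numeric(t(payoffs)),
                        csr$adj, csr$ptr, include_self)
  vec_to_state(v, nrow(state), ncol(state))
}

#' @rdname imitate_best
#' @export
imitate_best_myopic <- function(state, payoffs, graph, q = 0.9,
                                include_self = TRUE) {
  if (q < 0 || q > 1) stop("q out of [0,1]", call. = FALSE)
  csr <- as_csr(graph)
  v <- cpp_imitate_best_myopic(state_to_vec(state), as.numeric(t(payoffs)),
                               csr$adj, csr$ptr, q, include_self)
  vec_to_state(v, nrow(state), ncol(state))
}

#' @rdname imitate_best
#' @export
imitate_best_fermi <- function(state, payoffs, graph, K = 0.1) {
  if (K <= 0) stop("K must be > 0", call. = FALSE)
  csr <- as_csr(graph)
  v <- cpp_imitate_best_fermi(state_to_vec(state), as.numeric(t(payoffs)),
                              csr$adj, csr$ptr, K)
  vec_to_state(v, nrow(state), ncol(state))
}

#' Run a full SH-game simulation
#'
#' Builds the topology and initial state from `config`, then alternates
#' interaction rounds ([play_round()]) and synchronous strategy updates
#' for `config$rounds` rounds, recording the honest rate after every
#' round. Fully reproducible from `config$seed`.
#'
#' Homogeneous (all-H / all-D) states are absorbing under every update
#' rule; with `early_stop = TRUE` (default) the loop exits there and the
#' remaining honest rates are filled in with the absorbed value, so the
#' recorded series is identical to running all rounds.
#'
#' @param config an [sh_config()].
#' @param snapshot_rounds integer vector of rounds (>= 1) whose states to
#'   keep.
#' @param target_window optional `c(lo, hi)`: stop at the first round
#'   whose honest rate falls inside the window (used to harvest evolved
#'   cluster states); honest rates after the stop are `NA`.
#' @param early_stop exit early once the state is homogeneous.
#' @return An `sh_timeseries`: list with `h_rate` (length `rounds + 1`,
#'   entry 1 = initial state), `final_state`, `snapshots`, `stop_round`
#'   (-1 unless a target window was hit), `config`, `seed`.
#' @examples
#' cfg <- sh_config(rows = 20, cols = 20, rounds = 50,
#'                  params = sh_params(p = 0.4, s = 2), seed = 3)
#' ts <- run_simulation(cfg)
#' tail(ts$h_rate, 1)
#' @export
run_simulation <- function(config, snapshot_rounds = integer(0),
                           target_window = NULL, early_stop = TRUE) {
  validate_config(config)
  graph <- build_topology(config)
  state0 <- build_initial_state(config)
  csr <- as_csr(graph)
  snapshot_rounds <- sort(as.integer(snapshot_rounds))
  if (is.null(target_window)) target_window <- c(2, 1)  # never satisfied

  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(child_seed(config$seed, 2))
  p <- config$params
  res <- cpp_run_simulation(state_to_vec(state0), csr$adj, csr$ptr,
                            p$R, p$b, p$s, p$p_hd, p$p_dd,
                            rule_code(config$rule), config$q, config$K,
                            config$include_self %||% TRUE,
                            config$rounds, snapshot_rounds,
                            target_window[1], target_window[2],
                            early_stop)
  snaps <- lapply(res$snapshots, function(v) {
    if (is.null(v)) NULL else vec_to_state(v, config$rows, config$cols)
  })
  names(snaps) <- as.character(snapshot_rounds)
  structure(
    list(h_rate = as.numeric(res$h_rate),
         final_state = vec_to_state(res$final_state, config$rows, config$cols),
         snapshots = snaps,
         stop_round = res$stop_round,
         config = config, seed = config$seed),
    class = "sh_timeseries"
  )
}

#' @export
print.sh_timeseries <- function(x, ...) {
  cat("SH simulation:", x$config$rows, "x", x$config$cols,
      x$config$topology$kind, "-", x$config$rule, "rule -",
      x$config$rounds, "rounds\n")
  h <- x$h_rate[!is.na(x$h_rate)]
  cat(sprintf("  honest rate: initial %.3f -> final %.3f\n",
              h[1], h[length(h)]))
  invisible(x)
}
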