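# Shared helpers for the shgame test suite.

# Draw n realizations of sample_pair_payoffs and return an n x 2 matrix.
draw_pairs <- function(s_i, s_j, params, n, seed = 1) {
  set.seed(seed)
  t(vapply(seq_len(n), function(k) sample_pair_payoffs(s_i, s_j, params),
           numeric(2)))
}

# State from a character matrix ("H"/"D") written row by row.
state_from_rows <- function(rows) {
  chars <- strsplit(rows, "")
  m <- t(vapply(chars, function(r) as.integer(r == "H"),
                integer(length(chars[[1]]))))
  shgame:::new_sh_state(m)
}

# Small config used across engine tests.
small_config <- function(...) {
  sh_config(rows = 20L, cols = 20L, rounds = 100L, ...)
}

# Memoized coarse estimate of the s = 2 punishment-probability transition
# interval at the baseline setting (100x100 Moore r=1, best rule, 50%
# random start), shared by the acceptance blocks that need it.
.shgame_test_cache <- new.env(parent = emptyenv())
s2_transition <- function() {
  if (is.null(.shgame_test_cache$iv)) {
    cfg <- sh_config(params = sh_params(s = 2), seed = 20240501)
    sw <- sweep_param(cfg, "p", grid = seq(0.40, 0.60, by = 0.01),
                      n_runs = 5)
    .shgame_test_cache$iv <- transition_interval(sw)
  }
  .shgame_test_cache$iv
}

# Harvest evolved clustered states at a target honest rate, skipping seeds
# whose trajectory jumps over the capture window.
harvest_states <- function(p, target, n_states, master_seed,
                           tol = 0.02, max_attempts = 4 * n_states) {
  out <- list()
  k <- 0
  while (length(out) < n_states && k < max_attempts) {
    k <- k + 1
    st <- tryCatch(
      evolved_cluster_state(sh_config(params = sh_params(p = p, s = 2)),
                            target_h_rate = target, tol = tol,
                            max_rounds = 500, seed = child_seed(master_seed, k)),
      error = function(e) NULL)
    if (!is.null(st)) out[[length(out) + 1]] <- st
  }
  out
}
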