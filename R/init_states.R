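new_sh_state <- function(m) {
  stopifnot(is.matrix(m))
  storage.mode(m) <- "integer"
  structure(m, class = c("sh_state", "matrix"))
}

#' Random initial state with an exact honest fraction
#'
#' Places exactly `round(h_fraction * rows * cols)` honest cells uniformly
#' at random (without replacement). The count is exact rather than
#' binomial, so a requested 50% mixture is literally 50% even on small
#' lattices.
#'
#' @param rows,cols lattice dimensions.
#' @param h_fraction target honest fraction in \[0, 1\].
#' @param seed integer seed; the state is reproducible per seed.
#' @return An `sh_state`: an integer matrix with 1 = honest, 0 = dishonest.
#' @examples
#' st <- random_state(10, 10, 0.5, seed = 1)
#' sum(st)  # exactly 50
#' @export
random_state <- function(rows, cols, h_fraction, seed) {
  if (h_fraction < 0 || h_fraction > 1)
    stop("h_fraction out of [0,1]", call. = FALSE)
  n <- rows * cols
  n_h <- round(h_fraction * n)
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  cells <- integer(n)
  if (n_h > 0) cells[sample.int(n, n_h)] <- 1L
  # row-major cell order: fill the matrix by row
  new_sh_state(matrix(cells, nrow = rows, ncol = cols, byrow = TRUE))
}

#' Uniform state with a single dissident in the middle
#'
#' A lattice filled with one strategy except for a single cell of the
#' opposite (`center`) strategy at position `(rows %/% 2, cols %/% 2)`
#' (0-based).
#'
#' @param rows,cols lattice dimensions (>= 1).
#' @param center strategy of the central dissident, `"H"` or `"D"`.
#' @return An `sh_state`.
#' @export
single_dissident_state <- function(rows, cols, center = "H") {
  ci <- as_strategy_int(center)
  m <- matrix(1L - ci, nrow = rows, ncol = cols)
  m[rows %/% 2 + 1L, cols %/% 2 + 1L] <- ci
  new_sh_state(m)
}

#' Evolved, spatially clustered state at a target honest rate
#'
#' Produces a world state in which honest/dishonest clusters have already
#' formed, by letting a 50% random population evolve under the given
#' configuration and capturing the first post-update state whose honest
#' rate falls within `tol` of `target_h_rate`. The caller chooses dynamics
#' (through `config`) that pass through the target: a punishment
#' probability above the fixation threshold for high targets, below the
#' lower transition bound for low targets.
#'
#' @param config an [sh_config()]; its initial-state spec is ignored in
#'   favor of a 50% random start.
#' @param target_h_rate desired honest rate, strictly between 0 and 1.
#' @param tol half-width of the acceptance window around the target.
#' @param max_rounds rounds to try before giving up.
#' @param seed integer seed.
#' @return An `sh_state` with honest rate within `tol` of the target,
#'   with attribute `"round"` giving the capture round.
#' @export
evolved_cluster_state <- function(config, target_h_rate, tol = 0.02,
                                  max_rounds = 500L, seed = 1L) {
  if (target_h_rate <= 0 || target_h_rate >= 1)
    stop("target_h_rate must be strictly inside (0,1)", call. = FALSE)
  config$seed <- seed
  config$rounds <- as.integer(max_rounds)
  config$init <- list(type = "random", h_fraction = 0.5)
  res <- run_simulation(config,
                        target_window = c(target_h_rate - tol,
                                          target_h_rate + tol))
  if (res$stop_round < 0)
    stop("target honest rate not reached within max_rounds ",
         "(adjust p or s)", call. = FALSE)
  st <- res$final_state
  attr(st, "round") <- res$stop_round
  st
}

#' Honest-player rate of a state
#' @param state an `sh_state`.
#' @return Fraction of honest cells, in \[0, 1\].
#' @export
h_rate <- function(state) mean(state == 1L)

#' Read/write plain-text grid files
#'
#' A grid file holds one lattice row per line, one character per cell,
#' `'H'` or `'D'`, no header. Writing then reading reproduces the state
#' exactly.
#'
#' @param state an `sh_state`.
#' @param path file path.
#' @return `read_state` returns an `sh_state`; `write_state` its path,
#'   invisibly.
#' @export
write_state <- function(state, path) {
  lines <- apply(state, 1, function(r) paste(as_strategy_chr(r), collapse = ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  lines <- readLines(path)
  chars <- strsplit(lines, "")
  ncols <- unique(lengths(chars))
  if (length(ncols) != 1L)
    stop("ragged grid file: rows have unequal lengths", call. = FALSE)
  bad <- setdiff(unique(unlist(chars)), c("H", "D"))
  if (length(bad))
    stop("grid file contains invalid characters: ", paste(bad, collapse = " "),
         call. = FALSE)
  m <- t(vapply(chars, function(r) as.integer(r == "H"), integer(ncols)))
  new_sh_state(m)
}

#' @export
print.sh_state <- function(x, ...) {
  cat("SH lattice state", nrow(x), "x", ncol(x),
      sprintf("- honest rate %.3f\n", h_rate(x)))
  invisible(x)
}
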