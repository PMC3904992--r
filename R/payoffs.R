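#' Sample the payoffs of one pairwise SH interaction
#'
#' Draws one realization of the stochastic payoff pair for a single
#' interaction between strategies `s_i` and `s_j`. The interaction is a
#' single joint event: both participants see the same realization.
#'
#' * H-H: both players get `R`, deterministically.
#' * H-D: the honest player gets 0; the dishonest one is punished (`-s`)
#'   with probability `p_hd` and otherwise wins `b`.
#' * D-D: a fair coin picks a winner (`b` vs 0); each player is then
#'   punished independently with probability `p_dd`, and a punished
#'   player's payoff is overridden to `-s`. The two players can never win
#'   `b` simultaneously, but both may be punished.
#'
#' Randomness comes from R's global RNG stream; call [set.seed()] for
#' reproducibility.
#'
#' @param s_i,s_j strategies, `"H"` or `"D"` (integers 1/0 also accepted).
#' @param params an [sh_params()] object.
#' @return Numeric vector of length 2: payoffs of player i and player j.
#' @examples
#' set.seed(1)
#' sample_pair_payoffs("H", "H", sh_params())       # c(1, 1)
#' sample_pair_payoffs("D", "H", sh_params(p = 1))  # c(-2, 0)
#' @export
sample_pair_payoffs <- function(s_i, s_j, params) {
  validate_params(params)
  si <- as_strategy_int(s_i)
  sj <- as_strategy_int(s_j)
  R <- params$R; b <- params$b; s <- params$s
  if (si == 1L && sj == 1L) return(c(R, R))
  if (si == 1L && sj == 0L) {
    pj <- if (stats::runif(1) < params$p_hd) -s else b
    return(c(0, pj))
  }
  if (si == 0L && sj == 1L) {
    pi <- if (stats::runif(1) < params$p_hd) -s else b
    return(c(pi, 0))
  }
  # D-D: coin flip for the winner, then independent punishment overrides
  out <- if (stats::runif(1) < 0.5) c(b, 0) else c(0, b)
  if (stats::runif(1) < params$p_dd) out[1] <- -s
  if (stats::runif(1) < params$p_dd) out[2] <- -s
  out
}

#' Expected payoffs of one pairwise SH interaction
#'
#' Exact expectations of the payoff pair under the sampling scheme of
#' [sample_pair_payoffs()]:
#' H-H gives `(R, R)`; in H-D the honest player expects 0 and the
#' dishonest one `b (1 - p_hd) - s p_hd`; in D-D each player expects
#' `(1 - p_dd) b / 2 - p_dd s`.
#'
#' @inheritParams sample_pair_payoffs
#' @return Numeric vector of length 2: expected payoffs of players i and j.
#' @examples
#' expected_pair_payoffs("D", "H", sh_params(p = 0.5))  # c(0.5, 0)
#' @export
expected_pair_payoffs <- function(s_i, s_j, params) {
  validate_params(params)
  si <- as_strategy_int(s_i)
  sj <- as_strategy_int(s_j)
  R <- params$R; b <- params$b; s <- params$s
  e_d_vs_h <- b * (1 - params$p_hd) - s * params$p_hd
  e_dd <- (1 - params$p_dd) * b / 2 - params$p_dd * s
  if (si == 1L && sj == 1L) c(R, R)
  else if (si == 1L && sj == 0L) c(0, e_d_vs_h)
  else if (si == 0L && sj == 1L) c(e_d_vs_h, 0)
  else c(e_dd, e_dd)
}

# "H"/"D" labels <-> 1/0 integer coding used across the package
as_strategy_int <- function(x) {
  if (is.character(x)) {
    out <- match(x, c("D", "H")) - 1L
    if (anyNA(out)) stop("strategy must be \"H\" or \"D\"", call. = FALSE)
    return(out)
  }
  x <- as.integer(x)
  if (any(is.na(x)) || any(x != 0L & x != 1L))
    stop("strategy must be H/D or 1/0", call. = FALSE)
  x
}

as_strategy_chr <- function(x) c("D", "H")[as.integer(x) + 1L]
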