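#' Social Honesty game parameters
#'
#' Bundles the payoff and punishment parameters of the Social Honesty (SH)
#' game. Two honest players each earn the reward `R`. Against an honest
#' partner a dishonest player collects the dishonesty advantage `b` unless
#' punished, in which case it receives `-s`; punishment strikes with
#' probability `p_hd`. When two dishonest players meet, a fair coin decides
#' which of them wins `b` (the other gets 0), and each of them is then
#' punished independently with probability `p_dd`, punishment overriding
#' the coin outcome. By default both punishment probabilities equal the
#' single shared probability `p`.
#'
#' @param R reward for a mutually honest interaction (must be > 0).
#' @param b dishonesty advantage: payoff of an unpunished dishonest player
#'   facing an honest one (must be > 0).
#' @param s punishment severity: a punished player receives `-s` (s >= 0).
#' @param p shared punishment probability, used for both `p_hd` and `p_dd`
#'   unless those are given explicitly.
#' @param p_hd punishment probability in an H-D interaction, in \[0, 1\].
#' @param p_dd per-player punishment probability in a D-D interaction,
#'   in \[0, 1\].
#'
#' @return An object of class `sh_params`.
#' @examples
#' sh_params()                 # defaults: R = 1, b = 3, s = 2, p = 0.2
#' sh_params(p = 0.35, s = 8)
#' sh_params(p = 0.4, p_dd = 0)  # dishonest pairs never punished
#' @export
sh_params <- function(R = 1, b = 3, s = 2, p = 0.2, p_hd = p, p_dd = p) {
  params <- structure(
    list(R = R, b = b, s = s, p_hd = p_hd, p_dd = p_dd),
    class = "sh_params"
  )
  validate_params(params)
}

#' Validate SH game parameters
#'
#' Checks the parameter invariants (`R > 0`, `b > 0`, `s >= 0`, both
#' punishment probabilities in \[0, 1\]) and returns the object unchanged
#' when they hold.
#'
#' @param params an `sh_params` object (or a bare list with the same
#'   fields).
#' @return `params`, invisibly unchanged, if valid.
#' @export
validate_params <- function(params) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(params$R) || params$R <= 0) stop("R must be > 0", call. = FALSE)
  if (!num1(params$b) || params$b <= 0) stop("b must be > 0", call. = FALSE)
  if (!num1(params$s) || params$s < 0) stop("s must be >= 0", call. = FALSE)
  if (!num1(params$p_hd) || params$p_hd < 0 || params$p_hd > 1)
    stop("p_hd out of [0,1]", call. = FALSE)
  if (!num1(params$p_dd) || params$p_dd < 0 || params$p_dd > 1)
    stop("p_dd out of [0,1]", call. = FALSE)
  params
}

#' @export
print.sh_params <- function(x, ...) {
  cat("SH game parameters: R =", x$R, " b =", x$b, " s =", x$s,
      " p_hd =", x$p_hd, " p_dd =", x$p_dd, "\n")
  invisible(x)
}
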