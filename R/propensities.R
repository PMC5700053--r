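#' Game propensities of a pairwise activation/inactivation game
#'
#' A pair of brain regions plays a two-strategy game: strategy 1 is
#' "activate", strategy 2 is "inactivate". The game is summarised by two
#' propensities: `alpha`, the payoff coefficient for activating when the
#' neighbour is active, and `iota`, the coefficient for inactivating when the
#' neighbour is inactive. Equal positive propensities describe an emulative
#' attitude (the region tends to copy its neighbour), equal negative
#' propensities a non-emulative one (it tends to oppose it).
#'
#' Mixed-sign pairs (`alpha * iota < 0`) correspond to unconditional
#' activation or inactivation — the neighbour's state never changes the
#' preferred strategy — and are rejected in restricted mode. Restricted mode
#' additionally requires `alpha == iota` with value -1 or +1, which is the
#' regime under which the connectivity matrix is identifiable by linear least
#' squares.
#'
#' @param alpha Activation propensity (dimensionless real).
#' @param iota Inactivation propensity (dimensionless real).
#' @param restricted Logical; if `TRUE` enforce `alpha == iota` and
#'   `alpha` in `{-1, +1}`.
#' @return An object of class `game_propensities` with fields `alpha`, `iota`.
#' @seealso [reduce_payoff_matrix()], [payoff_difference()],
#'   [activation_threshold()]
#' @export
#' @examples
#' game_propensities(1, 1)            # emulative
#' game_propensities(-0.5, -2, restricted = FALSE)  # non-emulative, general
game_propensities <- function(alpha, iota, restricted = FALSE) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(iota), length(iota) == 1L, is.finite(iota))
  if (restricted) {
    if (alpha * iota < 0) {
      stop("mixed-sign propensities (alpha*iota < 0) describe unconditional ",
           "activation/inactivation and are excluded from the network model",
           call. = FALSE)
    }
    if (alpha != iota || !(alpha %in% c(-1, 1))) {
      stop("restricted mode requires alpha == iota with value -1 or +1",
           call. = FALSE)
    }
  }
  structure(list(alpha = alpha, iota = iota), class = "game_propensities")
}

#' @export
print.game_propensities <- function(x, ...) {
  att <- if (x$alpha > 0 && x$iota > 0) "emulative"
         else if (x$alpha < 0 && x$iota < 0) "non-emulative"
         else "indifferent"
  cat(sprintf("<game_propensities> alpha = %g, iota = %g (%s)\n",
              x$alpha, x$iota, att))
  invisible(x)
}

#' Reduce a 2x2 payoff matrix to its equivalent diagonal game
#'
#' Any two-strategy payoff matrix `B` induces the same replicator dynamics as
#' the diagonal game `diag(alpha, iota)` with `alpha = B[1,1] - B[2,1]` and
#' `iota = B[2,2] - B[1,2]`: only payoff differences between strategies
#' matter, not their absolute levels.
#'
#' @param B A 2x2 numeric matrix of payoffs; `B[i, j]` is the payoff of
#'   playing strategy `i` against strategy `j`.
#' @param restricted Passed to [game_propensities()].
#' @return A [game_propensities()] object.
#' @export
#' @examples
#' reduce_payoff_matrix(matrix(c(3, 5, 0, 1), 2, 2))  # alpha = -2, iota = 1
reduce_payoff_matrix <- function(B, restricted = FALSE) {
  if (!is.matrix(B) || !all(dim(B) == c(2L, 2L))) {
    stop("payoff matrix must be 2x2", call. = FALSE)
  }
  if (!is.numeric(B) || !all(is.finite(B))) {
    stop("payoff matrix entries must be finite numbers", call. = FALSE)
  }
  game_propensities(alpha = B[1, 1] - B[2, 1],
                    iota  = B[2, 2] - B[1, 2],
                    restricted = restricted)
}

#' Payoff difference between activation and inactivation
#'
#' Given the neighbour's activation level `x_w`, the focal region compares
#' the activation payoff `alpha * x_w` against the inactivation payoff
#' `iota * (1 - x_w)`. Their difference
#' `dp = (alpha + iota) * x_w - iota`
#' drives the replicator dynamics: the region raises its activation when
#' `dp > 0` and lowers it when `dp < 0`.
#'
#' @param x_w Neighbour activation level(s) in `[0, 1]` (vectorised).
#' @param props A [game_propensities()] object.
#' @return Numeric vector of payoff differences.
#' @export
payoff_difference <- function(x_w, props) {
  stopifnot(inherits(props, "game_propensities"), is.numeric(x_w))
  if (any(x_w < 0 | x_w > 1, na.rm = FALSE)) {
    stop("activation level x_w must lie in [0, 1]", call. = FALSE)
  }
  (props$alpha + props$iota) * x_w - props$iota
}

#' Activation threshold of a pairwise game
#'
#' The neighbour activation level at which the payoff difference changes
#' sign: `d = iota / (alpha + iota)`. An emulative region increases its
#' activation when the neighbour is above the threshold; a non-emulative
#' region does so when the neighbour is below it. Undefined for degenerate
#' games with `alpha + iota == 0`.
#'
#' @param props A [game_propensities()] object.
#' @return The threshold, a real in `[0, 1]` for equal-sign propensities.
#' @export
activation_threshold <- function(props) {
  stopifnot(inherits(props, "game_propensities"))
  s <- props$alpha + props$iota
  if (s == 0) {
    stop("degenerate game: alpha + iota == 0, activation threshold undefined",
         call. = FALSE)
  }
  props$iota / s
}
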