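#' Stage-game payoff matrix
#'
#' Constructs the 2x2 Prisoner's Dilemma stage-game payoff matrix from the
#' row player's point of view.  The default is the matrix used throughout the
#' package: reward 5 for mutual cooperation, sucker payoff 0, temptation 10,
#' punishment 1 for mutual defection.
#'
#' @param reward_cc Payoff when both players cooperate.
#' @param sucker_cd Payoff when the row player cooperates and the column
#'   player defects.
#' @param temptation_dc Payoff when the row player defects and the column
#'   player cooperates.
#' @param punishment_dd Payoff when both players defect.
#' @return An object of class `payoff_matrix`: a named list with components
#'   `reward_cc`, `sucker_cd`, `temptation_dc`, `punishment_dd`.
#' @examples
#' pm <- payoff_matrix()
#' expected_payoff(1, 1, pm)  # 5
#' @export
payoff_matrix <- function(reward_cc = 5, sucker_cd = 0, temptation_dc = 10,
                          punishment_dd = 1) {
  vals <- c(reward_cc, sucker_cd, temptation_dc, punishment_dd)
  if (!is.numeric(vals) || length(vals) != 4L || any(!is.finite(vals)))
    stop("all four payoff entries must be finite numbers", call. = FALSE)
  structure(
    list(reward_cc = as.numeric(reward_cc), sucker_cd = as.numeric(sucker_cd),
         temptation_dc = as.numeric(temptation_dc),
         punishment_dd = as.numeric(punishment_dd)),
    class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  m <- matrix(c(x$reward_cc, x$sucker_cd, x$temptation_dc, x$punishment_dd),
              2, 2, byrow = TRUE,
              dimnames = list(c("C", "D"), c("C", "D")))
  cat("Prisoner's Dilemma payoff matrix (row player):\n")
  print(m)
  invisible(x)
}

#' Bilinear coefficients of the stationary payoff
#'
#' The expected stage payoff of the row player at cooperation probabilities
#' (p1, p2) is bilinear, `U = b11 p1 p2 + b1 p1 + b2 p2 + b0`.  With the
#' default matrix this is `-4 p1 p2 - p1 + 9 p2 + 1`.
#'
#' @param payoffs A [payoff_matrix()].
#' @return Named numeric vector `c(b11, b1, b2, b0)`.
#' @export
payoff_coefficients <- function(payoffs = payoff_matrix()) {
  stopifnot(inherits(payoffs, "payoff_matrix"))
  c(b11 = payoffs$reward_cc - payoffs$sucker_cd - payoffs$temptation_dc +
        payoffs$punishment_dd,
    b1 = payoffs$sucker_cd - payoffs$punishment_dd,
    b2 = payoffs$temptation_dc - payoffs$punishment_dd,
    b0 = payoffs$punishment_dd)
}

#' Expected payoff at given cooperation probabilities
#'
#' Evaluates the row player's expected stage payoff when the two players
#' cooperate independently with probabilities `p1` and `p2`.  Vectorized over
#' `p1` and `p2`.
#'
#' @param p1,p2 Cooperation probabilities in \[0, 1\] (recycled to a common
#'   length).
#' @inheritParams payoff_coefficients
#' @return Numeric vector of payoffs.
#' @examples
#' expected_payoff(0, 0)        # 1, mutual defection
#' expected_payoff(0, 1)        # 10, temptation
#' expected_payoff(0.5, 0.5)    # 4
#' @export
expected_payoff <- function(p1, p2, payoffs = payoff_matrix()) {
  if (any(!is.finite(p1)) || any(!is.finite(p2)) ||
      any(p1 < 0 | p1 > 1) || any(p2 < 0 | p2 > 1))
    stop("cooperation probabilities must lie in [0, 1]", call. = FALSE)
  b <- payoff_coefficients(payoffs)
  b[["b11"]] * p1 * p2 + b[["b1"]] * p1 + b[["b2"]] * p2 + b[["b0"]]
}

#' Serialize / deserialize a payoff matrix as JSON
#'
#' The JSON form is a flat object `{"CC": 5, "CD": 0, "DC": 10, "DD": 1}`
#' keyed by the row player's action followed by the column player's.
#'
#' @param payoffs A [payoff_matrix()].
#' @return `payoff_to_json()` returns a JSON string; `payoff_from_json()`
#'   returns a [payoff_matrix()].
#' @export
payoff_to_json <- function(payoffs = payoff_matrix()) {
  stopifnot(inherits(payoffs, "payoff_matrix"))
  jsonlite::toJSON(
    list(CC = payoffs$reward_cc, CD = payoffs$sucker_cd,
         DC = payoffs$temptation_dc, DD = payoffs$punishment_dd),
    auto_unbox = TRUE, digits = NA)
}

#' @param json A JSON string or path to a JSON file.
#' @rdname payoff_to_json
#' @export
payoff_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  need <- c("CC", "CD", "DC", "DD")
  if (!all(need %in% names(x)))
    stop("payoff JSON must contain keys CC, CD, DC, DD", call. = FALSE)
  payoff_matrix(reward_cc = x$CC, sucker_cd = x$CD,
                temptation_dc = x$DC, punishment_dd = x$DD)
}
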