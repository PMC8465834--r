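#' Build the six-state hole-transfer kinetic scheme
#'
#' Assembles the transition-rate (generator) matrix of the four-step
#' hole-transfer mechanism over the states
#' `D` (hole localized on the donor), `D*` (donor/acceptor in vibronic
#' resonance, hole still on the donor side), `A*` (resonant, hole on the
#' acceptor side), `A` (hole relaxed on the acceptor), and the absorbing
#' oxidative-damage products `PD` and `PA`. The arrows are:
#' `D -> D*` at the Arrhenius-activated rate for `dE_DA`, `D* -> D` at
#' `k_rel_D`, `D* <-> A*` at `k_HT` in both directions, `A* -> A` at
#' `k_rel_A`, `A -> A*` at the activated rate for `dE_AD`, and the damage
#' channels `D -> PD` (`k_dam_D`) and `A -> PA` (`k_dam_A`). No other
#' transitions exist.
#'
#' The matrix uses the column convention `d p/dt = Q p`: entry `Q[j, i]` is
#' the rate from state `i` to state `j`, columns sum to zero, and the
#' absorbing product columns are identically zero.
#'
#' @param rates A [rate_set()].
#' @return An object of class `kinetic_scheme`: a list with the 6x6
#'   generator matrix `Q` (s^-1, dimnames over
#'   `c("D","Dstar","Astar","A","PD","PA")`), the `states` vector, a logical
#'   `absorbing` flag vector, and the originating `rates`.
#' @examples
#' sc <- build_scheme(rate_set(k_act0 = 1e10, k_HT = 6e12))
#' sc$Q["Dstar", "D"]   # activated resonance rate out of D
#' @export
build_scheme <- function(rates) {
  if (!inherits(rates, "rate_set")) {
    ht_error("ht_invalid_parameter", "`rates` must be a rate_set")
  }
  states <- c("D", "Dstar", "Astar", "A", "PD", "PA")
  k_act_DA <- arrhenius_activation(rates$k_act0, rates$dE_DA, rates$temperature)
  k_act_AD <- arrhenius_activation(rates$k_act0, rates$dE_AD, rates$temperature)

  Q <- matrix(0, 6, 6, dimnames = list(states, states))
  Q["Dstar", "D"]     <- k_act_DA
  Q["PD",    "D"]     <- rates$k_dam_D
  Q["D",     "Dstar"] <- rates$k_rel_D
  Q["Astar", "Dstar"] <- rates$k_HT
  Q["Dstar", "Astar"] <- rates$k_HT
  Q["A",     "Astar"] <- rates$k_rel_A
  Q["Astar", "A"]     <- k_act_AD
  Q["PA",    "A"]     <- rates$k_dam_A
  diag(Q) <- -colSums(Q)

  structure(
    list(Q = Q, states = states,
         absorbing = c(D = FALSE, Dstar = FALSE, Astar = FALSE, A = FALSE,
                       PD = TRUE, PA = TRUE),
         rates = rates),
    class = "kinetic_scheme"
  )
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Hole-transfer kinetic scheme (6 states; PD, PA absorbing)\n")
  cat("Generator matrix Q (s^-1), columns = source states:\n")
  print(signif(x$Q, 4))
  invisible(x)
}

transient_states <- function(scheme) scheme$states[!scheme$absorbing]

check_initial_state <- function(scheme, initial) {
  if (!initial %in% scheme$states) {
    ht_error("ht_invalid_parameter",
             sprintf("unknown initial state '%s'", initial))
  }
  if (scheme$absorbing[[initial]]) {
    ht_error("ht_invalid_parameter",
             sprintf("initial state '%s' is absorbing", initial))
  }
  initial
}
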