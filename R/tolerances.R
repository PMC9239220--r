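#' Numeric tolerances used throughout the package
#'
#' A single place for the numeric tolerances applied everywhere:
#' `feasibility` (bound violation allowed on solver output, 1e-9),
#' `balance` (mass-balance residual allowed on any returned flux vector,
#' 1e-6) and `zero` (absolute flux below which a reaction is classified
#' as carrying no flux, 1e-6).
#'
#' @return Named list with elements `feasibility`, `balance`, `zero`.
#' @examples
#' fluxTolerances()$balance
#' @export
fluxTolerances <- function() {
  list(feasibility = 1e-9, balance = 1e-6, zero = 1e-6)
}

.tol <- list(feasibility = 1e-9, balance = 1e-6, zero = 1e-6)
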