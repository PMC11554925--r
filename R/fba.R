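#' Flux balance analysis
#'
#' Solves the FBA linear program: optimize a reaction flux (or the stored
#' objective) subject to the steady-state constraint `S v = 0` and the flux
#' bounds. The LP is solved with the package's deterministic bounded-variable
#' simplex (tolerance 1e-9), so repeated runs are bit-identical.
#'
#' @param net a [metabolic_network()].
#' @param objective reaction identifier to optimize; `NULL` uses the
#'   network's stored objective coefficients.
#' @param sense `"max"` or `"min"`.
#' @return list with `flux` (named vector over reactions), `objective`
#'   (optimal value) and `status` (`"optimal"`).
#' @section Errors: an infeasible LP raises a `dcfba_infeasible_error`
#'   carrying the unbalanced metabolite set in `$violated`; an unbounded LP
#'   raises a `dcfba_unbounded_error`.
#' @export
fba_optimize <- function(net, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  obj <- if (is.null(objective)) {
    net$objective
  } else {
    if (!objective %in% net$reactions) {
      stop_model(sprintf("unknown objective reaction '%s'", objective))
    }
    setNames(as.numeric(net$reactions == objective), net$reactions)
  }
  res <- lp_solve(obj, net$stoich, rep(0, length(net$metabolites)),
                  net$lower, net$upper, maximize = (sense == "max"))
  if (res$status == "infeasible") {
    stop_infeasible(
      sprintf("FBA infeasible; unbalanced metabolite(s): %s",
              paste(res$violated, collapse = ", ")),
      violated = res$violated)
  }
  if (res$status == "unbounded") {
    stop_unbounded("FBA objective is unbounded for the requested sense")
  }
  list(flux = setNames(res$x, net$reactions),
       objective = res$objective, status = res$status)
}

#' Minimal oxygen uptake at a production-envelope point
#'
#' Fixes growth, glucose, acetoin and 2,3-butanediol exchange fluxes to the
#' given mass-specific rates (converted to mmol/gDW/h at this boundary) and
#' returns the oxygen exchange flux of minimal magnitude, i.e. the maximal
#' value of the non-positive oxygen exchange flux. Negative values indicate
#' uptake.
#'
#' @param net the production-strain network (e.g. [builtin_network()]).
#' @param mu growth rate (1/h).
#' @param gamma glucose exchange rate (g/gDW/h, <= 0 for uptake).
#' @param delta total diol (acetoin + butanediol) secretion rate (g/gDW/h).
#' @param alpha acetoin exchange rate (g/gDW/h; negative = uptake). The
#'   butanediol rate is `beta = delta - alpha`, which must be >= 0.
#' @param reactions named character vector mapping the roles `growth`,
#'   `glucose`, `acetoin`, `butanediol`, `oxygen` to reaction identifiers.
#' @param maintenance optional override for the ATP-maintenance lower bound
#'   (mmol/gDW/h); e.g. 0 to relax it for degenerate zero-rate states.
#' @return the oxygen exchange flux `xi` (mmol/gDW/h, <= 0).
#' @section Errors: a rate combination outside the network's feasible cone
#'   raises a `dcfba_infeasible_error`; this is the envelope-consistency
#'   signal used by [verify_envelope()].
#' @export
min_oxygen_uptake <- function(net, mu, gamma, delta, alpha,
                              reactions = c(growth = "BIOMASS",
                                            glucose = "EX_glc",
                                            acetoin = "EX_actn",
                                            butanediol = "EX_btd",
                                            oxygen = "EX_o2"),
                              maintenance = NULL) {
  beta <- delta - alpha
  if (beta < -1e-12) {
    stop_domain("beta = delta - alpha must be non-negative")
  }
  if (!is.null(maintenance) && "ATPM" %in% net$reactions) {
    net <- set_bounds(net, "ATPM", lower = maintenance)
  }
  net <- fix_flux(net, reactions[["growth"]], mu)
  net <- fix_flux(net, reactions[["glucose"]], g_to_mmol(gamma, "glucose"))
  net <- fix_flux(net, reactions[["acetoin"]], g_to_mmol(alpha, "acetoin"))
  net <- fix_flux(net, reactions[["butanediol"]], g_to_mmol(beta, "butanediol"))
  sol <- fba_optimize(net, objective = reactions[["oxygen"]], sense = "max")
  xi <- sol$objective
  if (xi > 1e-6) {
    stop_model(sprintf("oxygen exchange came out positive (%.3g); check the network", xi))
  }
  min(xi, 0)
}
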