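#' @include AllClasses.R
NULL

#' Activity budget of a decoded deployment
#'
#' Each fix contributes its interval to the next fix to its decoded
#' state's total; the last fix contributes the median inter-fix
#' interval. Unclassified gaps stay out of the activity totals but
#' remain in the deployment duration.
#'
#' @param sequence a \linkS4class{BehaviorSequence} or per-fix state
#'   vector.
#' @param deployment the matching \linkS4class{MurreDeployment}.
#' @return named list with tColonyH, tFlyH, tSwimH, tDiveH and
#'   deploymentDurH (hours).
#' @export
activityBudget <- function(sequence, deployment) {
  states <- if (is.character(sequence)) sequence else sequence@states
  fx <- deployment@fixes
  if (!length(states) || length(states) != nrow(fx))
    stop("sequence empty or not aligned with fixes")
  dtH <- diff(as.numeric(fx$t)) / 3600
  dtH <- c(dtH, if (length(dtH)) stats::median(dtH) else
    as.numeric(deployment@endT - deployment@startT, units = "hours"))
  tot <- vapply(BEHAVIOR_STATES,
                function(s) sum(dtH[states == s]), numeric(1))
  list(tColonyH = tot[["COLONY"]], tFlyH = tot[["FLY"]],
       tSwimH = tot[["SWIM"]], tDiveH = tot[["DIVE"]],
       deploymentDurH = as.numeric(deployment@endT - deployment@startT,
                                   units = "hours"))
}

#' Activity-budget daily energy expenditure
#'
#' DEE (kJ/day) = (r_colony T_colony + r_fly T_fly + r_swim T_swim +
#' r_dive T_dive) / deployment duration x 24, with the default rates
#' 32, 532.8, 100.8 and 97.2 kJ/h. Time not covered by the four
#' behaviours contributes zero energy but stays in the denominator;
#' set \code{renormalize = TRUE} to divide by classified time instead.
#'
#' @param budget activity budget from \code{\link{activityBudget}}.
#' @param rates named kJ/h rates (COLONY, FLY, SWIM, DIVE).
#' @param renormalize divide by classified rather than deployment hours.
#' @return daily energy expenditure in kJ/day.
#' @export
dee <- function(budget, rates = pipelineConfig()@energyRatesKjPerH,
                renormalize = FALSE) {
  if (budget$deploymentDurH <= 0) stop("deployment duration must be > 0")
  kj <- rates[["COLONY"]] * budget$tColonyH +
    rates[["FLY"]] * budget$tFlyH +
    rates[["SWIM"]] * budget$tSwimH +
    rates[["DIVE"]] * budget$tDiveH
  denom <- if (renormalize)
    budget$tColonyH + budget$tFlyH + budget$tSwimH + budget$tDiveH
  else budget$deploymentDurH
  if (denom <= 0) stop("no classified time to renormalize over")
  kj / denom * 24
}
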