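#' Final ancestry proportions implied by a migration schedule
#'
#' Probability that a sampled lineage's most recent migrant ancestor came from
#' each source: \code{a_p = sum_t m_p(t) prod_{1 < s < t} (1 - M(s))}, where
#' \code{M(s)} is the total replacement at generation \code{s}. Fractions sum
#' to 1 for any valid schedule.
#'
#' @param schedule A [MigrationSchedule-class].
#' @return Named numeric vector of genome-fraction expectations per source.
#' @examples
#' sched <- migrationSchedule(
#'   rbind(0, c(0, 0, 0.2), c(1, 0, 0)),
#'   populations = c("EUR", "NAT", "AFR"))
#' scheduleProportions(sched)  # EUR 0.8, AFR 0.2
#' @export
scheduleProportions <- function(schedule) {
  m <- migrationMatrix(schedule)
  M <- rowSums(m)
  T0 <- nrow(m)
  a <- numeric(ncol(m))
  surv <- 1
  for (t in 2:T0) {
    a <- a + m[t, ] * surv
    surv <- surv * (1 - M[t])
  }
  names(a) <- colnames(m)
  a
}

#' Demographic model identifiers
#'
#' Three nested pulse-model hypotheses: \code{BASE} (founding European/Native
#' admixture followed by one African pulse; free parameters \code{t0},
#' \code{t_afr}), \code{EUR_PULSE} and \code{AFR_PULSE} (base model plus one
#' later pulse of European or African migration; additional free parameters
#' \code{t_pulse}, \code{m_pulse}). Pulse magnitudes other than
#' \code{m_pulse}, and the founding split, are pinned so the schedule
#' reproduces the observed ancestry proportions exactly.
#' @export
DEMOGRAPHIC_MODELS <- c("BASE", "EUR_PULSE", "AFR_PULSE")

.model_code <- function(model) {
  match(match.arg(model, DEMOGRAPHIC_MODELS), DEMOGRAPHIC_MODELS) - 1L
}

.model_param_names <- function(model) {
  if (model == "BASE") c("t0", "t_afr") else c("t0", "t_afr", "t_pulse", "m_pulse")
}

#' Build a migration schedule from a demographic model
#'
#' Converts model parameters (admixture times in generations, pulse magnitude)
#' into a concrete per-generation migration schedule. The founding split
#' between the two founding sources and the African pulse magnitude are solved
#' so that the schedule-implied final proportions equal \code{proportions}
#' exactly. Non-integer times are mapped to the integer generation grid by
#' splitting the event between the two adjacent generations proportionally to
#' the fractional part.
#'
#' @param model "BASE", "EUR_PULSE" or "AFR_PULSE".
#' @param params Named or positional numeric vector: \code{t0}, \code{t_afr}
#'   and, for pulse models, \code{t_pulse}, \code{m_pulse}. Times are
#'   generations before present (sampled generation = 1); pulses must fall at
#'   least one generation after founding.
#' @param proportions Length-3 proportions (European-like, Native-like,
#'   African) summing to 1; names are carried to the schedule.
#' @return A [MigrationSchedule-class].
#' @examples
#' sched <- buildMigrationSchedule("BASE", c(t0 = 12, t_afr = 8),
#'                                 c(EUR = 0.60, NAT = 0.35, AFR = 0.05))
#' scheduleProportions(sched)
#' @export
buildMigrationSchedule <- function(model = DEMOGRAPHIC_MODELS, params,
                                   proportions) {
  model <- match.arg(model)
  if (length(proportions) != 3 || abs(sum(proportions) - 1) > 1e-6)
    stop("proportions must be three fractions summing to 1")
  k <- if (model == "BASE") 2L else 4L
  if (length(params) != k)
    stop(sprintf("model %s needs %d parameters (%s)", model, k,
                 paste(.model_param_names(model), collapse = ", ")))
  m <- build_schedule_cpp(.model_code(model), as.numeric(params),
                          as.numeric(proportions))
  if (!isTRUE(attr(m, "feasible")))
    stop(sprintf("infeasible parameters for model %s (%s)", model,
                 attr(m, "reason")))
  pops <- names(proportions)
  if (is.null(pops)) pops <- c("EUR", "NAT", "AFR")
  migrationSchedule(m, populations = pops)
}
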