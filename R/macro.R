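#' @include droplet.R
NULL

#' Read / write injection macros as YAML
#'
#' Macros are declarative ordered lists of primitive needle/pressure
#' actions, stored as YAML so they can be edited and versioned outside
#' the code.
#'
#' @param path YAML file path.
#' @param macro an \linkS4class{InjectionMacro}.
#' @return \code{macroFromYaml} returns an \linkS4class{InjectionMacro};
#'   \code{macroToYaml} returns the path invisibly.
#' @export
macroFromYaml <- function(path) {
  doc <- yaml::read_yaml(path)
  InjectionMacro(name = doc$name, steps = doc$steps)
}

#' @rdname macroFromYaml
#' @export
macroToYaml <- function(macro, path) {
  yaml::write_yaml(list(name = macro@name, steps = macro@steps), path)
  invisible(path)
}

#' Site-specific default injection macros
#'
#' Ships the validated per-site macros: duct of Cuvier (touchdown,
#' puncture, slight retraction along the needle axis, single pulse),
#' perivitelline space (angled entry, puncture, retraction into the PVS,
#' repeated pulses each followed by an operator checkpoint so users can
#' stop once enough cells are delivered) and hindbrain ventricle (edge
#' pose, puncture, double pulse).
#'
#' @param site one of "doc", "pvs", "hindbrain".
#' @return an \linkS4class{InjectionMacro}.
#' @export
defaultMacro <- function(site = c("doc", "pvs", "hindbrain")) {
  site <- match.arg(site)
  path <- system.file("extdata", "macros", paste0(site, ".yaml"),
                      package = "larvaInject")
  if (!nzchar(path)) stop("bundled macro files not found")
  macroFromYaml(path)
}

#' Simulated per-action time costs
#'
#' Seconds charged to the simulated session clock per primitive macro
#' action. These model throughput bookkeeping only and make no claim
#' about real-hardware timing.
#'
#' @return named numeric vector of seconds.
#' @export
actionCosts <- function() {
  c(approach = 6, descend_coarse = 8, descend_fine = 5,
    await_touchdown = 2, advance_along_axis = 1, await_puncture = 3,
    retract = 1, pulse = 0.5, operator_checkpoint = 4)
}

#' Execute an injection macro against a simulated hardware context
#'
#' Steps run in order on the simulated clock. \code{await_touchdown} and
#' \code{await_puncture} consume detector events from the context; a
#' missing event is a detector timeout, recorded as a failure reason —
#' never an exception — and aborts the remaining steps for this larva.
#' In semi-automated mode, \code{operator_checkpoint} steps consult the
#' scripted operator callback, which may abort the larva.
#'
#' @param macro an \linkS4class{InjectionMacro}.
#' @param context list with elements \code{touchdownEvent} and
#'   \code{punctureEvent} (event lists or NULL), optional
#'   \code{operator} callback \code{function(larvaId, trace)} returning
#'   "continue" or "abort", and \code{larvaId}.
#' @param costs named per-action second costs ([actionCosts()]).
#' @param startTime simulated clock at macro start.
#' @return list with \code{outcome} ("success"/"failure"), \code{reason},
#'   \code{trace} (data frame of executed steps), \code{endTime} and
#'   \code{pulsesDelivered}.
#' @export
executeMacro <- function(macro, context = list(), costs = actionCosts(),
                         startTime = 0) {
  steps <- flattenMacroSteps(macro@steps)
  t <- startTime
  rows <- list()
  outcome <- "success"; reason <- NA_character_
  punctured <- FALSE
  pulses <- 0L
  for (s in steps) {
    act <- s$action
    t0 <- t
    t <- t + unname(costs[act])
    status <- "ok"
    if (act == "await_touchdown") {
      ev <- context$touchdownEvent
      if (is.null(ev) || !identical(ev$kind, "touchdown")) {
        status <- "timeout"; outcome <- "failure"; reason <- "touchdown_timeout"
      }
    } else if (act == "await_puncture") {
      ev <- context$punctureEvent
      if (is.null(ev) || !identical(ev$kind, "puncture")) {
        status <- "timeout"; outcome <- "failure"; reason <- "puncture_timeout"
      } else punctured <- TRUE
    } else if (act == "operator_checkpoint") {
      if (!is.null(context$operator)) {
        resp <- context$operator(context$larvaId, do.call(rbind, rows))
        if (identical(resp, "abort")) {
          status <- "abort"; outcome <- "failure"; reason <- "operator_abort"
        }
      }
    } else if (act == "pulse") {
      pulses <- pulses + 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      action = act,
      detail = if (!is.null(s$distance)) as.character(s$distance)
               else if (!is.null(s$pressure)) as.character(s$pressure)
               else "",
      t_start = t0, t_end = t, status = status,
      stringsAsFactors = FALSE)
    if (outcome == "failure") break
  }
  trace <- if (length(rows)) do.call(rbind, rows) else
    data.frame(action = character(0), detail = character(0),
               t_start = numeric(0), t_end = numeric(0),
               status = character(0))
  list(outcome = outcome, reason = reason, trace = trace, endTime = t,
       pulsesDelivered = pulses, punctured = punctured)
}
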