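# Structured error conditions. Every error the package raises carries a
# subclass of "dcfba_error" so callers (and tests) can dispatch on the
# failure mode instead of matching message strings.

dcfba_stop <- function(message, class, call = sys.call(-1), ...) {
  stop(errorCondition(message, ..., class = c(class, "dcfba_error", "error"),
                      call = call))
}

stop_parse <- function(message, ...) dcfba_stop(message, "dcfba_parse_error", ...)
stop_model <- function(message, ...) dcfba_stop(message, "dcfba_model_error", ...)
stop_edit <- function(message, ...) dcfba_stop(message, "dcfba_edit_error", ...)
stop_domain <- function(message, ...) dcfba_stop(message, "dcfba_domain_error", ...)
stop_data <- function(message, ...) dcfba_stop(message, "dcfba_data_error", ...)
stop_config <- function(message, ...) dcfba_stop(message, "dcfba_config_error", ...)
stop_build <- function(message, ...) dcfba_stop(message, "dcfba_build_error", ...)
stop_solver <- function(message, ...) dcfba_stop(message, "dcfba_solver_error", ...)

stop_insufficient_data <- function(message, ...) {
  dcfba_stop(message, c("dcfba_insufficient_data_error", "dcfba_data_error"), ...)
}

#' @param violated bound/row identifiers responsible for the infeasibility,
#'   if known.
#' @noRd
stop_infeasible <- function(message, violated = NULL, ...) {
  dcfba_stop(message, "dcfba_infeasible_error", violated = violated, ...)
}

stop_unbounded <- function(message, ...) dcfba_stop(message, "dcfba_unbounded_error", ...)
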