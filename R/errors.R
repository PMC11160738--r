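# Condition helpers. Every user-facing failure is classed so the CLI can map
# it to an exit code: configuration (2), data (3), capacity (4).

abort_config <- function(message, ...) {
  abort(message, class = "srmforge_config_error", ...)
}

abort_data <- function(message, ...) {
  abort(message, class = "srmforge_data_error", ...)
}

abort_capacity <- function(message, ...) {
  abort(message, class = "srmforge_capacity_error", ...)
}

abort_state <- function(message, ...) {
  abort(message, class = "srmforge_state_error", ...)
}

#' Map a classed srmforge condition to a process exit code
#'
#' Used by the command-line wrapper: 2 for configuration errors, 3 for data
#' errors, 4 for capacity errors, 1 for anything else.
#'
#' @param cond A condition object.
#' @return Integer exit code.
#' @export
exit_code_for <- function(cond) {
  if (inherits(cond, "srmforge_config_error")) return(2L)
  if (inherits(cond, "srmforge_data_error")) return(3L)
  if (inherits(cond, "srmforge_capacity_error")) return(4L)
  1L
}
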