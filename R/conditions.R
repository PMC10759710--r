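# Classed conditions so callers (and the CLI exit-code mapping) can
# distinguish parse, contract, and convergence failures.

pc_error <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "parityclock_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

pc_parse_error <- function(message, ...) {
  pc_error(message, "pc_parse_error", ...)
}

pc_contract_error <- function(message, ...) {
  pc_error(message, "pc_contract_error", ...)
}

pc_convergence_error <- function(message, ...) {
  pc_error(message, "pc_convergence_error", ...)
}

pc_estimation_error <- function(message, ...) {
  pc_error(message, "pc_estimation_error", ...)
}

pc_warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "parityclock_warning")))
}
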