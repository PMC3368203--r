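# Classed conditions so callers can distinguish configuration mistakes,
# malformed data structures, and numerical failures programmatically.

stop_config <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("fluxmap_config_error", "fluxmap_error")))
}

stop_structural <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("fluxmap_structural_error", "fluxmap_error")))
}

stop_rank <- function(msg, columns = NULL) {
  stop(errorCondition(msg, columns = columns,
                      class = c("fluxmap_rank_error", "fluxmap_error")))
}

stop_no_root <- function(msg, interval = NULL, target = NA_real_) {
  stop(errorCondition(msg, interval = interval, target = target,
                      class = c("fluxmap_no_root_error", "fluxmap_error")))
}

stop_perfect_fit <- function(msg) {
  stop(errorCondition(msg, class = c("fluxmap_perfect_fit_error", "fluxmap_error")))
}

stop_positivity <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("fluxmap_positivity_error", "fluxmap_error")))
}
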