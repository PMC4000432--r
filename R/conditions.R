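# Classed conditions so callers (and the CLI) can distinguish bad user input
# from degenerate data that merely cannot support estimation.

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("clustericc_input_error", "clustericc_error")))
}

stop_degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("clustericc_degenerate_error", "clustericc_error")))
}

stop_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("clustericc_io_error", "clustericc_error")))
}

stop_fixture <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("clustericc_fixture_error", "clustericc_error")))
}

# round half away from zero (printed tables round 78.55 -> 78.6, not banker's)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
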