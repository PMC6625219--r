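#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. Seeded randomness always goes
# through with_seed() so no function leaves a footprint on .Random.seed.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_nirspain <- function(msg, class) {
  stop(structure(
    class = c(class, "nirspain_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_validation <- function(msg) abort_nirspain(msg, "nirspain_validation_error")
stop_config <- function(msg) abort_nirspain(msg, "nirspain_config_error")
stop_parse <- function(msg) abort_nirspain(msg, "nirspain_parse_error")

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop_validation(msg)
  invisible(TRUE)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream of child seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Exact decimal round-trip for doubles in text formats.
num_to_chr <- function(x) sprintf("%.17g", x)
chr_to_num <- function(x) as.numeric(x)
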