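# Internal helpers shared across modules.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

stop_config <- function(msg) abort(msg, class = "lupusrnn_config_error")
stop_data <- function(msg) abort(msg, class = "lupusrnn_data_error")
stop_schema <- function(msg) abort(msg, class = "lupusrnn_schema_error")
stop_domain <- function(msg) abort(msg, class = "lupusrnn_domain_error")

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == trunc(x)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)

# Round half-up to `digits` decimals (base round() is half-to-even).
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}
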