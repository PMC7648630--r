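# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded generators are pure functions of their spec.
with_rng_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_validation <- function(...) {
  stop(structure(class = c("lamquant_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_io <- function(...) {
  stop(structure(class = c("lamquant_io_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_validation(name, " must be a single positive finite number, got ",
                    deparse(substitute(x)))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != floor(x)) {
    stop_validation(name, " must be an integer >= ", min)
  }
  invisible(as.integer(x))
}

# Round half away from zero (round-half-up for non-negatives); base round()
# does banker's rounding, which would make 8-bit quantization value-dependent.
round_half_up <- function(x) floor(x + 0.5)

# Offsets (dy, dx) of a disk structuring element of the given radius.
disk_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}
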