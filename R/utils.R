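# Internal helpers shared across modules.

# Run `expr` under a fixed, platform-stable RNG state and restore the caller's
# state afterwards. Mersenne-Twister / Inversion / Rejection are pinned so that
# seeded outputs are bit-identical across machines and R sessions.
with_rng <- function(seed, expr) {
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
  }, add = TRUE)
  suppressWarnings(set.seed(as.integer(seed),
    kind = "Mersenne-Twister",
    normal.kind = "Inversion", sample.kind = "Rejection"
  ))
  expr
}

# Deterministic seed-splitting rule: stream k of master seed s gets
# (s + 1000003 * k) mod (2^31 - 1). Keeps every derived seed a valid 32-bit
# integer and makes cohorts generated from one master seed independent.
derive_seed <- function(seed, stream) {
  (as.double(seed) + 1000003 * as.double(stream)) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_brcadx <- function(...) stop(..., call. = FALSE)

assert_fraction <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !lo_ok || !hi_ok) {
    stop_brcadx(sprintf("'%s' must be a fraction in %s0, 1%s",
      name, if (open_left) "(" else "[", if (open_right) ")" else "]"
    ))
  }
  invisible(x)
}

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != round(x)) {
    stop_brcadx(sprintf("'%s' must be a positive integer", name))
  }
  invisible(as.integer(x))
}

# Midrank (Mann-Whitney) AUC of `score` for predicting `positive`.
# Shared by probe screening and fold metrics.
rank_auc <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    stop_brcadx("AUC requires both classes to be present")
  }
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
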