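# Internal helpers shared across modules.

#' Arrhythmia label vocabulary
#'
#' The six rhythm classes handled by the package, in canonical order:
#' normal sinus rhythm, atrial fibrillation, premature ventricular
#' contraction, premature atrial contraction, left and right bundle branch
#' block.
#'
#' @return Character vector of length 6.
#' @export
ecg_classes <- function() {
  c("Normal", "AF", "PVC", "PAC", "LBBB", "RBBB")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stopf("`%s` must be a finite number in [%s, %s]", name, format(min), format(max))
  }
  invisible(x)
}

# Sample-index moving average with window of n samples (centred not needed;
# trailing alignment is what the Pan-Tompkins integrator uses).
moving_sum <- function(x, n) {
  cs <- cumsum(c(0, x))
  n <- min(n, length(x))
  out <- cs[(n + 1):(length(x) + 1)] - cs[1:(length(x) - n + 1)]
  c(rep(out[1], n - 1), out)
}

# Local RNG scope: run `expr` under `seed` without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  force(expr)
}
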