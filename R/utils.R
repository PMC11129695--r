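#' Convert a frame count to seconds
#'
#' @param frames integer number of frames (may be a vector).
#' @param fps frames per second of the recording; must be > 0.
#' @return duration(s) in seconds, `frames / fps`.
#' @examples
#' frames_to_seconds(120, 120) # 1 s
#' frames_to_seconds(20000, 120) / 60 # the 2.8-min analysis window
#' @export
frames_to_seconds <- function(frames, fps) {
  if (!is.numeric(fps) || length(fps) != 1L || is.na(fps) || fps <= 0) {
    stop("`fps` must be a single positive number, got: ", deparse(fps))
  }
  frames / fps
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. All stochastic functions in the package go through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      stop("`seed` must be a single number")
    }
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a per-task seed from a master seed, staying inside 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
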