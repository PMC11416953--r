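#' Wrap an angle into (-pi, pi]
#'
#' All angles in the package are radians, counter-clockwise positive, with 0
#' pointing along the allocentric +x axis.
#'
#' @param theta numeric vector of angles (radians).
#' @return angles wrapped into the half-open interval (-pi, pi].
#' @export
#' @examples
#' wrap_angle(3 * pi)      # pi
#' wrap_angle(-pi)         # pi (the interval is open at -pi)
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  # %% maps exact multiples of 2*pi + pi to -pi; the convention is (-pi, pi]
  w[w <= -pi] <- pi
  w
}

#' Derive a named substream seed from a top-level seed
#'
#' One top-level seed fans out deterministically to independent named
#' substreams (projection wiring, policy draws, environment noise, ...), so a
#' single integer reproduces an entire experiment. Kept below 2^31.
#'
#' @param seed integer top-level seed.
#' @param name character substream label.
#' @return an integer seed usable with [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) * 69069 + h * 104729) %% 2147483587L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
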