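#' @keywords internal
"_PACKAGE"

## Small internal helpers shared across modules.

#' Wrap angles into [0, 2*pi)
#' @param x numeric vector of angles in radians.
#' @return angles reduced modulo 2*pi into [0, 2*pi).
#' @export
wrap_angle <- function(x) {
  out <- x %% (2 * pi)
  out[out == 2 * pi] <- 0
  out
}

#' Convert hours on a 24-h clock to radians
#' @param h numeric vector of clock hours.
#' @param period_h period in hours (default 24).
#' @return angles in [0, 2*pi).
#' @export
hours_to_rad <- function(h, period_h = 24) {
  wrap_angle(2 * pi * h / period_h)
}

#' Convert radians to hours on a 24-h clock
#' @param theta numeric vector of angles in radians.
#' @param period_h period in hours (default 24).
#' @return hours in [0, period_h).
#' @export
rad_to_hours <- function(theta, period_h = 24) {
  wrap_angle(theta) * period_h / (2 * pi)
}

## Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic per-stage seed derivation from a master seed; always < 2^31.
derive_seed <- function(master_seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(master_seed) * 7919 + h * 104729) %% 2147483629 + 1)
}

## Stop unless `cond`; message built with sprintf.
fail_unless <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}

## Circular mean of angles, optionally weighted; NA if resultant ~ 0.
circular_mean <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  s <- sum(w * sin(theta))
  c_ <- sum(w * cos(theta))
  if (sqrt(s^2 + c_^2) < 1e-12 * sum(abs(w))) return(NA_real_)
  wrap_angle(atan2(s, c_))
}

## Mean resultant length of a sample of angles.
resultant_length <- function(theta) {
  sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}
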