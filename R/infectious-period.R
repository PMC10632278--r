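#' Infectious period laws
#'
#' Constructors for the infectious period distribution \eqn{T_I} used
#' throughout the household epidemic machinery. Each law carries its mean
#' \eqn{E[T_I]}, variance and Laplace transform
#' \eqn{\phi(\theta) = E[e^{-\theta T_I}]}, which is all the final-outcome
#' algebra needs. The exponential law additionally drives the Markovian ODE
#' limit and the Gillespie simulator.
#'
#' @param rate positive recovery rate \eqn{\gamma}; the mean infectious
#'   period is \code{1/rate}.
#' @param duration positive constant infectious period.
#' @param shape positive integer Erlang shape.
#'
#' @return An object of class \code{ti_law} with fields \code{kind},
#'   \code{mean}, \code{var}, the Laplace transform \code{phi}, and (where
#'   defined) the parameters of the law.
#'
#' @examples
#' law <- ti_exponential(rate = 1)
#' law$phi(1)      # 0.5
#' ti_fixed(1)$phi(1)  # exp(-1)
#' @export
ti_exponential <- function(rate = 1) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate > 0)
  new_ti_law(
    kind = "exponential", mean = 1 / rate, var = 1 / rate^2,
    phi = function(theta) {
      ifelse(is.infinite(theta), 0, rate / (rate + theta))
    },
    rate = rate
  )
}

#' @rdname ti_exponential
#' @export
ti_fixed <- function(duration = 1) {
  stopifnot(is.numeric(duration), length(duration) == 1L, duration > 0)
  new_ti_law(
    kind = "fixed", mean = duration, var = 0,
    phi = function(theta) exp(-theta * duration),
    duration = duration
  )
}

#' @rdname ti_exponential
#' @export
ti_erlang <- function(shape, rate) {
  stopifnot(
    is.numeric(shape), length(shape) == 1L, shape >= 1,
    shape == round(shape),
    is.numeric(rate), length(rate) == 1L, rate > 0
  )
  new_ti_law(
    kind = "erlang", mean = shape / rate, var = shape / rate^2,
    phi = function(theta) {
      ifelse(is.infinite(theta), 0, (rate / (rate + theta))^shape)
    },
    shape = shape, rate = rate
  )
}

new_ti_law <- function(kind, mean, var, phi, ...) {
  structure(
    list(kind = kind, mean = mean, var = var, phi = phi, ...),
    class = "ti_law"
  )
}

#' @export
print.ti_law <- function(x, ...) {
  cat("Infectious period law:", x$kind,
      sprintf("(mean %.4g, var %.4g)\n", x$mean, x$var))
  invisible(x)
}

as_ti_law <- function(x) {
  if (inherits(x, "ti_law")) return(x)
  stop("expected a 'ti_law' object (see ti_exponential, ti_fixed, ti_erlang)")
}
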