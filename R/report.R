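#' Convert between the local rate and the local contact probability
#'
#' The probability that an infective contacts a given housemate during its
#' infectious period is \eqn{p_L = 1 - \phi(\lambda_L)}. The inverse is
#' solved numerically (closed form for the exponential law).
#'
#' @param lambda_L local rate (vectorised).
#' @param p_L local contact probability (vectorised).
#' @param T_I infectious period law.
#' @export
p_L_from_lambda_L <- function(lambda_L, T_I) {
  T_I <- as_ti_law(T_I)
  1 - T_I$phi(lambda_L)
}

#' @rdname p_L_from_lambda_L
#' @export
lambda_L_from_p_L <- function(p_L, T_I) {
  T_I <- as_ti_law(T_I)
  stopifnot(all(p_L >= 0), all(p_L <= 1))
  vapply(p_L, function(p) {
    if (p == 0) return(0)
    if (p == 1) return(Inf)
    if (T_I$kind == "exponential") return(T_I$rate * p / (1 - p))
    stats::uniroot(function(l) 1 - T_I$phi(l) - p, c(1e-12, 1e8),
                   tol = 1e-12)$root
  }, numeric(1))
}

#' Global rate attaining a target rank-generation R0
#'
#' Solves \eqn{R_0(\lambda_G) = } \code{R0_target} for \eqn{\lambda_G}
#' (monotone root find).
#'
#' @param dist a \code{hh_dist}.
#' @param lambda_L local rate.
#' @param T_I infectious period law.
#' @param R0_target desired rank-generation reproduction number (> 1).
#' @export
lambda_G_for_R0 <- function(dist, lambda_L, T_I, R0_target) {
  dist <- as_hh_dist(dist)
  T_I <- as_ti_law(T_I)
  stopifnot(R0_target > 0)
  f <- function(lg) R0(dist, lg, lambda_L, T_I) - R0_target
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(1e-10, hi), tol = 1e-12)$root
}

#' Herd immunity levels over a grid of local contact probabilities
#'
#' For each local contact probability \eqn{p_L} in the grid, chooses
#' \eqn{\lambda_G} so that the rank-generation \eqn{R_0} equals
#' \code{R0_target}, and computes the vaccine-induced level \eqn{h_C}, the
#' final-size approximation \eqn{\tilde h_D}, and (optionally) the
#' ODE-trajectory levels \eqn{h_D} (SIR) and \eqn{h_D^L} (SEIR with
#' latency rate \code{delta}). Subcritical points are flagged, not
#' errored.
#'
#' @param dist a \code{hh_dist}.
#' @param p_L_grid local contact probabilities in \eqn{[0, 1]}.
#' @param R0_target rank-generation R0 held fixed across the grid.
#' @param gamma recovery rate.
#' @param delta latency rate for the SEIR level (\code{NULL} to skip
#'   \code{h_D_L}).
#' @param ode if \code{TRUE} also compute the trajectory-based levels.
#' @param epsilon ODE seeding fraction.
#' @return Data frame: one row per grid point with \code{p_L},
#'   \code{lambda_L}, \code{lambda_G}, \code{R0}, \code{R_star},
#'   \code{h_C}, \code{h_tilde_D} and (if requested) \code{h_D},
#'   \code{h_D_L}.
#' @export
levels_grid <- function(dist, p_L_grid, R0_target = 2, gamma = 1,
                        delta = NULL, ode = TRUE, epsilon = 1e-5) {
  dist <- as_hh_dist(dist)
  T_I <- ti_exponential(gamma)
  rows <- lapply(p_L_grid, function(p) {
    lambda_L <- lambda_L_from_p_L(p, T_I)
    lambda_G <- lambda_G_for_R0(dist, lambda_L, T_I, R0_target)
    Rs <- R_star(dist, lambda_G, lambda_L, T_I)
    hc <- h_C(dist, lambda_G, lambda_L, T_I)$level
    htd <- if (is.infinite(lambda_L)) {
      h_tilde_D_highly_local(dist, lambda_G, T_I)$level
    } else {
      h_tilde_D(dist, lambda_G, lambda_L, T_I)$level
    }
    hd <- hdl <- NA_real_
    if (ode && is.finite(lambda_L) && Rs > 1) {
      hd <- h_D(dist, lambda_G, lambda_L, gamma, epsilon)$level
      if (!is.null(delta)) {
        hdl <- h_D_L(dist, lambda_G, lambda_L, gamma, delta, epsilon)$level
      }
    }
    data.frame(p_L = p, lambda_L = lambda_L, lambda_G = lambda_G,
               R0 = R0_target, R_star = Rs, supercritical = Rs > 1,
               h_C = hc, h_tilde_D = htd, h_D = hd, h_D_L = hdl)
  })
  do.call(rbind, rows)
}

#' Percentage error of the final-size approximation at one parameter point
#'
#' Computes \eqn{\tilde h_D}, the trajectory-based \eqn{h_D} (SIR, with
#' \eqn{\gamma = 1} as the time-unit convention), and the percentage error
#' \eqn{100\,|\tilde h_D - h_D| / h_D}.
#'
#' @param dist a \code{hh_dist} (or a common household size given as a
#'   single integer).
#' @param lambda_G,lambda_L contact rates.
#' @param gamma recovery rate (default 1).
#' @param epsilon ODE seeding fraction.
#' @return List with \code{h_tilde_D}, \code{h_D}, \code{pct_error},
#'   \code{R0} and \code{p_L}.
#' @export
table1_point <- function(dist, lambda_G, lambda_L, gamma = 1,
                         epsilon = 1e-5) {
  if (is.numeric(dist) && length(dist) == 1 && dist == round(dist)) {
    dist <- hh_common(dist)
  }
  dist <- as_hh_dist(dist)
  T_I <- ti_exponential(gamma)
  htd <- h_tilde_D(dist, lambda_G, lambda_L, T_I)$level
  hd <- h_D(dist, lambda_G, lambda_L, gamma, epsilon)$level
  list(
    h_tilde_D = htd, h_D = hd,
    pct_error = 100 * abs(htd - hd) / hd,
    R0 = R0(dist, lambda_G, lambda_L, T_I),
    p_L = p_L_from_lambda_L(lambda_L, T_I)
  )
}

#' Herd immunity levels at a fixed early growth rate
#'
#' Calibration used for day-unit comparisons: a reference reproduction
#' number \code{R0BBT} (with latency rate \code{delta} and recovery rate
#' \code{gamma}) fixes the early exponential growth rate \eqn{r} through
#' \eqn{R_0 = (1 + r/\delta)(1 + r/\gamma)}; for each \eqn{p_L} in the
#' grid, \eqn{\lambda_G} is then chosen so that the household model grows
#' at exactly that rate, and the herd immunity levels are computed.
#'
#' @inheritParams levels_grid
#' @param R0BBT reference reproduction number (> 1).
#' @param gamma recovery rate (default 1/4, day units).
#' @param delta latency rate (default 1/3, day units).
#' @param ode if \code{TRUE} also compute \eqn{h_D} and \eqn{h_D^L}.
#' @return Data frame with one row per grid point: \code{p_L},
#'   \code{lambda_L}, \code{r}, \code{lambda_G}, \code{R0}, \code{h_C},
#'   \code{h_tilde_D} and (if requested) \code{h_D}, \code{h_D_L}.
#' @export
calibrate_grid <- function(dist, p_L_grid, R0BBT, gamma = 1/4,
                           delta = 1/3, ode = FALSE, epsilon = 1e-5) {
  dist <- as_hh_dist(dist)
  stopifnot(R0BBT > 1)
  T_I <- ti_exponential(gamma)
  r <- r_from_R0BBT(R0BBT, gamma, delta)
  rows <- lapply(p_L_grid, function(p) {
    lambda_L <- lambda_L_from_p_L(p, T_I)
    lambda_G <- calibrate_lambda_G(dist, lambda_L, gamma, delta, r)
    hc <- h_C(dist, lambda_G, lambda_L, T_I)$level
    htd <- h_tilde_D(dist, lambda_G, lambda_L, T_I)$level
    hd <- hdl <- NA_real_
    if (ode) {
      hd <- h_D(dist, lambda_G, lambda_L, gamma, epsilon)$level
      hdl <- h_D_L(dist, lambda_G, lambda_L, gamma, delta, epsilon)$level
    }
    data.frame(p_L = p, lambda_L = lambda_L, r = r, lambda_G = lambda_G,
               R0 = R0(dist, lambda_G, lambda_L, T_I),
               h_C = hc, h_tilde_D = htd, h_D = hd, h_D_L = hdl)
  })
  do.call(rbind, rows)
}

#' Ordering verdicts and critical moment curves
#'
#' For each supplied household size distribution, reports the size-biased
#' mean and variance, the ordering verdicts in the just-supercritical and
#' weakly-local regimes, and the two critical curves in the
#' \eqn{(\mu_{\tilde H}, \sigma^2_{\tilde H})} plane that separate them:
#' \eqn{\sigma^2 = \mu(\mu - 1)} (just-supercritical, highly locally
#' infectious) and \eqn{\sigma^2 = \mu - 1} (weakly locally infectious).
#' Distributions between the curves receive contrasting verdicts.
#'
#' @param dists a \code{hh_dist} or list of them (named, optionally).
#' @return List with \code{verdicts} (data frame) and \code{curves}
#'   (functions \code{just_supercritical(mu)} and \code{weak_local(mu)}).
#' @export
orderings_report <- function(dists) {
  if (inherits(dists, "hh_dist")) dists <- list(dists)
  if (is.null(names(dists))) {
    names(dists) <- paste0("dist", seq_along(dists))
  }
  rows <- lapply(names(dists), function(nm) {
    sb <- size_bias(as_hh_dist(dists[[nm]]))
    js <- ordering_just_supercritical(sb)
    wl_gap <- (sb$mu - 1) - sb$var
    wl <- if (abs(wl_gap) < 1e-12) {
      "inconclusive"
    } else if (wl_gap > 0) "h_tilde_D > h_C" else "h_tilde_D < h_C"
    data.frame(
      id = nm, mu_tilde = sb$mu, var_tilde = sb$var,
      just_supercritical = js$verdict,
      just_supercritical_witness = ifelse(is.na(js$witness_index), NA,
                                          js$witness_index),
      weak_local = wl
    )
  })
  list(
    verdicts = do.call(rbind, rows),
    curves = list(
      just_supercritical = function(mu) mu * (mu - 1),
      weak_local = function(mu) mu - 1
    )
  )
}

#' Replicated simulation summary
#'
#' Runs \code{replicates} stochastic epidemics, classifies major
#' outbreaks against the analytic final size, and summarises the final
#' fractions. Deterministic given \code{seed}.
#'
#' @inheritParams simulate_epidemic
#' @param dist a \code{hh_dist}.
#' @param m number of households.
#' @param replicates number of independent realisations.
#' @param seed integer; replicate \code{k} uses \code{seed + k}.
#' @return List with the per-replicate data frame \code{runs}, the
#'   analytic \code{z}, the number of excluded minor outbreaks, and the
#'   mean final fraction among major outbreaks.
#' @export
simulate_summary <- function(dist, m, lambda_G, lambda_L, T_I,
                             delta = NULL, replicates = 10L, seed = 1L,
                             method = "auto") {
  dist <- as_hh_dist(dist)
  pop <- build_population(dist, m, mode = "exact")
  z <- final_size(dist, lambda_G, lambda_L, T_I)$z
  runs <- lapply(seq_len(replicates), function(k) {
    ep <- simulate_epidemic(pop, lambda_G, lambda_L, T_I, delta = delta,
                            seed = seed + k, method = method)
    data.frame(replicate = k, final_fraction = ep$final_fraction,
               major = is_major_outbreak(ep$final_fraction, z, pop$N))
  })
  runs <- do.call(rbind, runs)
  list(
    runs = runs, z = z,
    n_minor_excluded = sum(!runs$major),
    mean_major_fraction = mean(runs$final_fraction[runs$major])
  )
}

#' Serialise herd immunity results
#'
#' Writes one or more herd immunity results as CSV rows (distribution id,
#' rates, level kind, level, diagnostics) with a JSON sidecar carrying the
#' same records plus the package version and solver tolerances.
#'
#' @param results a \code{herd_immunity_result} or list of them.
#' @param path CSV output path; the JSON sidecar replaces the extension
#'   with \code{.json}.
#' @param dist_id label for the household size distribution.
#' @param lambda_G,lambda_L the rates the results were computed at.
#' @return Invisibly, the data frame written.
#' @export
write_herd_immunity_report <- function(results, path, dist_id = "dist",
                                       lambda_G = NA_real_,
                                       lambda_L = NA_real_) {
  if (inherits(results, "herd_immunity_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    data.frame(
      dist_id = dist_id, lambda_G = lambda_G, lambda_L = lambda_L,
      kind = r$kind, level = r$level,
      kappa_hat = if (!is.null(r$kappa_hat)) r$kappa_hat else NA_real_,
      pi = if (!is.null(r$pi)) r$pi else NA_real_,
      z = if (!is.null(r$z)) r$z else NA_real_,
      T_star = if (!is.null(r$T_star)) r$T_star else NA_real_,
      residual_R = if (!is.null(r$residual_R)) r$residual_R else NA_real_
    )
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(
    list(package = "hhimmunity",
         version = as.character(utils::packageVersion("hhimmunity")),
         records = df),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(df)
}
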