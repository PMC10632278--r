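# Fenwick (binary indexed) tree for O(log m) weighted sampling over
# households. Stored as a plain numeric vector of partial sums.
fen_new <- function(w) {
  m <- length(w)
  tree <- numeric(m)
  for (i in seq_len(m)) {
    tree[i] <- tree[i] + w[i]
    j <- i + bitwAnd(i, -i)
    if (j <= m) tree[j] <- tree[j] + tree[i]
  }
  tree
}

fen_add <- function(tree, i, delta) {
  m <- length(tree)
  while (i <= m) {
    tree[i] <- tree[i] + delta
    i <- i + bitwAnd(i, -i)
  }
  tree
}

fen_total <- function(tree) {
  m <- length(tree)
  tot <- 0
  i <- m
  while (i > 0) {
    tot <- tot + tree[i]
    i <- i - bitwAnd(i, -i)
  }
  tot
}

# smallest index with cumulative weight >= u
fen_find <- function(tree, u) {
  m <- length(tree)
  pos <- 0L
  pw <- 2^floor(log2(m))
  while (pw >= 1) {
    np <- pos + pw
    if (np <= m && tree[np] < u) {
      u <- u - tree[np]
      pos <- np
    }
    pw <- pw / 2
  }
  as.integer(pos) + 1L
}

#' Build a household-structured population
#'
#' @param dist a \code{hh_dist}.
#' @param m number of households.
#' @param mode \code{"exact"} rounds \code{m * alpha_n} with
#'   largest-remainder correction so the empirical size frequencies match
#'   the distribution as closely as possible; \code{"sampled"} draws sizes
#'   independently.
#' @param seed integer seed (used by \code{"sampled"} mode).
#' @return Object of class \code{hh_population}: list with \code{sizes}
#'   (household size vector), \code{m} and total population size \code{N}.
#' @export
build_population <- function(dist, m, mode = c("exact", "sampled"),
                             seed = 1L) {
  mode <- match.arg(mode)
  dist <- as_hh_dist(dist)
  stopifnot(m >= 1, m == round(m))
  if (mode == "exact") {
    raw <- m * dist$probs
    counts <- floor(raw)
    rem <- m - sum(counts)
    if (rem > 0) {
      frac_order <- order(raw - counts, decreasing = TRUE)
      counts[frac_order[seq_len(rem)]] <- counts[frac_order[seq_len(rem)]] + 1
    }
    sizes <- rep(seq_len(dist$n_max), counts)
  } else {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sizes <- sample(seq_len(dist$n_max), m, replace = TRUE,
                    prob = dist$probs)
  }
  structure(list(sizes = as.integer(sizes), m = length(sizes),
                 N = sum(sizes)),
            class = "hh_population")
}

#' @export
print.hh_population <- function(x, ...) {
  cat(sprintf("Household population: %d households, %d individuals\n",
              x$m, x$N))
  print(table(x$sizes))
  invisible(x)
}

#' Simulate a household SEIR epidemic
#'
#' Event-driven stochastic simulation of the household epidemic: global
#' contacts at rate \eqn{\lambda_G / N} per infective-susceptible pair and
#' local contacts at rate \eqn{\lambda_L} per within-household pair. Two
#' engines are provided and chosen automatically from the infectious period
#' law: a Gillespie algorithm for Markov laws (exponential \eqn{T_I},
#' optional exponential latency), which also records the event-time
#' trajectory and the empirical residual threshold parameter
#' \eqn{R_V^{(m)}(t)}; and a Sellke-threshold construction for fixed or
#' Erlang laws (final outcome only — the final-size distribution is
#' invariant to the latent period).
#'
#' @param pop a \code{hh_population}.
#' @param lambda_G,lambda_L contact rates (\code{lambda_L = Inf} makes a
#'   contacted household fully infected).
#' @param T_I infectious period law.
#' @param delta latency rate (\code{NULL} for no latent period; Gillespie
#'   only).
#' @param seed integer seed.
#' @param method \code{"auto"}, \code{"gillespie"} or \code{"sellke"}.
#' @param trajectory if \code{TRUE} (Gillespie only) record
#'   \code{(t, S, E, I, R_V)} at every event.
#' @param initial_infectives number of initial infectives (individuals
#'   chosen uniformly at random, i.e. households size-biased).
#' @return Object of class \code{hh_epidemic}: list with per-household
#'   \code{sizes} and infected counts \code{v}, \code{final_fraction},
#'   \code{T_star} and \code{H_D} (Gillespie; \code{NA} if \eqn{R_V}
#'   never crossed one), and optionally \code{trajectory}.
#' @export
simulate_epidemic <- function(pop, lambda_G, lambda_L, T_I,
                              delta = NULL, seed = 1L,
                              method = c("auto", "gillespie", "sellke"),
                              trajectory = FALSE,
                              initial_infectives = 1L) {
  method <- match.arg(method)
  T_I <- as_ti_law(T_I)
  stopifnot(inherits(pop, "hh_population"), lambda_G >= 0, lambda_L >= 0)
  if (method == "auto") {
    method <- if (T_I$kind == "exponential") "gillespie" else "sellke"
  }
  if (method == "gillespie" && T_I$kind != "exponential") {
    stop("the Gillespie engine requires an exponential infectious period")
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (method == "gillespie") {
    sim_gillespie(pop, lambda_G, lambda_L, T_I$rate, delta, trajectory,
                  initial_infectives, T_I)
  } else {
    sim_sellke(pop, lambda_G, lambda_L, T_I, initial_infectives)
  }
}

#' @export
print.hh_epidemic <- function(x, ...) {
  cat(sprintf(
    "Household epidemic realisation (%s): final fraction %.4g (%d of %d infected)\n",
    x$method, x$final_fraction, sum(x$v), sum(x$sizes)))
  if (!is.null(x$H_D) && !is.na(x$H_D)) {
    cat(sprintf("  empirical R_V crossed 1 at t = %.4g; H_D = %.4g\n",
                x$T_star, x$H_D))
  }
  invisible(x)
}

# Gillespie engine on household counts (individuals within a household are
# exchangeable, so (s, e, i) per household is a sufficient state).
sim_gillespie <- function(pop, lambda_G, lambda_L, gamma, delta,
                          trajectory, initial_infectives, T_I) {
  m <- pop$m
  N <- pop$N
  sizes <- pop$sizes
  seir <- !is.null(delta)
  loc_inf <- is.infinite(lambda_L)

  s <- sizes
  e <- integer(m)
  i <- integer(m)

  # empirical residual threshold parameter bookkeeping:
  # R_V^(m) = lambda_G E[T_I] * sum_h s_h mu_{s_h}(lambda_L) / N
  mu_by_s <- single_household_mean_size(0:max(sizes), lambda_L, T_I)
  smu <- (0:max(sizes)) * mu_by_s          # smu[s+1] = s * mu_s
  M <- sum(smu[s + 1])
  rv_const <- lambda_G * T_I$mean / N

  # seed: individuals uniformly at random -> households size-biased
  seed_h <- fen_find_many(fen_new(as.numeric(sizes)),
                          stats::runif(initial_infectives) * N)
  infect <- function(h) {
    # one susceptible in household h becomes exposed (or infective)
    if (s[h] == 0L) return(invisible())
    M <<- M - smu[s[h] + 1]
    s[h] <<- s[h] - 1L
    M <<- M + smu[s[h] + 1]
    if (seir) e[h] <<- e[h] + 1L else i[h] <<- i[h] + 1L
    if (loc_inf) {
      # highly locally infectious: the whole household is infected at once
      k <- s[h]
      if (k > 0) {
        M <<- M - smu[s[h] + 1]
        s[h] <<- 0L
        if (seir) e[h] <<- e[h] + k else i[h] <<- i[h] + k
      }
    }
  }
  for (h in seed_h) infect(h)

  # Fenwick trees over households: susceptibles (global targets),
  # s*i (local infection), i (recovery), e (latency)
  tg <- fen_new(as.numeric(s))
  tl <- if (!loc_inf) fen_new(as.numeric(s) * i) else NULL
  tr <- fen_new(as.numeric(i))
  te <- if (seir) fen_new(as.numeric(e)) else NULL

  sync <- function(h, s0, e0, i0) {
    tg <<- fen_add(tg, h, s[h] - s0)
    if (!loc_inf) tl <<- fen_add(tl, h, s[h] * i[h] - s0 * i0)
    tr <<- fen_add(tr, h, i[h] - i0)
    if (seir) te <<- fen_add(te, h, e[h] - e0)
  }

  t <- 0
  S_tot <- sum(s); E_tot <- sum(e); I_tot <- sum(i)
  T_star <- NA_real_
  H_D <- NA_real_
  traj <- if (trajectory) {
    list(t = numeric(0), S = numeric(0), E = numeric(0), I = numeric(0),
         R_V = numeric(0))
  } else NULL
  record <- function() {
    if (trajectory) {
      traj$t <<- c(traj$t, t); traj$S <<- c(traj$S, S_tot)
      traj$E <<- c(traj$E, E_tot); traj$I <<- c(traj$I, I_tot)
      traj$R_V <<- c(traj$R_V, rv_const * M)
    }
    if (is.na(T_star) && rv_const * M <= 1) {
      T_star <<- t
      H_D <<- 1 - S_tot / N
    }
  }
  record()

  while (E_tot + I_tot > 0) {
    r_gl <- lambda_G / N * I_tot * S_tot
    r_lo <- if (loc_inf) 0 else lambda_L * fen_total(tl)
    r_re <- gamma * I_tot
    r_la <- if (seir) delta * E_tot else 0
    tot <- r_gl + r_lo + r_re + r_la
    t <- t + stats::rexp(1, tot)
    u <- stats::runif(1) * tot
    if (u < r_gl) {
      h <- fen_find(tg, stats::runif(1) * S_tot)
      s0 <- s[h]; e0 <- e[h]; i0 <- i[h]
      infect(h)
      sync(h, s0, e0, i0)
    } else if (u < r_gl + r_lo) {
      h <- fen_find(tl, stats::runif(1) * (r_lo / lambda_L))
      s0 <- s[h]; e0 <- e[h]; i0 <- i[h]
      infect(h)
      sync(h, s0, e0, i0)
    } else if (u < r_gl + r_lo + r_re) {
      h <- fen_find(tr, stats::runif(1) * I_tot)
      i[h] <- i[h] - 1L
      tr <- fen_add(tr, h, -1)
      if (!loc_inf) tl <- fen_add(tl, h, -s[h])
    } else {
      h <- fen_find(te, stats::runif(1) * E_tot)
      e[h] <- e[h] - 1L
      i[h] <- i[h] + 1L
      te <- fen_add(te, h, -1)
      tr <- fen_add(tr, h, 1)
      if (!loc_inf) tl <- fen_add(tl, h, s[h])
    }
    S_tot <- sum_update(S_tot, s)
    E_tot <- sum(e); I_tot <- sum(i)
    record()
  }

  structure(
    list(sizes = sizes, v = sizes - s,
         final_fraction = 1 - sum(s) / N,
         T_star = T_star, H_D = H_D,
         trajectory = if (trajectory) as.data.frame(traj) else NULL,
         method = "gillespie"),
    class = "hh_epidemic")
}

# recompute S_tot cheaply (s is small integer vector; sum is O(m) but in C)
sum_update <- function(S_tot, s) sum(s)

fen_find_many <- function(tree, us) {
  vapply(us, function(u) fen_find(tree, u), integer(1))
}

# Sellke engine: thresholds Exp(1); iterate the infection pressure map to
# its fixed point. Valid for any infectious period law (final size only).
sim_sellke <- function(pop, lambda_G, lambda_L, T_I, initial_infectives) {
  N <- pop$N
  sizes <- pop$sizes
  hid <- rep(seq_len(pop$m), sizes)
  T_dur <- draw_ti(T_I, N)
  Q <- stats::rexp(N)
  init <- sample.int(N, initial_infectives)
  infected <- logical(N)
  infected[init] <- TRUE
  loc_inf <- is.infinite(lambda_L)
  repeat {
    G <- sum(T_dur[infected])
    L_h <- rowsum_by(T_dur * infected, hid, pop$m)
    local_press <- if (loc_inf) {
      ifelse(L_h[hid] - T_dur * infected > 0, Inf, 0)
    } else {
      lambda_L * (L_h[hid] - T_dur * infected)
    }
    expo <- lambda_G / N * G + local_press
    new_inf <- infected | (Q < expo)
    new_inf[init] <- TRUE
    if (all(new_inf == infected)) break
    infected <- new_inf
  }
  v <- rowsum_by(as.numeric(infected), hid, pop$m)
  structure(
    list(sizes = sizes, v = as.integer(v),
         final_fraction = sum(infected) / N,
         T_star = NA_real_, H_D = NA_real_, trajectory = NULL,
         method = "sellke"),
    class = "hh_epidemic")
}

rowsum_by <- function(x, g, m) {
  out <- numeric(m)
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

draw_ti <- function(T_I, n) {
  switch(T_I$kind,
         exponential = stats::rexp(n, T_I$rate),
         fixed = rep(T_I$duration, n),
         erlang = stats::rgamma(n, shape = T_I$shape, rate = T_I$rate),
         stop("unsupported infectious period law"))
}

#' Empirical household outcome distribution
#'
#' The empirical proportions \eqn{(P_{n,v})_{v=0}^n} of size-\code{n}
#' households with \eqn{v} members ultimately infected, pooled over the
#' supplied epidemics (intended for realisations classified as major
#' outbreaks).
#'
#' @param epidemics a \code{hh_epidemic} or list of them.
#' @param n household size.
#' @export
empirical_household_outcomes <- function(epidemics, n) {
  if (inherits(epidemics, "hh_epidemic")) epidemics <- list(epidemics)
  counts <- numeric(n + 1)
  for (ep in epidemics) {
    v <- ep$v[ep$sizes == n]
    counts <- counts + tabulate(v + 1L, nbins = n + 1L)
  }
  if (sum(counts) == 0) stop(sprintf("no households of size %d observed", n))
  counts / sum(counts)
}

#' Classify realisations as major outbreaks
#'
#' A realisation is a major outbreak when its final fraction exceeds
#' \code{max(0.1 * z_analytic, 20 / N)} — a cutoff that separates the two
#' modes of the bimodal final-size distribution.
#'
#' @param final_fractions numeric vector of final fractions.
#' @param z_analytic the deterministic final size from [final_size()].
#' @param N population size.
#' @export
is_major_outbreak <- function(final_fractions, z_analytic, N) {
  final_fractions > pmax(0.1 * z_analytic, 20 / N)
}

#' Empirical disease-induced herd immunity level from one realisation
#'
#' Runs a Gillespie realisation, tracks the empirical residual threshold
#' parameter \eqn{R_V^{(m)}(t)} along the household census, and returns
#' \eqn{1 - S^{(m)}(T_*^{(m)})} at its first crossing of one. Minor
#' outbreaks (final fraction below the classification cutoff, or no
#' crossing) are flagged via \code{NA}.
#'
#' @inheritParams simulate_epidemic
#' @param z_analytic deterministic final size used by the major-outbreak
#'   cutoff.
#' @return List with \code{H_D} (or \code{NA}), \code{T_star},
#'   \code{final_fraction} and \code{major}.
#' @export
empirical_h_D <- function(pop, lambda_G, lambda_L, T_I, delta = NULL,
                          seed = 1L, z_analytic = NULL) {
  ep <- simulate_epidemic(pop, lambda_G, lambda_L, T_I, delta = delta,
                          seed = seed, method = "gillespie")
  if (is.null(z_analytic)) {
    cnt <- tabulate(ep$sizes)
    dist <- hh_dist(cnt / sum(cnt))
    z_analytic <- final_size(dist, lambda_G, lambda_L, T_I)$z
  }
  major <- is_major_outbreak(ep$final_fraction, z_analytic, pop$N)
  list(
    H_D = if (major && !is.na(ep$H_D)) ep$H_D else NA_real_,
    T_star = ep$T_star,
    final_fraction = ep$final_fraction,
    major = major
  )
}
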