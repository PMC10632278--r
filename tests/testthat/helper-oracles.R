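# Independent oracles used to validate the package's final-outcome algebra.
# These deliberately share no code with the implementation.

# Exact final-size distribution of a Markov SIR single-household epidemic
# (exponential infectious period, rate gamma) by recursive enumeration of
# the embedded jump chain. Returns P(total ever infected = v) for
# v = 0..n, starting from a initial infectives among n members.
oracle_household_final_dist <- function(n, a, lambda_L, gamma = 1) {
  memo <- new.env()
  # P(final number of susceptibles = k) from state (s infectives-free
  # susceptibles, i infectives)
  rec <- function(s, i) {
    if (i == 0) {
      out <- numeric(s + 1)
      out[s + 1] <- 1          # k = s
      return(out)
    }
    key <- paste(s, i)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (s == 0) {
      out <- c(1)              # k = 0
      memo[[key]] <- out
      return(out)
    }
    p_inf <- lambda_L * s / (lambda_L * s + gamma)
    out <- numeric(s + 1)
    sub <- rec(s - 1, i + 1)   # infection
    out[seq_along(sub)] <- out[seq_along(sub)] + p_inf * sub
    sub <- rec(s, i - 1)       # recovery
    out[seq_along(sub)] <- out[seq_along(sub)] + (1 - p_inf) * sub
    memo[[key]] <- out
    out
  }
  ps <- rec(n - a, a)          # over final susceptibles k = 0..n-a
  out <- numeric(n + 1)
  for (k in 0:(n - a)) out[n - k + 1] <- ps[k + 1]   # v = n - k
  out
}

# Exact mean single-household final size with one initial infective.
oracle_mu_n <- function(n, lambda_L, gamma = 1) {
  p <- oracle_household_final_dist(n, 1, lambda_L, gamma)
  sum((0:n) * p)
}

# Exact outcome distribution with Bin(n, 1 - pi) initial (globally
# infected) members.
oracle_outcome_dist <- function(n, lambda_L, pi, gamma = 1) {
  out <- numeric(n + 1)
  for (a in 0:n) {
    w <- stats::dbinom(a, n, 1 - pi)
    if (a == 0) {
      out[1] <- out[1] + w
    } else {
      out <- out + w * oracle_household_final_dist(n, a, lambda_L, gamma)
    }
  }
  out
}

# Monte-Carlo single-household mean final size via the threshold
# construction, valid for any infectious period law. Vectorised over
# replicates; returns mean and its standard error.
oracle_mc_mean_final <- function(n, lambda_L, T_I, reps = 1e4,
                                 seed = 1) {
  set.seed(seed)
  if (n == 1) return(list(mean = 1, se = 0))
  draw <- function(k) {
    switch(T_I$kind,
           exponential = stats::rexp(k, T_I$rate),
           fixed = rep(T_I$duration, k),
           erlang = stats::rgamma(k, shape = T_I$shape, rate = T_I$rate))
  }
  Tm <- matrix(draw(reps * n), reps, n)     # periods in order of infection
  Q <- matrix(stats::rexp(reps * (n - 1)), reps, n - 1)
  Q <- t(apply(Q, 1, sort))
  if (n == 2) Q <- matrix(Q, reps, 1)
  csum <- Tm                                # csum[, k] = T_1 + ... + T_k
  for (k in 2:n) csum[, k] <- csum[, k - 1] + Tm[, k]
  size <- rep(1, reps)
  active <- rep(TRUE, reps)
  for (k in 1:(n - 1)) {
    active <- active & (Q[, k] < lambda_L * csum[, k])
    size <- size + active
  }
  list(mean = mean(size), se = stats::sd(size) / sqrt(reps))
}

# Brute-force rank-generation means by enumerating every realisation of
# the within-household directed random graph (feasible for n <= 3).
# P(out-set of a node is a specific set of size a, missing b = n-1-a
# others) = sum_j C(a,j) (-1)^j phi((j+b) lambda_L).
oracle_rank_generations <- function(n, lambda_L, T_I) {
  phi <- function(th) T_I$phi(th)
  wset <- function(a) {
    b <- n - 1 - a
    j <- 0:a
    sum(choose(a, j) * (-1)^j * phi((j + b) * lambda_L))
  }
  others <- lapply(1:n, function(v) setdiff(1:n, v))
  subsets <- function(x) {
    out <- list(integer(0))
    for (e in x) out <- c(out, lapply(out, function(s) c(s, e)))
    out
  }
  per_node <- lapply(others, subsets)
  means <- numeric(n)
  idx <- rep(1L, n)
  counts <- vapply(per_node, length, integer(1))
  repeat {
    prob <- 1
    adj <- vector("list", n)
    for (v in 1:n) {
      A <- per_node[[v]][[idx[v]]]
      adj[[v]] <- A
      prob <- prob * wset(length(A))
    }
    # BFS from node 1
    depth <- rep(NA_integer_, n)
    depth[1] <- 0L
    frontier <- 1L
    d <- 0L
    while (length(frontier) > 0) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(depth[nxt])]
      d <- d + 1L
      depth[nxt] <- d
      frontier <- nxt
    }
    for (g in 0:(n - 1)) {
      means[g + 1] <- means[g + 1] + prob * sum(depth == g, na.rm = TRUE)
    }
    # advance the odometer
    v <- 1L
    while (v <= n) {
      idx[v] <- idx[v] + 1L
      if (idx[v] <= counts[v]) break
      idx[v] <- 1L
      v <- v + 1L
    }
    if (v > n) break
  }
  means
}

# Bisection oracle for the homogeneous final-size equation
# z = 1 - exp(-R0 z).
oracle_homogeneous_z <- function(R0, tol = 1e-12) {
  f <- function(z) z - 1 + exp(-R0 * z)
  lo <- 1e-9; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Monte-Carlo outcome distribution of a single household exposed to
# global escape probability pi (Bin(n, 1 - pi) initial infectives),
# via the threshold construction; any infectious period law.
oracle_mc_outcome <- function(n, lambda_L, T_I, pi, reps = 1e4,
                              seed = 1) {
  set.seed(seed)
  draw <- function(k) {
    switch(T_I$kind,
           exponential = stats::rexp(k, T_I$rate),
           fixed = rep(T_I$duration, k),
           erlang = stats::rgamma(k, shape = T_I$shape, rate = T_I$rate))
  }
  a_all <- stats::rbinom(reps, n, 1 - pi)
  v <- integer(reps)
  for (a in unique(a_all)) {
    sel <- which(a_all == a)
    k <- length(sel)
    if (a == 0 || a == n) {
      v[sel] <- a
      next
    }
    ns <- n - a                             # susceptibles
    Tm <- matrix(draw(k * n), k, n)         # periods in infection order
    Q <- matrix(stats::rexp(k * ns), k, ns)
    Q <- matrix(t(apply(Q, 1, sort)), k, ns)
    csum <- matrix(Tm[, 1], k, 1)
    for (j in 2:n) csum <- cbind(csum, csum[, j - 1] + Tm[, j])
    size <- rep(a, k)
    active <- rep(TRUE, k)
    for (j in 1:ns) {
      active <- active & (Q[, j] < lambda_L * csum[, a + j - 1])
      size <- size + active
    }
    v[sel] <- size
  }
  counts <- tabulate(v + 1L, nbins = n + 1L)
  list(probs = counts / reps,
       se = sqrt(pmax(counts / reps * (1 - counts / reps), 1e-12) / reps))
}

# Monte-Carlo rank-generation means by sampling the within-household
# directed random graph and taking BFS layers from node 1.
oracle_mc_rank_generations <- function(n, lambda_L, T_I, reps = 1e4,
                                       seed = 1) {
  set.seed(seed)
  draw <- function(k) {
    switch(T_I$kind,
           exponential = stats::rexp(k, T_I$rate),
           fixed = rep(T_I$duration, k),
           erlang = stats::rgamma(k, shape = T_I$shape, rate = T_I$rate))
  }
  # adj[[v]]: reps x n logical, edge v -> u
  adj <- vector("list", n)
  for (v in 1:n) {
    Tv <- draw(reps)
    p_edge <- 1 - exp(-lambda_L * Tv)
    E <- matrix(stats::runif(reps * n) < p_edge, reps, n)
    E[, v] <- FALSE
    adj[[v]] <- E
  }
  reached <- matrix(FALSE, reps, n)
  reached[, 1] <- TRUE
  frontier <- reached
  gen_sizes <- matrix(0, reps, n)           # column g: size of gen g-1
  gen_sizes[, 1] <- 1
  for (g in 2:n) {
    nxt <- matrix(FALSE, reps, n)
    for (v in 1:n) {
      nxt <- nxt | (frontier[, v] & adj[[v]])
    }
    nxt <- nxt & !reached
    reached <- reached | nxt
    frontier <- nxt
    gen_sizes[, g] <- rowSums(nxt)
  }
  list(means = colMeans(gen_sizes),
       se = apply(gen_sizes, 2, stats::sd) / sqrt(reps))
}
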