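# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive implementations kept separate from the package code
# paths they check.

# closed-form normalised-LMS update (APA with P = 1)
oracle_nlms <- function(w, u, d, mu, eps = 0) {
  e <- d - sum(u * w)
  w + mu * u * e / (sum(u * u) + eps)
}

# APA update for P = 2 via the explicit 2x2 inverse
oracle_apa_p2 <- function(w, U, dvec, mu, eps = 0) {
  e <- dvec - drop(t(U) %*% w)
  G <- t(U) %*% U + diag(eps, 2)
  det <- G[1, 1] * G[2, 2] - G[1, 2] * G[2, 1]
  Ginv <- matrix(c(G[2, 2], -G[2, 1], -G[1, 2], G[1, 1]), 2, 2) / det
  w + mu * drop(U %*% (Ginv %*% e))
}

# maximum bipartite matching size by augmenting paths (Kuhn's algorithm);
# adjacency: detected j can match true i iff |dt[j] - tr[i]| <= half
oracle_max_matching <- function(tr, dt, half) {
  nt <- length(tr); nd <- length(dt)
  if (!nt || !nd) return(0L)
  match_of_true <- rep(0L, nt)
  try_kuhn <- function(j, seen) {
    for (i in seq_len(nt)) {
      if (!seen[i] && abs(dt[j] - tr[i]) <= half) {
        seen[i] <- TRUE
        if (match_of_true[i] == 0L) {
          match_of_true[i] <<- j
          return(list(ok = TRUE, seen = seen))
        }
        res <- try_kuhn(match_of_true[i], seen)
        seen <- res$seen
        if (res$ok) {
          match_of_true[i] <<- j
          return(list(ok = TRUE, seen = seen))
        }
      }
    }
    list(ok = FALSE, seen = seen)
  }
  size <- 0L
  for (j in seq_len(nd)) {
    if (try_kuhn(j, rep(FALSE, nt))$ok) size <- size + 1L
  }
  size
}

# offline least-squares weight estimate for the system-identification setup
oracle_offline_ls <- function(rl, rr, d, L) {
  n <- length(d)
  X <- t(vapply(seq_len(n), function(i) reference_vector(rl, rr, i, L),
                numeric(2 * L)))
  qr.solve(X, d)
}

# system-identification fixture: white references, d = w* . n' + noise
sysid_fixture <- function(n = 5000, L = 4, sigma = 0.01, seed = 123,
                          impulse_rate = 0, impulse_scale = 50) {
  set.seed(seed)
  rl <- rnorm(n); rr <- rnorm(n)
  w_star <- rnorm(2 * L)
  w_star <- w_star / sqrt(sum(w_star^2))
  d <- vapply(seq_len(n), function(i)
    sum(w_star * reference_vector(rl, rr, i, L)), 0) + rnorm(n, sd = sigma)
  if (impulse_rate > 0) {
    hit <- which(runif(n) < impulse_rate)
    d[hit] <- d[hit] + sample(c(-1, 1), length(hit), replace = TRUE) *
      impulse_scale * sd(d)
  }
  list(rl = rl, rr = rr, d = d, w_star = w_star)
}

# run a step function over the fixture, tracking weight-error trajectory
sysid_run <- function(fix, cfg, n_iter = length(fix$d)) {
  st <- init_state(cfg)
  L <- cfg$L; P <- cfg$P
  U <- matrix(0, 2 * L, P)
  dv <- numeric(P)
  err <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    if (P > 1) {
      U[, 2:P] <- U[, 1:(P - 1)]
      dv[2:P] <- dv[1:(P - 1)]
    }
    U[, 1] <- reference_vector(fix$rl, fix$rr, i, L)
    dv[1] <- fix$d[i]
    st <- switch(cfg$algorithm,
      apa = apa_step(st, U, dv, cfg$mu, cfg$eps_reg)$state,
      proposed = proposed_step(st, U, dv, cfg)$state,
      rvss = rvss_step(st, U, dv, cfg)$state)
    err[i] <- sqrt(sum((st$w - fix$w_star)^2))
  }
  list(state = st, err = err)
}
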