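#' Adaptive-filter configuration
#'
#' Parameters of the four supported weight-update rules.  The filter has
#' `2 * L` weights (L taps per reference channel) and uses the last `P`
#' reference vectors (the projection order).
#'
#' Algorithms:
#' * `"apa"` — affine projection algorithm with fixed step `mu`.
#' * `"apsa"` — affine projection sign algorithm with fixed step `mu`
#'   (the update always has Euclidean norm `mu`).
#' * `"rvss"` — robust variable-step-size switch: APA (unit step) when its
#'   update norm is below the adaptive threshold `delta`, otherwise APSA
#'   with step `delta`; `delta` tracks `min(|e|/||n'||, delta)` with memory
#'   `alpha`.
#' * `"proposed"` — QRS-preserving switch: APA with step `mu1` while the
#'   APA update norm is below `beta * delta`, otherwise APSA with the small
#'   step `gamma * delta`; `delta` tracks the APA update norm on APA
#'   iterations and is frozen on sign iterations.  The large update that a
#'   QRS complex provokes is thus treated like impulsive noise: the filter
#'   barely moves, so the QRS power in the error output is conserved.
#'
#' Defaults `mu1 = 0.4`, `gamma = 0.01`, `beta = 3.5` and `mu = 0.05` are
#' the reference operating point for ECG denoising at 200 Hz; `alpha`
#' (memory factor, close to one) and `delta0` are start-up choices.
#'
#' @param algorithm one of `"proposed"`, `"apa"`, `"apsa"`, `"rvss"`.
#' @param L taps per reference channel (weight length `2 * L`).
#' @param P projection order.
#' @param mu step size for plain APA / APSA.
#' @param mu1 APA step of the proposed switch.
#' @param gamma sign-step scale of the proposed switch, in (0, 1).
#' @param beta threshold scale of the proposed switch.
#' @param alpha memory factor in `[0, 1]`.
#' @param delta0 initial adaptive threshold, > 0.
#' @param eps_reg ridge added to \eqn{U^T U} before inversion (start-up
#'   regularisation), >= 0.
#' @return object of class `"filter_config"`.
#' @export
filter_config <- function(algorithm = c("proposed", "apa", "apsa", "rvss"),
                          L = 16L, P = 4L, mu = 0.05, mu1 = 0.4,
                          gamma = 0.01, beta = 3.5, alpha = 0.995,
                          delta0 = 0.01, eps_reg = 1e-6) {
  algorithm <- match.arg(algorithm)
  if (L < 1L || P < 1L) .fail("need L >= 1 and P >= 1")
  .check_scalar_num(mu, "mu", 0, 1, strict_lower = TRUE)
  .check_scalar_num(mu1, "mu1", 0, 1, strict_lower = TRUE)
  .check_scalar_num(gamma, "gamma", 0, 1, strict_lower = TRUE,
                    strict_upper = TRUE)
  .check_scalar_num(beta, "beta", 0, strict_lower = TRUE)
  .check_scalar_num(alpha, "alpha", 0, 1)
  .check_scalar_num(delta0, "delta0", 0, strict_lower = TRUE)
  .check_scalar_num(eps_reg, "eps_reg", 0)
  structure(list(algorithm = algorithm, L = as.integer(L), P = as.integer(P),
                 mu = mu, mu1 = mu1, gamma = gamma, beta = beta,
                 alpha = alpha, delta0 = delta0, eps_reg = eps_reg),
            class = "filter_config")
}

#' Initialise adaptive-filter state
#'
#' Zero weights, `delta = delta0`, iteration counter 0.
#'
#' @param cfg a [filter_config()].
#' @return object of class `"filter_state"` with elements `w`, `delta`,
#'   `iteration`.
#' @export
init_state <- function(cfg) {
  stopifnot(inherits(cfg, "filter_config"))
  structure(list(w = numeric(2L * cfg$L), delta = cfg$delta0,
                 iteration = 0L),
            class = "filter_state")
}

.trace <- function(branch, q, state, e1, step_norm) {
  list(branch = branch, apa_update_norm = q, delta_after = state$delta,
       e = e1, step_norm = step_norm)
}

.apa_solve <- function(U, e, eps_reg) {
  G <- crossprod(U)
  if (eps_reg > 0) G <- G + diag(eps_reg, nrow(G))
  x <- tryCatch(solve(G, e), error = function(err) NULL)
  if (is.null(x))
    .fail(paste0("U'U is singular; set eps_reg > 0 to regularise ",
                 "the affine-projection inversion"))
  drop(U %*% x)
}

#' One affine-projection (APA) update
#'
#' Computes the a-priori error vector `e = d_vec - t(U) %*% w` and moves the
#' weights by `mu * U %*% solve(t(U) %*% U + eps_reg * I, e)`.
#'
#' @param state a [init_state()] filter state.
#' @param U `2L x P` matrix of the last `P` reference vectors, newest in
#'   column 1.
#' @param d_vec length-`P` vector of the last desired samples, newest first.
#' @param mu step size.
#' @param eps_reg ridge regulariser (default from standard practice, 1e-6).
#' @return list with updated `state` and a `trace` (branch, APA update norm
#'   `q`, `delta_after`, first-tap error `e`).
#' @export
apa_step <- function(state, U, d_vec, mu, eps_reg = 1e-6) {
  stopifnot(inherits(state, "filter_state"))
  U <- as.matrix(U)
  e <- as.numeric(d_vec) - drop(crossprod(U, state$w))
  upd <- mu * .apa_solve(U, e, eps_reg)
  state$w <- state$w + upd
  state$iteration <- state$iteration + 1L
  q <- sqrt(sum(upd^2))
  list(state = state, trace = .trace("APA", q, state, e[1], q))
}

#' One affine-projection sign (APSA) update
#'
#' Moves the weights by
#' `step * U %*% sign(e) / sqrt(t(sign(e)) %*% t(U) %*% U %*% sign(e))`,
#' i.e. a fixed-Euclidean-norm step of length `step` along `U sign(e)`.
#' When `U %*% sign(e)` is zero (for example a zero error vector, with
#' `sign(0) = 0`) the update is skipped.
#'
#' @param state a [init_state()] filter state.
#' @param U `2L x P` reference matrix, newest column first.
#' @param e_vec length-`P` error vector.
#' @param step step size (> 0); equals the norm of the applied update.
#' @return list with updated `state` and `trace` (branch `"APSA"` or
#'   `"SKIPPED"`).
#' @export
apsa_step <- function(state, U, e_vec, step) {
  stopifnot(inherits(state, "filter_state"), step > 0)
  U <- as.matrix(U)
  s <- sign(as.numeric(e_vec))
  Us <- drop(U %*% s)
  nn <- sqrt(sum(Us^2))
  state$iteration <- state$iteration + 1L
  if (nn == 0)
    return(list(state = state,
                trace = .trace("SKIPPED", 0, state, e_vec[1], 0)))
  state$w <- state$w + step * Us / nn
  list(state = state, trace = .trace("APSA", 0, state, e_vec[1], step))
}

#' One robust variable-step-size (RVSS) update
#'
#' Computes the unit-step APA candidate; applies it if its norm is below
#' the current threshold `delta`, otherwise takes an APSA step of length
#' `delta`.  The threshold then relaxes towards
#' `min(|e| / ||n'||, delta)` with memory `alpha`, where `n'` is the newest
#' reference vector (column 1 of `U`).
#'
#' @inheritParams apa_step
#' @param cfg a [filter_config()] (uses `alpha`, `eps_reg`).
#' @return list with updated `state` and `trace`.
#' @export
rvss_step <- function(state, U, d_vec, cfg) {
  stopifnot(inherits(state, "filter_state"), inherits(cfg, "filter_config"))
  U <- as.matrix(U)
  e <- as.numeric(d_vec) - drop(crossprod(U, state$w))
  cand <- .apa_solve(U, e, cfg$eps_reg)
  q <- sqrt(sum(cand^2))
  delta_prev <- state$delta
  if (q < delta_prev) {
    state$w <- state$w + cand
    branch <- "APA"; step_norm <- q
  } else {
    s <- sign(e)
    Us <- drop(U %*% s)
    nn <- sqrt(sum(Us^2))
    if (nn > 0) {
      state$w <- state$w + delta_prev * Us / nn
      branch <- "APSA"; step_norm <- delta_prev
    } else {
      branch <- "SKIPPED"; step_norm <- 0
    }
  }
  rn <- sqrt(sum(U[, 1]^2))
  term <- if (rn > 0) min(abs(e[1]) / rn, delta_prev) else delta_prev
  state$delta <- cfg$alpha * delta_prev + (1 - cfg$alpha) * term
  state$iteration <- state$iteration + 1L
  list(state = state, trace = .trace(branch, q, state, e[1], step_norm))
}

#' One update of the proposed QRS-preserving switched algorithm
#'
#' Computes the APA update with step `mu1` and its norm `q`.  If
#' `q < beta * delta` the APA update is applied and the threshold tracks
#' `q` with memory `alpha`; otherwise (an impulsive event, e.g. a QRS
#' complex) an APSA step of the much smaller length `gamma * delta` is
#' taken and `delta` is left unchanged.
#'
#' @inheritParams apa_step
#' @param cfg a [filter_config()] (uses `mu1`, `gamma`, `beta`, `alpha`,
#'   `eps_reg`).
#' @return list with updated `state` and `trace`.
#' @export
proposed_step <- function(state, U, d_vec, cfg) {
  stopifnot(inherits(state, "filter_state"), inherits(cfg, "filter_config"))
  U <- as.matrix(U)
  e <- as.numeric(d_vec) - drop(crossprod(U, state$w))
  upd <- cfg$mu1 * .apa_solve(U, e, cfg$eps_reg)
  q <- sqrt(sum(upd^2))
  delta_prev <- state$delta
  if (q < cfg$beta * delta_prev) {
    state$w <- state$w + upd
    state$delta <- cfg$alpha * delta_prev + (1 - cfg$alpha) * q
    branch <- "APA"; step_norm <- q
  } else {
    s <- sign(e)
    Us <- drop(U %*% s)
    nn <- sqrt(sum(Us^2))
    step <- cfg$gamma * delta_prev
    if (nn > 0) {
      state$w <- state$w + step * Us / nn
      branch <- "APSA"; step_norm <- step
    } else {
      branch <- "SKIPPED"; step_norm <- 0
    }
    # delta frozen: the impulsive event must not inflate the threshold
  }
  state$iteration <- state$iteration + 1L
  list(state = state, trace = .trace(branch, q, state, e[1], step_norm))
}
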