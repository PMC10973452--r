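#' Kinetic parameters of the transcription-splicing-degradation model
#'
#' Bundles the rates of the two-species mRNA kinetic model
#' \deqn{du/dt = \alpha - \beta u, \qquad ds/dt = \beta u - \gamma s}
#' where `u` is unspliced (nascent) and `s` spliced (mature) mRNA abundance.
#' Transcription is on (`alpha > 0`) during induction and switches off at
#' latent time `t_switch`, after which the trajectory relaxes with
#' `alpha = 0` (repression).
#'
#' Because only the ratio of unspliced to spliced abundance is identifiable
#' from count data, `beta` is conventionally fixed to 1 and `gamma` is
#' interpreted as the ratio gamma/beta.
#'
#' @param alpha transcription rate (molecules per unit latent time, >= 0).
#' @param beta splicing rate (> 0), conventionally 1.
#' @param gamma degradation rate (> 0), i.e. gamma/beta when beta = 1.
#' @param t_switch latent time at which induction switches to repression
#'   (finite, >= 0).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(alpha, beta = 1, gamma, t_switch = Inf) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(gamma))
  if (any(!is.finite(c(alpha, beta, gamma))) || alpha < 0 || beta <= 0 || gamma <= 0)
    stop("invalid kinetic parameters: need alpha >= 0, beta > 0, gamma > 0, all finite")
  if (is.na(t_switch) || t_switch < 0)
    stop("invalid kinetic parameters: t_switch must be >= 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, t_switch = t_switch),
            class = "kinetic_params")
}

# closed-form solution of the linear system for constant alpha, from (u0, s0).
# Handles the gamma == beta degeneracy by the limiting expression
# (e^{-gamma t} - e^{-beta t})/(gamma - beta) -> -t e^{-beta t}.
.kinetics_closed_form <- function(alpha, beta, gamma, t, u0, s0) {
  eb <- exp(-beta * t)
  eg <- exp(-gamma * t)
  u <- u0 * eb + (alpha / beta) * (1 - eb)
  dif <- if (abs(gamma - beta) < 1e-10 * max(gamma, beta)) -t * eb
         else (eg - eb) / (gamma - beta)
  s <- s0 * eg + (alpha / gamma) * (1 - eg) + (alpha - beta * u0) * dif
  list(u = u, s = s)
}

#' Expected unspliced and spliced abundance along the kinetic trajectory
#'
#' Evaluates the closed-form solution of the transcription-splicing-
#' degradation ODE at latent time(s) `t`, starting from `(u0, s0)`.
#' For `t <= t_switch` the induction branch (transcription on) is used;
#' beyond the switch the trajectory continues with `alpha = 0` from the
#' state reached at `t_switch`.
#'
#' @param params a [kinetic_params()] object.
#' @param t latent time(s), >= 0.
#' @param u0,s0 initial abundances at t = 0 (default 0).
#' @return A list with numeric vectors `u` and `s`, same length as `t`.
#' @examples
#' p <- kinetic_params(alpha = 2, gamma = 0.5, t_switch = 4)
#' simulate_kinetics(p, t = c(0.5, 2, 6))
#' @export
simulate_kinetics <- function(params, t, u0 = 0, s0 = 0) {
  if (!inherits(params, "kinetic_params")) stop("params must be a kinetic_params object")
  if (any(!is.finite(t)) || any(t < 0)) stop("invalid parameter: latent time t must be finite and >= 0")
  if (u0 < 0 || s0 < 0) stop("invalid parameter: initial abundances must be >= 0")
  a <- params$alpha; b <- params$beta; g <- params$gamma; ts <- params$t_switch

  u <- s <- numeric(length(t))
  ind <- t <= ts
  if (any(ind)) {
    res <- .kinetics_closed_form(a, b, g, t[ind], u0, s0)
    u[ind] <- res$u; s[ind] <- res$s
  }
  if (any(!ind)) {
    sw <- .kinetics_closed_form(a, b, g, ts, u0, s0)
    res <- .kinetics_closed_form(0, b, g, t[!ind] - ts, sw$u, sw$s)
    u[!ind] <- res$u; s[!ind] <- res$s
  }
  list(u = u, s = s)
}

#' Expected RNA velocity along the kinetic trajectory
#'
#' The velocity is the instantaneous rate of change of spliced abundance,
#' `ds/dt = beta * u - gamma * s`, evaluated on the closed-form trajectory.
#' Positive during (early) induction, negative once the trajectory decays.
#'
#' @inheritParams simulate_kinetics
#' @return Numeric vector of velocities, same length as `t`.
#' @export
kinetic_velocity <- function(params, t, u0 = 0, s0 = 0) {
  tr <- simulate_kinetics(params, t, u0 = u0, s0 = s0)
  params$beta * tr$u - params$gamma * tr$s
}
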