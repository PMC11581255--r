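# Boosted Harris Hawks / shuffled-shepherd hybrid optimizer (BHHSHO).
#
# Canonical Harris Hawks Optimization switches between exploration and four
# "besiege" exploitation strategies via a decaying escape energy. The boosted
# variant implemented here (i) replaces the random-hawk reference in the
# exploration step with the mean of the best, worst and current positions,
# (ii) injects chaos into the escape energy through a logistic-map
# multiplier, and (iii) follows every hard besiege with a shuffled-shepherd
# position update (attraction to the best hawk plus a Levy-flight kick,
# accepted greedily).

#' Logistic map step
#'
#' One iterate of the chaotic logistic recurrence
#' `phi_{k+1} = a * phi_k * (1 - phi_k)`, used to produce the chaotic
#' multiplier of the escape energy.
#'
#' @param phi State in `[0, 1]`.
#' @param a Map parameter in `(0, 4]`; `a = 4` is fully chaotic.
#' @return The next state, guaranteed in `[0, 1]` for valid inputs.
#' @export
logistic_step <- function(phi, a) {
  if (!is.finite(phi) || phi < 0 || phi > 1) {
    stop("`phi` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(a) || a <= 0 || a > 4) {
    stop("`a` must lie in (0, 4]", call. = FALSE)
  }
  a * phi * (1 - phi)
}

#' Chaotic escape energy
#'
#' The prey's escape energy `Eg = 2 * C * Eg0 * (1 - t / t_max)`, where
#' `Eg0` is the initial energy drawn per hawk per iteration and `C` is a
#' chaotic multiplier in `(0, 1)` from the logistic map. `|Eg|` decays to 0
#' as `t` approaches `t_max`, shifting hawks from exploration to
#' exploitation.
#'
#' @param Eg0 Initial energy (typically uniform in `(-1, 1)`).
#' @param C Chaotic multiplier in `(0, 1)`.
#' @param t Current iteration, `0 <= t <= t_max`.
#' @param t_max Maximum iterations (> 0).
#' @return The escape energy.
#' @export
escape_energy <- function(Eg0, C, t, t_max) {
  if (t_max <= 0) stop("`t_max` must be positive", call. = FALSE)
  if (t < 0 || t > t_max) stop("`t` must lie in [0, t_max]", call. = FALSE)
  2 * C * Eg0 * (1 - t / t_max)
}

#' Boosted random-hawk reference
#'
#' The boosted exploration step replaces the uniformly random hawk of
#' canonical HHO with the componentwise mean of the best, worst and current
#' positions, biasing exploration toward informative regions.
#'
#' @param best,worst,current Numeric position vectors of equal length.
#' @return `(best + worst + current) / 3`.
#' @export
boosted_srand <- function(best, worst, current) {
  if (length(best) != length(worst) || length(best) != length(current)) {
    stop("position vectors must have equal dimension", call. = FALSE)
  }
  (best + worst + current) / 3
}

#' Mantegna Levy-flight scale
#'
#' The scale `sigma` of the Mantegna algorithm for Levy-stable steps:
#' `sigma = (gamma(1+g) * sin(pi*g/2) / (gamma((1+g)/2) * g * 2^((g-1)/2)))^(1/g)`.
#' A Levy step in each coordinate is then `l * sigma / |m|^(1/g)` with `l`,
#' `m` standard-normal draws.
#'
#' @param gamma Stability exponent in `(0, 2]`; 1.5 by convention.
#' @return The positive scale `sigma`.
#' @export
levy_sigma <- function(gamma = 1.5) {
  if (!is.finite(gamma) || gamma <= 0 || gamma > 2) {
    stop("`gamma` must lie in (0, 2]", call. = FALSE)
  }
  (gamma(1 + gamma) * sin(pi * gamma / 2) /
     (gamma((1 + gamma) / 2) * gamma * 2^((gamma - 1) / 2)))^(1 / gamma)
}

#' Levy-flight step vector
#'
#' Draws a `d`-dimensional heavy-tailed step by the Mantegna method, scaled
#' by 0.01 as is conventional for Levy-flight moves in swarm optimizers.
#'
#' @param d Dimension.
#' @param gamma Stability exponent in `(0, 2]`.
#' @return Numeric vector of length `d`.
#' @export
levy_step <- function(d, gamma = 1.5) {
  sigma <- levy_sigma(gamma)
  l <- stats::rnorm(d)
  m <- stats::rnorm(d)
  0.01 * l * sigma / abs(m)^(1 / gamma)
}

.clamp <- function(x, lb, ub) pmin(pmax(x, lb), ub)

#' Exploration step
#'
#' With probability ~1/2 a perch relative to the boosted random reference,
#' `S_rand - r1 * |S_rand - 2 * r2 * S|`; otherwise a perch relative to prey
#' and flock mean, `(S_prey - S_m) - r3 * (lb + r4 * (ub - lb))`. All random
#' numbers are fresh uniform draws; the result is clamped to the bounds.
#'
#' @param S Current hawk position.
#' @param S_prey Best position found so far.
#' @param S_m Mean position of the flock.
#' @param S_rand Boosted random reference (see [boosted_srand()]).
#' @param lb,ub Bound vectors.
#' @return New position vector within `[lb, ub]`.
#' @export
explore_step <- function(S, S_prey, S_m, S_rand, lb, ub) {
  q <- stats::runif(1)
  new <- if (q >= 0.5) {
    r1 <- stats::runif(1); r2 <- stats::runif(1)
    S_rand - r1 * abs(S_rand - 2 * r2 * S)
  } else {
    r3 <- stats::runif(1); r4 <- stats::runif(1)
    (S_prey - S_m) - r3 * (lb + r4 * (ub - lb))
  }
  .clamp(new, lb, ub)
}

#' Soft besiege
#'
#' `S_prey - S - Eg * |Jp * S_prey - S|` with jump strength
#' `Jp = 2 * (1 - r5)`, `r5` a fresh uniform draw.
#'
#' @inheritParams explore_step
#' @param Eg Escape energy.
#' @param Jp Optional fixed jump strength (drawn if `NULL`).
#' @return New position vector (unclamped; the driver clamps).
#' @export
soft_besiege <- function(S, S_prey, Eg, Jp = NULL) {
  if (is.null(Jp)) Jp <- 2 * (1 - stats::runif(1))
  (S_prey - S) - Eg * abs(Jp * S_prey - S)
}

#' Hard besiege
#'
#' `S_prey - Eg * |S_prey - S|`: a contraction onto the prey as its energy
#' fades.
#'
#' @inheritParams soft_besiege
#' @return New position vector.
#' @export
hard_besiege <- function(S, S_prey, Eg) {
  S_prey - Eg * abs(S_prey - S)
}

#' Shuffled-shepherd position update
#'
#' The boosting step applied after a hard besiege: a candidate
#' `S_best + r * (S_prey - S) + Levy(gamma)` with `r` uniform elementwise,
#' accepted only if it improves the hawk's objective value (greedy).
#'
#' @inheritParams soft_besiege
#' @param S_best Best position (identical to `S_prey` in the driver; kept
#'   separate for clarity of the update rule).
#' @param fitness Current objective value of the hawk (minimization sense).
#' @param objective Function evaluating a position.
#' @param gamma Levy exponent.
#' @param lb,ub Bounds for clamping.
#' @return List with `position` and `fitness` after greedy acceptance.
#' @export
ssoa_update <- function(S, S_best, S_prey, fitness, objective, gamma,
                        lb, ub) {
  d <- length(S)
  stepsize <- stats::runif(d) * (S_prey - S)
  cand <- .clamp(S_best + stepsize + levy_step(d, gamma), lb, ub)
  f_cand <- objective(cand)
  if (is.finite(f_cand) && f_cand < fitness) {
    list(position = cand, fitness = f_cand)
  } else {
    list(position = S, fitness = fitness)
  }
}

# shared accept/reject structure of the two progressive-dive strategies
.dive_accept <- function(S, fitness, U, objective, gamma, lb, ub) {
  d <- length(S)
  U <- .clamp(U, lb, ub)
  f_U <- objective(U)
  if (is.finite(f_U) && f_U < fitness) {
    return(list(position = U, fitness = f_U))
  }
  V <- .clamp(U + stats::runif(d) * levy_step(d, gamma), lb, ub)
  f_V <- objective(V)
  if (is.finite(f_V) && f_V < fitness) {
    return(list(position = V, fitness = f_V))
  }
  list(position = S, fitness = fitness)
}

#' Soft besiege with progressive quick dives
#'
#' Candidate `U = S_prey - Eg * |Jp * S_prey - S|`; if `U` does not improve
#' the hawk, a Levy-flight dive `V = U + Q x LF(d)` is tried; if neither
#' improves, the hawk keeps its position.
#'
#' @inheritParams ssoa_update
#' @param Eg Escape energy.
#' @return List with `position` and `fitness`.
#' @export
soft_besiege_dives <- function(S, S_prey, Eg, fitness, objective, gamma,
                               lb, ub) {
  Jp <- 2 * (1 - stats::runif(1))
  U <- S_prey - Eg * abs(Jp * S_prey - S)
  .dive_accept(S, fitness, U, objective, gamma, lb, ub)
}

#' Hard besiege with progressive quick dives
#'
#' As [soft_besiege_dives()] but the dive is referenced to the flock mean:
#' `U = S_prey - Eg * |Jp * S_prey - S_m|`.
#'
#' @inheritParams soft_besiege_dives
#' @param S_m Mean position of the flock.
#' @return List with `position` and `fitness`.
#' @export
hard_besiege_dives <- function(S, S_prey, S_m, Eg, fitness, objective,
                               gamma, lb, ub) {
  Jp <- 2 * (1 - stats::runif(1))
  U <- S_prey - Eg * abs(Jp * S_prey - S_m)
  .dive_accept(S, fitness, U, objective, gamma, lb, ub)
}

#' BHHSHO configuration
#'
#' @param N Population size (>= 2).
#' @param iters Maximum iterations (>= 1).
#' @param lb,ub Bound vectors (recycled to the problem dimension;
#'   `lb < ub` componentwise).
#' @param gamma Levy exponent, default 1.5.
#' @param logistic_a Logistic-map parameter in `(0, 4]`, default 4.
#' @param seed Integer seed; every run with the same seed is bit-identical.
#' @param sense `"minimize"` (default) or `"maximize"`.
#' @return A list of class `bhhsho_config`.
#' @export
bhhsho_config <- function(N = 30L, iters = 200L, lb, ub, gamma = 1.5,
                          logistic_a = 4, seed = 1L,
                          sense = c("minimize", "maximize")) {
  sense <- match.arg(sense)
  stopifnot(N >= 2, iters >= 1, all(lb < ub))
  structure(list(N = as.integer(N), iters = as.integer(iters),
                 lb = as.numeric(lb), ub = as.numeric(ub),
                 gamma = gamma, logistic_a = logistic_a,
                 seed = as.integer(seed), sense = sense),
            class = "bhhsho_config")
}

#' Run the BHHSHO optimizer
#'
#' Bounded black-box optimization. Per hawk and iteration, the initial
#' escape energy is redrawn uniformly in `(-1, 1)` and multiplied by a
#' chaotic logistic-map factor; `|Eg| >= 1` dispatches to exploration,
#' otherwise one of the four besiege strategies is chosen by `(|Eg|, r)`
#' with `r` uniform. Every hard besiege is followed by the greedy
#' shuffled-shepherd update. Candidates are clamped to the bounds before
#' evaluation; non-finite objective values reject the candidate. The global
#' best ("prey") is maintained greedily, so the best-so-far history is
#' monotone.
#'
#' @param objective Function mapping a position vector to a finite scalar.
#' @param config A [bhhsho_config()].
#' @return An object of class `bhhsho_result`: list with `best_position`,
#'   `best_fitness` (in the configured sense), `history` tibble
#'   (`iteration`, `best_fitness`, `mean_fitness`), `n_rejected`, and the
#'   config.
#' @export
bhhsho_optimize <- function(objective, config) {
  stopifnot(inherits(config, "bhhsho_config"))
  maximize <- config$sense == "maximize"
  obj <- if (maximize) function(x) -objective(x) else objective
  d <- max(length(config$lb), length(config$ub))
  lb <- rep_len(config$lb, d); ub <- rep_len(config$ub, d)
  withr::local_seed(config$seed)

  pos <- t(replicate(config$N, lb + stats::runif(d) * (ub - lb)))
  if (d == 1L) pos <- matrix(pos, ncol = 1L)
  fit <- apply(pos, 1, obj)
  n_rejected <- sum(!is.finite(fit))
  fit[!is.finite(fit)] <- Inf
  best_i <- which.min(fit)
  prey <- pos[best_i, ]; prey_fit <- fit[best_i]
  # chaotic multiplier chain, seeded away from the map's degenerate points
  phi <- stats::runif(1, 0.05, 0.95)
  while (phi %in% c(0.25, 0.5, 0.75)) phi <- stats::runif(1, 0.05, 0.95)

  history <- matrix(NA_real_, nrow = config$iters, ncol = 2)
  for (t in seq_len(config$iters)) {
    S_m <- colMeans(pos)
    worst_i <- which.max(fit)
    for (i in seq_len(config$N)) {
      S <- pos[i, ]
      phi <- logistic_step(phi, config$logistic_a)
      Eg0 <- stats::runif(1, -1, 1)
      Eg <- escape_energy(Eg0, phi, t, config$iters)
      if (abs(Eg) >= 1) {
        S_rand <- boosted_srand(prey, pos[worst_i, ], S)
        cand <- explore_step(S, prey, S_m, S_rand, lb, ub)
        f_cand <- obj(cand)
        if (is.finite(f_cand)) {
          pos[i, ] <- cand; fit[i] <- f_cand
        } else n_rejected <- n_rejected + 1L
      } else {
        r <- stats::runif(1)
        if (r >= 0.5 && abs(Eg) >= 0.5) {
          cand <- .clamp(soft_besiege(S, prey, Eg), lb, ub)
          f_cand <- obj(cand)
          if (is.finite(f_cand)) {
            pos[i, ] <- cand; fit[i] <- f_cand
          } else n_rejected <- n_rejected + 1L
        } else if (r >= 0.5) {
          cand <- .clamp(hard_besiege(S, prey, Eg), lb, ub)
          f_cand <- obj(cand)
          if (is.finite(f_cand)) {
            pos[i, ] <- cand; fit[i] <- f_cand
          } else n_rejected <- n_rejected + 1L
          upd <- ssoa_update(pos[i, ], prey, prey, fit[i], obj,
                             config$gamma, lb, ub)
          pos[i, ] <- upd$position; fit[i] <- upd$fitness
        } else if (abs(Eg) >= 0.5) {
          upd <- soft_besiege_dives(S, prey, Eg, fit[i], obj,
                                    config$gamma, lb, ub)
          pos[i, ] <- upd$position; fit[i] <- upd$fitness
        } else {
          upd <- hard_besiege_dives(S, prey, S_m, Eg, fit[i], obj,
                                    config$gamma, lb, ub)
          pos[i, ] <- upd$position; fit[i] <- upd$fitness
        }
      }
      if (fit[i] < prey_fit) {        # strict: ties keep the incumbent
        prey_fit <- fit[i]; prey <- pos[i, ]
      }
    }
    history[t, ] <- c(prey_fit, mean(fit[is.finite(fit)]))
  }

  sign <- if (maximize) -1 else 1
  structure(list(
    best_position = prey,
    best_fitness = sign * prey_fit,
    history = tibble::tibble(iteration = seq_len(config$iters),
                             best_fitness = sign * history[, 1],
                             mean_fitness = sign * history[, 2]),
    n_rejected = n_rejected,
    config = config), class = "bhhsho_result")
}

#' @export
print.bhhsho_result <- function(x, ...) {
  cat(sprintf(
    "<bhhsho_result: best fitness %.6g (%s) after %d iterations, N = %d>\n",
    x$best_fitness, x$config$sense, x$config$iters, x$config$N))
  invisible(x)
}

#' Classification precision used as tuning fitness
#'
#' `P = TP / (TP + FP)`; the hyperparameter search maximizes this.
#'
#' @param counts List or named vector with elements `TP` and `FP`.
#' @return Precision in `[0, 1]`.
#' @export
fitness_precision <- function(counts) {
  TP <- counts[["TP"]]; FP <- counts[["FP"]]
  if (TP + FP == 0) {
    stop("undefined precision: no positive predictions (TP + FP = 0)",
         call. = FALSE)
  }
  TP / (TP + FP)
}
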