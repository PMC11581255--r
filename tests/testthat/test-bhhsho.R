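test_that("logistic map: arithmetic, fixed point, domain, confinement", {
  expect_equal(logistic_step(0.5, 4), 1.0)
  expect_equal(logistic_step(0.75, 4), 0.75)   # fixed point of a = 4
  expect_equal(logistic_step(0, 2.7), 0)
  expect_error(logistic_step(1.2, 4), "phi")
  expect_error(logistic_step(0.5, 4.5), "a")

  phi <- 0.7
  for (i in 1:1000) {
    phi <- logistic_step(phi, 4)
    expect_true(phi >= 0 && phi <= 1)
  }
})

test_that("escape energy follows 2*C*Eg0*(1 - t/t_max)", {
  expect_equal(escape_energy(1, 1, 10, 10), 0)
  expect_equal(escape_energy(1, 1, 0, 10), 2)
  expect_equal(escape_energy(-1, 0.5, 5, 10), -0.5)
  expect_error(escape_energy(1, 1, 0, 0), "positive")
  expect_error(escape_energy(1, 1, 11, 10), "t")

  # decay envelope: |Eg| <= 2 * (1 - t/t_max) for C in (0,1), |Eg0| < 1
  set.seed(1)
  for (i in 1:200) {
    t <- sample(0:99, 1)
    Eg <- escape_energy(runif(1, -1, 1), runif(1), t, 100)
    expect_lte(abs(Eg), 2 * (1 - t / 100) + 1e-12)
  }
})

test_that("boosted random reference is the three-point mean", {
  v <- c(1.5, -2)
  expect_equal(boosted_srand(v, v, v), v)
  expect_equal(boosted_srand(3, 0, 0), 1)
  set.seed(2)
  x <- rnorm(4); y <- rnorm(4); z <- rnorm(4)
  expect_equal(boosted_srand(2 * x, 2 * y, 2 * z),
               2 * boosted_srand(x, y, z))
  expect_error(boosted_srand(1:2, 1:3, 1:2), "dimension")
})

test_that("Mantegna Levy scale matches independent special-function values", {
  # frozen from an external gamma-function evaluation
  expect_equal(levy_sigma(1.5), 0.6965745025576968, tolerance = 1e-10)
  expect_equal(levy_sigma(1.0), 1.0)
  for (g in c(0.5, 1.0, 1.5, 2.0)) {
    s <- levy_sigma(g)
    expect_true(is.finite(s) && s > 0)
  }
  expect_error(levy_sigma(2.5), "gamma")

  # heavy tail: sample kurtosis far above the Gaussian value of 3
  set.seed(3)
  draws <- levy_step(1e5, 1.5)
  kurt <- mean((draws - mean(draws))^4) / stats::var(draws)^2
  expect_gt(kurt, 10)
})

test_that("besiege moves reproduce their closed forms", {
  S <- c(0, 0); prey <- c(1, 1)

  # soft besiege with Eg = 0 reduces to the prey offset Delta S
  expect_equal(soft_besiege(S, prey, Eg = 0, Jp = 1), prey - S)
  # at the prey with Jp = 1 the hawk stays put (zero offset from prey)
  expect_equal(soft_besiege(prey, prey, Eg = 0.7, Jp = 1), c(0, 0))

  # hard besiege collapses onto the prey as energy vanishes
  expect_equal(hard_besiege(S, prey, Eg = 0), prey)
  expect_equal(hard_besiege(prey, prey, Eg = 0.3), prey)
  expect_equal(hard_besiege(0, 1, Eg = 0.4), 0.6)
})

test_that("dive strategies accept greedily and never worsen the hawk", {
  sphere <- function(x) sum(x^2)
  lb <- c(-5, -5); ub <- c(5, 5)
  set.seed(4)

  # prey at the optimum: accepted moves never increase the objective
  prey <- c(0, 0)
  for (i in 1:300) {
    S <- runif(2, -5, 5)
    f <- sphere(S)
    for (fun in c("soft", "hard")) {
      upd <- if (fun == "soft") {
        soft_besiege_dives(S, prey, runif(1, -1, 1), f, sphere, 1.5, lb, ub)
      } else {
        hard_besiege_dives(S, prey, runif(2, -1, 1), runif(1, -0.5, 0.5),
                           f, sphere, 1.5, lb, ub)
      }
      expect_lte(upd$fitness, f)
      expect_equal(upd$fitness, sphere(upd$position))
    }
  }

  # both candidates worse: position unchanged (objective penalizes moving)
  stay <- function(x) if (all(x == c(1, 1))) 0 else 10
  upd <- soft_besiege_dives(c(1, 1), c(3, 3), 0.9, 0, stay, 1.5, lb, ub)
  expect_equal(upd$position, c(1, 1))
  expect_equal(upd$fitness, 0)

  # shuffled-shepherd update keeps the incumbent unless strictly better
  upd2 <- ssoa_update(c(1, 1), c(3, 3), c(3, 3), 0, stay, 1.5, lb, ub)
  expect_equal(upd2$position, c(1, 1))
})

test_that("exploration stays within bounds", {
  set.seed(5)
  lb <- c(-1, -1); ub <- c(1, 1)
  for (i in 1:1000) {
    S <- runif(2, -1, 1)
    out <- explore_step(S, runif(2, -1, 1), runif(2, -1, 1),
                        boosted_srand(runif(2, -1, 1), runif(2, -1, 1), S),
                        lb, ub)
    expect_true(all(out >= lb & out <= ub))
  }
})

test_that("optimizer contract: determinism, monotone history, feasibility", {
  cfg <- bhhsho_config(N = 10, iters = 40, lb = c(-5, -5), ub = c(5, 5),
                       seed = 6)

  # constant objective: flat history at that constant
  rc <- bhhsho_optimize(function(x) 4.2, cfg)
  expect_true(all(rc$history$best_fitness == 4.2))

  # identical seeds give identical runs
  sphere <- function(x) sum(x^2)
  r1 <- bhhsho_optimize(sphere, cfg)
  r2 <- bhhsho_optimize(sphere, cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_position, r2$best_position)

  # every evaluated candidate within bounds; best-so-far never worsens
  seen <- new.env(); seen$bad <- 0
  watched <- function(x) {
    if (any(x < -5 | x > 5)) seen$bad <- seen$bad + 1
    sum(x^2)
  }
  for (s in 1:10) {
    cs <- bhhsho_config(N = 8, iters = 30, lb = c(-5, -5), ub = c(5, 5),
                        seed = s)
    r <- bhhsho_optimize(watched, cs)
    expect_true(all(diff(r$history$best_fitness) <= 0))
    expect_equal(r$best_fitness, min(r$history$best_fitness))
  }
  expect_equal(seen$bad, 0)

  # maximization negates cleanly
  rm <- bhhsho_optimize(function(x) -sum(x^2),
                        bhhsho_config(N = 10, iters = 60, lb = c(-5, -5),
                                      ub = c(5, 5), seed = 7,
                                      sense = "maximize"))
  expect_true(all(diff(rm$history$best_fitness) >= 0))
  expect_gt(rm$best_fitness, -1e-2)

  # non-finite objective values are rejected, not propagated
  spiky <- function(x) if (abs(x[1]) < 0.5) NaN else sum(x^2)
  rs <- bhhsho_optimize(spiky, cfg)
  expect_true(is.finite(rs$best_fitness))
  expect_gt(rs$n_rejected, 0)
})

test_that("precision fitness follows TP / (TP + FP)", {
  expect_equal(fitness_precision(list(TP = 9, FP = 1)), 0.9)
  expect_equal(fitness_precision(list(TP = 5, FP = 0)), 1.0)
  expect_equal(fitness_precision(list(TP = 0, FP = 3)), 0.0)
  expect_error(fitness_precision(list(TP = 0, FP = 0)),
               "undefined precision")
})

test_that("tidiers and plots expose the optimizer run", {
  r <- bhhsho_optimize(function(x) sum(x^2),
                       bhhsho_config(N = 5, iters = 10, lb = -1, ub = 1,
                                     seed = 1))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("iteration", "best_fitness", "mean_fitness"))
  gl <- glance(r)
  expect_equal(gl$best_fitness, r$best_fitness)
  expect_s3_class(autoplot(r), "ggplot")
})
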