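fake_sim <- function(n_t = 5, N = 1, mgmt = 100, ref = 100) {
  structure(list(series = tibble::tibble(
    t = seq_len(n_t), M = round(N * 100), N = N,
    mean_mrna_mgmt = 1, mean_mgmt = mgmt,
    mean_mrna_ref = 1, mean_ref = ref,
    ratio = mgmt / ref
  )), class = "phenosel_sim")
}

test_that("error functions match their definitions on controlled input", {
  expect_equal(compute_errors(fake_sim(N = 1), which = "E2"), c(E2 = 0))
  expect_equal(compute_errors(fake_sim(N = 0.4), which = "E2"),
               c(E2 = 0.6))
  expect_equal(compute_errors(fake_sim(mgmt = 80, ref = 80),
                              which = "E1"), c(E1 = 1))
  expect_equal(compute_errors(fake_sim(mgmt = 200, ref = 50),
                              which = "E1"), c(E1 = 0.25))
  # undefined E1 scores worst
  expect_equal(compute_errors(fake_sim(mgmt = 0), which = "E1"),
               c(E1 = Inf))
})

test_that("E3 is zero when the simulated series reproduces the data", {
  tt <- c(24, 48)
  sim0 <- fake_sim(N = 1)
  sim0$series$t <- c(0, 24, 48, 72, 96)
  sim8 <- sim0
  sim8$series$N <- c(1, 0.8, 0.6, 0.5, 0.4)
  pct <- 100 * sim8$series$N[2:3]
  data <- tibble::tibble(
    dose_uM = rep(c(0, 800), each = 2), time_h = rep(tt, 2),
    rep1 = c(100, 100, pct), rep2 = c(100, 100, pct)
  )
  e <- compute_errors(list("0" = sim0, "800" = sim8), data = data,
                      which = "E3")
  expect_equal(e, c(E3 = 0))
  # perturbing the data by a constant offset gives MSE = offset^2 * 2
  data2 <- dplyr::mutate(data, rep1 = rep1 + 3, rep2 = rep2 + 3)
  expect_equal(compute_errors(list("0" = sim0, "800" = sim8),
                              data = data2, which = "E3"),
               c(E3 = 18))
  expect_error(compute_errors(sim8, data = data, which = "E3"), "dose")
})

test_that("zero-loss rejection keeps a prior sample with full bookkeeping", {
  set.seed(41)
  pr <- prior_spec(c("kd", "eps"), lower = c(0, 0), upper = c(10, 0.1))
  post <- abc_rejection(pr, function(th) c(E2 = 0), budget = 400,
                        keep = 100)
  expect_equal(nrow(tidy(post)), 100L)
  expect_true(all(tidy(post)$score == 0))
  # accepted draws stay inside the prior box and look uniform
  expect_true(all(tidy(post)$kd >= 0 & tidy(post)$kd <= 10))
  expect_gt(suppressWarnings(
    stats::ks.test(tidy(post)$kd, "punif", 0, 10))$p.value, 1e-3)
  g <- glance(post)
  expect_equal(g$n_proposed, 400L)
  expect_equal(g$n_kept, 100L)
  expect_error(abc_rejection(pr, function(th) 0, budget = 5, keep = 10),
               "budget")
})

test_that("failing or non-finite losses never crash and score worst", {
  set.seed(42)
  pr <- prior_spec("x", 0, 1)
  post <- abc_rejection(pr, function(th) {
    if (th$x > 0.5) stop("boom")
    c(err = th$x)
  }, budget = 100, keep = 10)
  expect_true(all(tidy(post)$x <= 0.5))
  expect_gt(glance(post)$n_failed, 0)
})

test_that("rejection ABC approaches the analytic posterior in a toy", {
  # Normal mean with known unit variance, n = 25 observations, flat
  # prior: the exact posterior is N(xbar, 1/25) (sd = 0.2) as the
  # acceptance threshold shrinks
  set.seed(43)
  obs <- stats::rnorm(25, mean = 0.5, sd = 1)
  xbar <- mean(obs)
  pr <- prior_spec("theta", -5, 5)
  loss <- function(th) {
    c(err = abs(mean(stats::rnorm(25, th$theta, 1)) - xbar))
  }
  post_loose <- abc_rejection(pr, loss, budget = 8000, keep = 2000)
  post_tight <- abc_rejection(pr, loss, budget = 8000, keep = 120)
  th_tight <- tidy(post_tight)$theta
  expect_lt(abs(mean(th_tight) - xbar), 0.12)
  expect_gt(stats::sd(th_tight), 0.15)
  expect_lt(stats::sd(th_tight), 0.40)
  # tightening the acceptance shrinks the posterior toward the analytic one
  expect_lt(stats::sd(th_tight), stats::sd(tidy(post_loose)$theta))
})

test_that("posterior mode is the best-scoring accepted draw", {
  pr <- prior_spec("x", 0, 1)
  set.seed(44)
  post <- abc_rejection(pr, function(th) c(e = abs(th$x - 0.3)),
                        budget = 500, keep = 50)
  expect_lt(abs(posterior_mode(post)$x - 0.3), 0.02)
  # single-draw posterior returns that draw
  post1 <- abc_rejection(pr, function(th) c(e = th$x), budget = 30,
                         keep = 1)
  expect_equal(posterior_mode(post1)$x, min(post1$proposals$x))
})

test_that("posterior correlations detect compensation and degeneracy", {
  set.seed(45)
  # a loss that only constrains the death-rate ratio induces kd-s
  # compensation: accepted draws ride the ridge kd*tmz ~ s*MGMT
  pr <- prior_spec(c("kd", "s"), lower = c(0.01, 0.1),
                   upper = c(10, 100), scale = "log")
  target <- (0.1808 * 800) / (0.1808 * 800 + 96.8167 * 100)
  loss <- function(th) {
    f2 <- (th$kd * 800) / (th$kd * 800 + th$s * 100)
    c(e = abs(f2 - target))
  }
  post <- abc_rejection(pr, loss, budget = 3000, keep = 100)
  ct <- posterior_correlations(post)
  expect_gt(ct$correlation[ct$param1 == "log_kd" &
                             ct$param2 == "log_s"], 0.9)
  # a constant parameter gets correlation 0 by convention
  fake <- post
  fake$accepted$s <- 50
  expect_equal(posterior_correlations(fake)$correlation, 0)
})

test_that("posterior precision ranks constrained parameters highest", {
  set.seed(46)
  pr <- prior_spec(c("a", "b"), lower = -100, upper = 100)
  draws <- tibble::tibble(a = stats::rnorm(500, 0, 1),
                          b = stats::rnorm(500, 0, 2), score = 0)
  post <- structure(list(accepted = draws, priors = pr, budget = 500L,
                         keep = 500L, error_names = "e"),
                    class = "phenosel_abc")
  sens <- posterior_sensitivity(post)
  expect_equal(unname(sens$precision), c(1, 0.25), tolerance = 0.2)
  expect_false(any(sens$regularized))
  # perfectly collinear draws force the ridge fallback
  draws2 <- dplyr::mutate(draws, b = 2 * a)
  post2 <- structure(list(accepted = draws2, priors = pr, budget = 500L,
                          keep = 500L, error_names = "e"),
                     class = "phenosel_abc")
  expect_true(all(posterior_sensitivity(post2)$regularized))
})

test_that("growth fitting recovers the rate and prefers the right model", {
  set.seed(47)
  # noise-free exponential data at the fitted mu
  g <- synth_growth(mu_true = 0.01388, cv = 0)
  fit <- fit_growth(g, budget = 3000)
  expect_lt(abs(fit$mu - 0.01388) / 0.01388, 0.10)
  expect_equal(fit$doubling_time, log(2) / fit$mu)
  expect_lt(abs(log(2) / 0.01388 - 49.956), 0.05)
  # the logistic nests the exponential (Kc -> Inf), so on exact
  # exponential data the comparison can only mildly prefer the smaller
  # model; it must not prefer the logistic one decisively
  expect_gte(fit$model_probs[["exponential"]], 0.4)
  # visibly saturating logistic data flips the comparison
  tt <- seq(0, 144, by = 24)
  Kc <- 3e5
  n0 <- 8e4
  mu <- 0.03
  ylog <- Kc * n0 * exp(mu * tt) / (Kc + n0 * (exp(mu * tt) - 1))
  gl <- tibble::tibble(time_h = tt, rep1 = ylog, rep2 = ylog, rep3 = ylog)
  fit_l <- fit_growth(gl, budget = 3000)
  expect_gt(fit_l$model_probs[["logistic"]], 0.5)
  expect_error(fit_growth(dplyr::mutate(g, rep1 = -rep1)), "> 0")
})
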