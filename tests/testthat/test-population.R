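test_that("volume growth is exponential with the expected doubling time", {
  cells <- one_cell(volume = 15)
  expect_equal(grow_volume(cells, 0.0948, log(2) / 0.0948)$volume, 30)
  expect_equal(grow_volume(cells, 0.0948, 0)$volume, 15)
  # doubling time of the fitted cell line: ln 2 / 0.01388 = 49.94 h
  expect_equal(grow_volume(cells, 0.01388, 49.956)$volume, 30,
               tolerance = 1e-3)
  expect_error(grow_volume(cells, 0.1, -1), "dt")
})

test_that("the size map is exact when noise-free and bounded when asked", {
  p <- params_general(sigma1 = 0)
  expect_equal(draw_vf_target(15, p, bounded = FALSE), 30)  # a=1, b=15
  set.seed(21)
  p2 <- params_general()  # sigma1 = 0.2
  v <- draw_vf_target(rep(15, 1e5), p2, bounded = FALSE)
  expect_lt(abs(stats::sd(v) - 0.2), 0.005)
  expect_lt(abs(mean(v) - 30), 3 * 0.2 / sqrt(1e5))
  vb <- draw_vf_target(rep(15, 1e4), p2, bounded = TRUE)
  expect_true(all(vb > 29.25 & vb < 30.75))
  expect_error(draw_vf_target(-1, p2), "v_init")
})

test_that("division conserves molecules and splits volume by eta2", {
  set.seed(22)
  p <- params_general()
  for (i in 1:200) {
    parent <- one_cell(volume = stats::runif(1, 29, 31),
                       mgmt = sample(0:500, 1), ref = sample(0:500, 1),
                       mrna_mgmt = sample(0:5, 1),
                       mrna_ref = sample(0:5, 1))
    d <- divide_cell(parent, p)
    for (cn in c("mrna_mgmt", "mgmt", "mrna_ref", "ref")) {
      expect_identical(d[[cn]][1] + d[[cn]][2], parent[[cn]])
      expect_true(all(d[[cn]] >= 0))
    }
    expect_equal(sum(d$volume), parent$volume)
    expect_true(all(d$vf_target >= 29.25 & d$vf_target <= 30.75))
  }
  # sigma2 = 0: exact halving of volume, fair binomial per molecule
  p0 <- params_general(sigma2 = 0)
  d0 <- divide_cell(one_cell(volume = 30, mgmt = 10), p0)
  expect_equal(d0$volume, c(15, 15))
  splits <- vapply(1:2000, function(i) {
    divide_cell(one_cell(mgmt = 1), p0)$mgmt[1]
  }, numeric(1))
  expect_lt(abs(mean(splits) - 0.5), 3 * 0.5 / sqrt(2000))
  expect_error(divide_cell(dplyr::mutate(one_cell(), alive = FALSE), p),
               "alive")
})

test_that("forced eta2 arithmetic matches the daughter-volume equations", {
  set.seed(30)
  p <- params_general()
  # V_F = 30 with eta2 = 0.4 gives daughters of 12 and 18
  d <- divide_cell(one_cell(volume = 30), p, eta2 = 0.4)
  expect_equal(d$volume, c(12, 18))
  d5 <- divide_cell(one_cell(volume = 30, mgmt = 10), p, eta2 = 0.5)
  expect_equal(sum(d5$mgmt), 10)
  expect_error(divide_cell(one_cell(), p, eta2 = 1.2), "eta2")
})

test_that("slot count is constant and N is consistent with live slots", {
  set.seed(23)
  p <- params_constrained(K = 150)
  sim <- simulate_population(p, dose_schedule("sigmoid", 800), t_end = 96)
  expect_equal(nrow(sim$cells), 150L)
  expect_true(all(sim$series$M <= 150))
  expect_true(all(sim$series$N == sim$series$M / 150))
  expect_equal(viability(sim), mean(sim$cells$alive))
})

test_that("populations without death keep every slot occupied", {
  set.seed(24)
  p <- model_params(mu0 = 0.0948, kd = 0, eps = 0, K = 100L)
  sim <- simulate_population(p, dose_schedule("step", 0, t_in = 1e9),
                             t_end = 72)
  expect_true(all(sim$series$N == 1))
  expect_gt(sim$n_divisions, 0)  # turnover happens, slots stay full
})

test_that("overwhelming death drives monotone extinction", {
  set.seed(25)
  # no MGMT production and saturating dose: every cell dies at ~kd2
  p <- model_params(mu0 = 0.0948, b1 = 0, b2 = 0, d = 0, kd = 1.92,
                    kd2 = 1, eps = 0, K = 120L)
  init <- init_population(p, 120)
  init$mgmt <- 0
  init$ref <- 0
  sim <- simulate_population(p, dose_schedule("step", 800, t_in = 0),
                             t_end = 30, init = init)
  expect_true(all(diff(sim$series$N) <= 0))
  expect_equal(viability(sim), 0)
  # all-dead populations short-circuit
  init$alive <- FALSE
  sim2 <- simulate_population(p, dose_schedule("step", 800, t_in = 0),
                              t_end = 5, init = init)
  expect_true(all(sim2$series$N == 0))
  expect_equal(sim2$n_divisions + sim2$n_deaths, 0)
})

test_that("one outer step advances the clock and preserves the slots", {
  set.seed(26)
  p <- params_constrained(K = 80)
  cells <- init_population(p, 80)
  out <- step_population(cells, t = 0, params = p,
                         schedule = dose_schedule("sigmoid", 800))
  expect_equal(out$t, 0.1)
  expect_equal(nrow(out$cells), 80L)
  expect_true(all(out$cells$mgmt >= 0))
})

test_that("MGMT and REF are exchangeable without TMZ", {
  set.seed(27)
  p <- params_constrained(K = 400)
  sim <- simulate_population(p, dose_schedule("step", 0, t_in = 1e9),
                             t_end = 120)
  live <- sim$cells[sim$cells$alive, ]
  ks <- suppressWarnings(stats::ks.test(live$mgmt, live$ref))
  expect_gt(ks$p.value, 1e-3)
  lr <- log(mean(live$mgmt) / mean(live$ref))
  se <- sqrt(stats::var(live$mgmt) / (nrow(live) * mean(live$mgmt)^2) +
               stats::var(live$ref) / (nrow(live) * mean(live$ref)^2))
  expect_lt(abs(lr), 3 * se)
})

test_that("viability and recovery bookkeeping follow their definitions", {
  expect_equal(viability_recovery(c(1.0, 0.4, 0.7)), 0.3)
  expect_equal(viability_recovery(c(1, 0.8, 0.6, 0.5)), 0)
  expect_equal(viability_recovery(rep(0.7, 5)), 0)
  expect_error(viability_recovery(numeric(0)), "empty")
  cells <- dplyr::bind_rows(purrr::map(1:10, ~ one_cell()))
  cells$alive <- rep(c(TRUE, FALSE), 5)
  expect_equal(viability(cells), 0.5)
})

test_that("replacement policy does not change population outcomes", {
  p <- params_constrained(K = 300)
  sched <- dose_schedule("sigmoid", 800)
  final_n <- function(policy, seed) {
    set.seed(seed)
    viability(simulate_population(p, sched, t_end = 120,
                                  replacement = policy))
  }
  a <- mean(vapply(1:3, function(s) final_n("random", s), numeric(1)))
  b <- mean(vapply(1:3, function(s) final_n("dead_first", s + 10),
                   numeric(1)))
  expect_lt(abs(a - b), 0.1)
})
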