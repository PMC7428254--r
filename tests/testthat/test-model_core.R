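test_that("parameter validation enforces the model's invariants", {
  expect_s3_class(params_general(), "phenosel_params")
  expect_error(model_params(mu0 = -1), "mu0")
  expect_error(model_params(sigma2 = 0.7), "sigma2")
  expect_error(model_params(vf_bounds = c(31, 29)), "vf_bounds")
  expect_error(model_params(K = 0), "K")
  expect_error(model_params(b1 = NaN), "b1")
})

test_that("growth rate reduces to mu0 off-dose and is inhibited on-dose", {
  p <- params_general(I50 = 0.0013)
  expect_equal(growth_rate(p, tmz = 0, dosing_active = TRUE), 0.0948)
  expect_equal(growth_rate(p, tmz = 800, dosing_active = FALSE), 0.0948)
  # printed Table-1 arithmetic: mu0 / (1 + 800/0.0013)
  expect_equal(growth_rate(p, tmz = 800, dosing_active = TRUE),
               0.0948 / (1 + 800 / 0.0013), tolerance = 1e-12)
  expect_lt(growth_rate(p, tmz = 800, dosing_active = TRUE), 1.6e-7)
  # result always in (0, mu0]
  for (tmz in c(0, 1, 100, 1e4)) {
    f1 <- growth_rate(p, tmz)
    expect_gt(f1, 0)
    expect_lte(f1, p$mu0)
  }
  expect_error(growth_rate(p, tmz = -1), "tmz")
  expect_error(growth_rate(p, tmz = Inf), "tmz")
})

test_that("death rate follows the pseudo-steady-state closed form", {
  p <- params_general()
  # MGMT = 0: repair term vanishes, f2 saturates at kd2
  expect_equal(death_rate(p, mgmt = 0, tmz = 800), 1.0)
  # no TMZ: no damage source
  expect_equal(death_rate(p, mgmt = 50, tmz = 0), 0)
  # the 0/0 corner is defined as 0
  expect_equal(death_rate(p, mgmt = 0, tmz = 0), 0)
  # Table-1 arithmetic: 1536 / (1536 + 20225)
  expect_equal(death_rate(p, mgmt = 100, tmz = 800),
               (1.92 * 800) / (1.92 * 800 + 202.25 * 100),
               tolerance = 1e-12)
  # basal term added only on request
  pc <- params_constrained()
  expect_equal(death_rate(pc, 100, 800, include_basal = TRUE) -
                 death_rate(pc, 100, 800), pc$eps)
})

test_that("f2 is bounded by kd2, decreasing in MGMT, non-decreasing in TMZ", {
  p <- params_general()
  mgmt <- c(0, 1, 10, 100, 1e4, 1e7)
  f2 <- death_rate(p, mgmt, tmz = 800)
  expect_true(all(diff(f2) < 0))
  expect_true(all(f2 >= 0 & f2 <= p$kd2))
  expect_equal(max(f2), p$kd2)
  tmz <- c(0, 1, 10, 400, 800)
  expect_true(all(diff(death_rate(p, 100, tmz)) > 0))
})

test_that("damaged-DNA fraction matches death_rate / kd2 and its examples", {
  p <- params_general()
  expect_equal(dna_dam_pss(p, mgmt = 0, tmz = 800), 1)
  expect_equal(dna_dam_pss(p, mgmt = 50, tmz = 0), 0)
  mgmt <- c(0, 3, 50, 2000)
  expect_equal(dna_dam_pss(p, mgmt, 800), death_rate(p, mgmt, 800) / p$kd2)
  expect_true(all(dna_dam_pss(p, mgmt, 800) >= 0 &
                    dna_dam_pss(p, mgmt, 800) <= 1))
})

test_that("reduced network has the published channel list", {
  net <- build_network(params_general(), "reduced")
  expect_equal(nrow(net$reactions), 7L)  # 2 transcription, 2 decay,
  expect_equal(sum(net$reactions$is_death), 1L)  # 2 translation, 1 death
  expect_setequal(net$species, c("mRNA_MGMT", "MGMT", "mRNA_REF", "REF"))
  # optional protein decay adds two channels
  net2 <- build_network(model_params(d2 = 0.01), "reduced")
  expect_equal(nrow(net2$reactions), 9L)
  expect_error(build_network(params_general(), "bogus"))
})

test_that("full network's damage channel is silent without TMZ or damage", {
  p <- params_general()
  net <- build_network(p, "full")
  expect_true("DNA_DAM" %in% net$species)
  # no TMZ: the damage state can never switch on, death never fires
  res <- advance_reactions(c(0, 0, 0, 0, 0), net, window = 50,
                           cfg = engine_config("ssa"), tmz = 0)
  expect_equal(res$state[["DNA_DAM"]], 0)
  expect_false(res$death_fired)
})

test_that("full and reduced models agree on death statistics at the fitted s", {
  # frozen expression (b1 = b2 = 0, d = 0): the death hazard of the full
  # model after the fast damage/repair cycle equilibrates must match the
  # reduced model's closed-form f2.  Oracle: the full network itself.
  set.seed(42)
  p <- model_params(mu0 = 0.0948, b1 = 0, d = 0, b2 = 0,
                    s = 202.25, kd = 1.92, kd2 = 1, eps = 0)
  window <- 10
  n <- 1500
  died_of <- function(variant) {
    net <- build_network(p, variant)
    x0 <- if (variant == "full") c(0, 100, 0, 100, 0) else c(0, 100, 0, 100)
    mean(vapply(seq_len(n), function(i) {
      advance_reactions(x0, net, window, engine_config("ssa"),
                        tmz = 800)$death_fired
    }, logical(1)))
  }
  p_full <- died_of("full")
  p_red <- died_of("reduced")
  p_theory <- 1 - exp(-death_rate(p, 100, 800) * window)
  se <- sqrt(p_theory * (1 - p_theory) / n)
  expect_lt(abs(p_full - p_theory), 3 * se)
  expect_lt(abs(p_red - p_theory), 3 * se)
  expect_lt(abs(p_full - p_red), 3 * se * sqrt(2))
})

test_that("time-averaged damage occupancy converges to the closed form", {
  # with expression frozen, DNA_DAM is a fast two-state switch whose
  # occupancy should match kd*tmz / (kd*tmz + s*MGMT); estimated here by
  # the fraction of many short windows ending damaged (ergodic average)
  set.seed(43)
  p <- model_params(mu0 = 0, b1 = 0, d = 0, b2 = 0,
                    s = 2, kd = 0.05, kd2 = 0, eps = 0)
  net <- build_network(p, "full")
  mgmt <- 40
  tmz <- 800
  n <- 800
  occ <- mean(vapply(seq_len(n), function(i) {
    advance_reactions(c(0, mgmt, 0, 0, 0), net, window = 5,
                      engine_config("ssa"), tmz = tmz)$state[["DNA_DAM"]]
  }, numeric(1)))
  target <- dna_dam_pss(p, mgmt, tmz)
  se <- sqrt(target * (1 - target) / n)
  expect_lt(abs(occ - target), 3 * se)
})

test_that("mean-field steady states match the published closed forms", {
  p <- params_general()
  mf <- mean_field(p)
  expect_equal(mf$mean_mrna, 0.0016 / (0.0003 + 0.0948), tolerance = 1e-12)
  expect_equal(mf$mean_protein,
               0.0016 * 5483.75 / ((0.0003 + 0.0948) * 0.0948),
               tolerance = 1e-12)
  # b1 -> 0 sends both to 0
  mf0 <- mean_field(model_params(b1 = 0))
  expect_equal(mf0$mean_mrna, 0)
  expect_equal(mf0$mean_protein, 0)
})
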