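test_that("the default gate recovers the planted algal population exactly", {
  tab <- mixed_events(100, 400)
  g <- gate_algae(tab)
  expect_identical(g$cells_total, 100L)
  expect_identical(g$mask, attr(tab, "truth")$is_algal)
})

test_that("an impossible threshold is an error and gating is idempotent", {
  tab <- mixed_events(100, 400, seed = 4)
  expect_error(gate_algae(tab, gate_spec("absolute", red_value = 1e9)),
               "no events")
  g <- gate_algae(tab)
  sub <- tab[g$mask, ]
  class(sub) <- class(tab)
  g2 <- gate_algae(sub)
  expect_true(all(g2$mask))
  expect_identical(g2$cells_total, g$cells_total)
})

test_that("quantile and absolute gate policies are honoured", {
  tab <- mixed_events(200, 200, seed = 5)
  gq <- gate_algae(tab, gate_spec("quantile", red_value = 0.5))
  expect_identical(gq$cells_total, 200L)   # balanced mixture: median splits it
  ga <- gate_algae(tab, gate_spec("absolute", red_value = 50))
  expect_identical(ga$cells_total, sum(tab$red >= 50))
  expect_error(gate_spec("quantile", red_value = 1.5), "quantile")
  expect_error(gate_spec(fsc_bounds = c(5, 2)), "fsc_bounds")
})

test_that("GF_prior is the gated baseline maximum (or a configured quantile)", {
  base <- make_event_table(fsc = c(10, 10, 10), red = c(5, 5, 5),
                           green = c(1.2, 3.4, 9.9), timepoint = "baseline")
  g <- gate_spec("absolute", red_value = 1)
  expect_equal(gf_prior(base, g), 9.9)
  one <- make_event_table(fsc = 10, red = 5, green = 4.2,
                          timepoint = "baseline")
  expect_equal(gf_prior(one, g), 4.2)
  # order-statistics oracle: a 0.999 quantile sits below the maximum
  set.seed(6)
  big <- make_event_table(fsc = rep(10, 1e5), red = rep(5, 1e5),
                          green = rlnorm(1e5), timepoint = "baseline")
  expect_lt(gf_prior(big, g, policy = "quantile", q = 0.999),
            gf_prior(big, g, policy = "max"))
})

test_that("per_fed counts strict exceedances of GF_prior", {
  green <- c(rep(2, 150), rep(8, 50))
  tab <- make_event_table(fsc = rep(10, 200), red = rep(5, 200), green = green)
  g <- gate_spec("absolute", red_value = 1)
  pf <- per_fed(tab, g, gf_prior = 5)
  expect_identical(pf$cells_total, 200L)
  expect_identical(pf$cells_fed, 50L)
  expect_equal(pf$per_fed, 25)
  # ties do not count as fed; nothing above threshold gives zero
  expect_identical(per_fed(tab, g, gf_prior = 8)$cells_fed, 0L)
})

test_that("per_delta is the t3 - t0 difference and may be negative", {
  expect_equal(per_delta(c(t0 = 5, t1 = 10, t2 = 20, t3 = 30)), 25)
  expect_equal(per_delta(c(t0 = 12, t3 = 12)), 0)
  expect_equal(per_delta(c(t0 = 6, t3 = 2.5)), -3.5)
  expect_error(per_delta(c(t0 = 5, t2 = 8)), "t3")
})

test_that("FLB stability testing flags shifted and degenerate inputs", {
  set.seed(9)
  flb0 <- make_event_table(fsc = rep(10, 1000), red = rep(1, 1000),
                           green = rlnorm(1000, log(300), 0.3))
  same <- flb_stability(flb0, flb0)
  expect_equal(same$p, 1)
  expect_true(same$stable)
  flb3 <- flb0; flb3$green <- flb3$green * 3
  class(flb3) <- class(flb0)
  shifted <- flb_stability(flb0, flb3)
  expect_false(shifted$stable)
  expect_true(shifted$p >= 0 && shifted$p <= 1)
  const <- make_event_table(fsc = c(1, 1), red = c(1, 1), green = c(2, 2))
  expect_true(flb_stability(const, const)$degenerate)
})

test_that("per_fed increases with the planted fed fraction", {
  mean_delta <- vapply(c(0, 0.2, 0.4, 0.6), function(f) {
    deltas <- vapply(1:5, function(s) {
      cfg <- facs_config(n_algal_events = 2000L, n_flb_events = 2000L,
                         treatments = "CT", replicates = 1L,
                         f_max = f, rate = 10, seed = 100 + s)
      feeding_results(generate_facs_run(cfg))$per_delta
    }, numeric(1))
    mean(deltas)
  }, numeric(1))
  expect_true(all(diff(mean_delta) > 0))
})

test_that("feeding_results assembles GF_prior, the per_fed series and per_delta", {
  cfg <- facs_config(n_algal_events = 1500L, n_flb_events = 1500L,
                     f_max = 0.5, rate = 10, seed = 11)
  run <- generate_facs_run(cfg, strain = "P_parkeae", nutrient = "limited")
  res <- feeding_results(run)
  expect_s3_class(res, "feeding_result")
  expect_identical(nrow(res), 9L)    # 3 treatments x 3 replicates
  expect_true(all(c("gf_prior", "per_fed_t0", "per_fed_t3", "per_delta")
                  %in% names(res)))
  expect_true(all(res$per_fed_t0 >= 0 & res$per_fed_t0 <= 100))
  ct <- res$treatment == "CT"
  expect_gt(mean(res$per_delta[ct]), 30)
  expect_lt(max(abs(res$per_delta[res$treatment == "CT_PFA"])), 5)
  s <- summarize_feeding(res)
  expect_identical(nrow(s), 3L)
  expect_identical(s$n, c(3L, 3L, 3L))
})
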