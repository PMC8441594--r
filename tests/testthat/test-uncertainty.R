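spec_row <- function(name) {
  s <- parameter_specs()
  s[s$name == name, , drop = FALSE]
}

test_that("method-of-moments fits match hand-derived hyperparameters", {
  g <- fit_distribution(spec_row("c_event"))
  expect_equal(unname(g$pars["shape"]), 61.46, tolerance = 1e-3)
  expect_equal(unname(g$pars["scale"]), 28.19, tolerance = 1e-3)

  b <- fit_distribution(spec_row("u_high"))
  ab <- sum(b$pars)
  expect_equal(ab, 14.72, tolerance = 1e-3)
  expect_equal(unname(b$pars["alpha"]), 11.72, tolerance = 1e-3)

  ln <- fit_distribution(spec_row("rr_intervention"))
  expect_equal(unname(ln$pars["mu"]), log(0.88))
  expect_equal(unname(ln$pars["sigma"]), 0.05757, tolerance = 1e-3)

  tri <- fit_distribution(spec_row("p_cvd_fatal"))
  expect_equal(unname(tri$pars), c(0.26, 0.30, 0.33))

  expect_error(fit_distribution(spec_row("discount_rate")), "no sampling")
})

test_that("a negative decrement fits on its magnitude and draws negative", {
  d <- fit_distribution(spec_row("du_event"))
  expect_true(d$negate)
  expect_equal(distribution_mean(d), -0.2775, tolerance = 0.01 * 0.2775)
  x <- withr::with_seed(5, draw_distribution(d, 1000))
  expect_true(all(x < 0 & x > -1))
})

test_that("fitted distributions centre on the base case and sample true", {
  specs <- parameter_specs()
  specs <- specs[specs$in_psa, ]
  for (i in seq_len(nrow(specs))) {
    d <- fit_distribution(specs[i, ])
    if (d$family != "triangular")
      expect_lt(abs(distribution_mean(d) - specs$base[i]) /
                  abs(specs$base[i]), 0.01)
    x <- withr::with_seed(100 + i, draw_distribution(d, 1e5))
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - distribution_mean(d)), 3 * se)
  }
})

test_that("tornado entries respond monotonically and sort by spread", {
  cfg <- default_config()
  lt <- default_lt()
  tor <- one_way_sensitivity(cfg, lt)
  expect_true(all(diff(tor$spread) <= 0))
  expect_setequal(tor$parameter,
                  cfg$specs$name[cfg$specs$in_oneway])
  # programme cost raises only the intervention arm's cost
  cp <- tor[tor$parameter == "c_program", ]
  expect_gt(cp$icer_at_high, cp$icer_at_low)
  # the health-service costs and the RR dominate the tornado
  expect_true(all(c("c_hs_intervention", "c_hs_control", "rr_intervention")
                  %in% tor$parameter[1:5]))
  # a collapsed range contributes zero spread and sorts last
  cfg2 <- cfg
  i <- cfg2$specs$name == "c_event"
  cfg2$specs$low[i] <- cfg2$specs$high[i] <- cfg2$specs$base[i]
  tor2 <- one_way_sensitivity(cfg2, lt)
  expect_equal(tor2$spread[tor2$parameter == "c_event"], 0)
  expect_equal(tor2$parameter[nrow(tor2)], "c_event")
  # both tornado ends at base reproduce the deterministic base-case ICER;
  # the relative-risk row is exempt because its spec base is the quoted
  # 0.88 while the model carries the SBP-derived value at full precision
  cfg3 <- cfg
  cfg3$specs$low <- cfg3$specs$high <- cfg3$specs$base
  tor3 <- one_way_sensitivity(cfg3, lt)
  keep <- tor3$parameter != "rr_intervention"
  expect_equal(tor3$icer_at_low[keep],
               rep(tor3$icer_base[1], sum(keep)))
  expect_equal(tor3$icer_at_high, tor3$icer_at_low)
})

test_that("PSA is seed-reproducible and centred on the deterministic case", {
  cfg <- default_config()
  lt <- default_lt()
  a <- run_psa(cfg, lt, n_iter = 40, seed = 9)
  b <- run_psa(cfg, lt, n_iter = 40, seed = 9)
  expect_identical(a$draws, b$draws)
  c <- run_psa(cfg, lt, n_iter = 40, seed = 10)
  expect_false(identical(a$draws$delta_cost, c$draws$delta_cost))
  # all drawn parameters respect hard bounds after redraws
  pd <- a$param_draws
  expect_true(all(pd[, "rr_intervention"] <= 1 & pd[, "rr_intervention"] > 0))
  expect_true(all(pd[, c("u_high", "u_low", "prop_high")] <= 1))
  expect_true(all(pd[, "du_event"] < 0 & pd[, "du_event"] > -1))

  psa <- run_psa(cfg, lt, n_iter = 200, seed = 31)
  det <- run_scenario(cfg, "intermediate", lt)$comparison
  se <- stats::sd(psa$draws$delta_cost) / sqrt(psa$iterations)
  expect_lt(abs(mean(psa$draws$delta_cost) - det$delta_cost), 3 * se)
})

test_that("CEAC reduces to its analytic limits and steps at the ICER", {
  cfg <- default_config()
  psa <- run_psa(cfg, default_lt(), n_iter = 200, seed = 31)
  cc <- compute_ceac(psa, c(0, 1e9))
  expect_equal(cc$probability_cost_effective[1],
               mean(psa$draws$delta_cost < 0))
  expect_equal(cc$probability_cost_effective[2],
               mean(psa$draws$delta_qaly > 0))
  expect_true(all(cc$probability_cost_effective >= 0 &
                  cc$probability_cost_effective <= 1))
  # degenerate PSA at the base case: a step function at the base ICER
  base <- structure(list(iterations = 50, seed = 1,
                         draws = data.frame(iteration = 1:50,
                                            delta_cost = 623.01,
                                            delta_qaly = 0.12697)),
                    class = "psa_result")
  icer <- 623.01 / 0.12697
  step <- compute_ceac(base, c(icer - 1, icer + 1))
  expect_equal(step$probability_cost_effective, c(0, 1))
  expect_error(compute_ceac(psa, numeric(0)), "nonempty")
})
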