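test_that("biomass equivalents and monetary values reproduce the worked arithmetic", {
  econ <- economic_assumptions()  # 4444 plants/ha, 70 per tonne
  # delaying flowering 44 d at 2.2 g dry matter per plant per day
  t_flower <- biomass_equivalent(44, 2.2, econ)
  expect_equal(round(t_flower, 2), 0.43)
  expect_equal(round(monetary_value(t_flower, econ)), 30)
  # 5-point lignin reduction at 180 g per plant per point
  t_lignin <- biomass_equivalent(5, 180, econ)
  expect_equal(round(t_lignin, 1), 4.0)
  expect_equal(round(monetary_value(t_lignin, econ)), 280)
  # 5-point cellulose increase at 72 g per plant per point
  expect_equal(round(monetary_value(biomass_equivalent(5, 72, econ))), 112)
  expect_identical(biomass_equivalent(0, 123, econ), 0)
  expect_identical(monetary_value(0, econ), 0)
})

test_that("monetization is linear in delta, ratio, density and price", {
  econ <- economic_assumptions()
  base <- monetary_value(biomass_equivalent(3, 7, econ), econ)
  expect_equal(monetary_value(biomass_equivalent(6, 7, econ), econ), 2 * base)
  expect_equal(monetary_value(biomass_equivalent(3, 14, econ), econ), 2 * base)
  econ2 <- economic_assumptions(density = 2 * 4444)
  expect_equal(monetary_value(biomass_equivalent(3, 7, econ2), econ2), 2 * base)
  econ3 <- economic_assumptions(price = 140)
  expect_equal(monetary_value(biomass_equivalent(3, 7, econ3), econ3), 2 * base)
  expect_error(economic_assumptions(density = 0), "positive")
  expect_error(economic_assumptions(price = -1), "non-negative")
})

test_that("run_scenario composes the stages correctly on the identity case", {
  ip <- identity_params(2L)
  s <- scenario("T", data.frame(trait = "t1", value = 2, mode = "absolute"))
  rep1 <- run_scenario(ip$panel, ip$params, s)
  expect_equal(unname(rep1$solution$b), c(2, 0))
  expect_equal(unname(rep1$solution$Q_star), c(2, 0))
  expect_equal(rep1$solution$sigma_I, 2)
  expect_equal(rep1$solution$p, fraction_from_intensity(2), tolerance = 1e-9)
  expect_equal(rep1$table$delta, c(2, 0))
  expect_equal(rep1$table$pct_change, c(200, 0))  # means are 1
  expect_equal(rep1$table$econ_ratio, c(1, 0))    # a = b when G = P
})

test_that("run_scenario is deterministic and labels stage failures", {
  rp <- random_params(5L, seed = 77)
  s <- scenario("D", data.frame(trait = c("t1", "t3"), value = c(1, -0.5),
                                mode = "absolute"))
  r1 <- run_scenario(rp$panel, rp$params, s)
  r2 <- run_scenario(rp$panel, rp$params, s)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$solution, r2$solution)

  bad <- scenario("B", data.frame(trait = "nope", value = 1,
                                  mode = "absolute"))
  expect_error(run_scenario(rp$panel, rp$params, bad),
               "\\[absolute_gains\\]")
})

test_that("refining a scenario appends zero-gain constraints and stars the name", {
  s1 <- scenario("S1", data.frame(trait = c("DryMatter", "DOYFS1"),
                                  value = c(20, 44),
                                  mode = c("percent", "absolute")))
  s1s <- refine_scenario(s1, "Moisture")
  expect_identical(s1s$name, "S1*")
  expect_identical(nrow(s1s$gains), 3L)
  expect_identical(s1s$gains$value[s1s$gains$trait == "Moisture"], 0)
  expect_identical(nrow(s1$gains), 2L)  # original untouched
  expect_identical(refine_scenario(s1, character(0)), s1)
  expect_error(refine_scenario(s1, "DryMatter"), "nonzero")
})

test_that("held traits show zero response in a refined scenario's own report", {
  rp <- random_params(6L, seed = 123)
  s <- scenario("S", data.frame(trait = c("t1", "t2"), value = c(1, -2),
                                mode = "absolute"))
  s_star <- refine_scenario(s, c("t4", "t6"))
  r <- run_scenario(rp$panel, rp$params, s_star)
  expect_equal(r$table$delta[rp$panel$name %in% c("t4", "t6")], c(0, 0),
               tolerance = 1e-8)
  expect_equal(r$table$delta[1:2], c(1, -2), tolerance = 1e-8)
})

test_that("scenario comparison aligns traits and flags sign flips", {
  rp <- random_params(4L, seed = 5)
  sA <- scenario("A", data.frame(trait = "t1", value = 1, mode = "absolute"))
  rA <- run_scenario(rp$panel, rp$params, sA)
  cmp_same <- compare_scenarios(rA, rA)
  expect_false(any(cmp_same$sign_flip))  # identical reports cannot flip

  ip <- identity_params(2L)
  s1 <- scenario("up", data.frame(trait = "t1", value = 1, mode = "absolute"))
  s2 <- scenario("dn", data.frame(trait = "t1", value = -1, mode = "absolute"))
  cmp <- compare_scenarios(run_scenario(ip$panel, ip$params, s1),
                           run_scenario(ip$panel, ip$params, s2))
  expect_equal(cmp$delta_up, c(1, 0))
  expect_equal(cmp$delta_dn, c(-1, 0))
  expect_identical(cmp$sign_flip, c(TRUE, FALSE))

  other <- identity_params(3L)
  expect_error(compare_scenarios(run_scenario(ip$panel, ip$params, s1),
                                 run_scenario(other$panel, other$params,
                                              scenario("x", c(t1 = 1)))),
               "panel mismatch")
})

test_that("explicit-delta monetization decouples the valued change from the target", {
  ip <- identity_params(2L, reference = "t2")
  r <- run_scenario(ip$panel, ip$params,
                    refine_scenario(scenario("T0", c(t2 = 1)), "t1"))
  m <- monetize_trait(r, "t1", delta = 1)
  expect_equal(m$tonnes_per_ha,
               biomass_equivalent(1, m$econ_ratio, r$econ))
  expect_error(monetize_trait(r, "zz", 1), "unknown trait")
})
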