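test_that("livestock table validation and 2050 baseline scaling", {
  tab <- livestock_table(
    c("tmr", "extensive"), c("high", "low"), c(10, 5)
  )
  expect_identical(baseline_2050(tab, 1.0)$mt_ch4_2010, tab$mt_ch4_2010)
  scaled <- baseline_2050(tab, 1.3)
  expect_equal(scaled$mt_ch4_2010, c(13, 6.5))
  expect_equal(sum(scaled$mt_ch4_2010), 1.3 * sum(tab$mt_ch4_2010))
  expect_error(
    livestock_table(c("tmr", "tmr"), c("high", "high"), c(1, 2)),
    "unique"
  )
  expect_error(livestock_table("tmr", "high", -1), ">= 0")
})

test_that("mitigation potential is the adoption x efficacy sum over applicable cells", {
  tab <- livestock_table(
    c("tmr", "extensive"), c("high", "low"), c(3, 7)
  )
  # zero adoption -> zero potential
  none <- intervention("none", c("tmr", "extensive"), c("high", "low"),
    efficacy = 0.2, adoption = 0
  )
  expect_equal(mitigation_potential(tab, none), 0)
  # hand-summed toy case: 1.3 * (3*0.2*1 + 7*0.2*0.5) = 1.69
  iv <- intervention("toy", c("tmr", "extensive"), c("high", "low"),
    efficacy = 0.2, adoption = c(high = 1.0, low = 0.5), growth = 1.3
  )
  expect_equal(mitigation_potential(tab, iv), 1.69)
  # adoption for an inapplicable group warns and is ignored
  expect_warning(
    iv2 <- intervention("warned", "tmr", "high",
      efficacy = 0.3, adoption = c(high = 1, low = 0.4)
    ),
    "inapplicable"
  )
  expect_equal(mitigation_potential(tab, iv2), 3 * 1.3 * 0.3)
})

test_that("the calibrated fixture reproduces the TMR-inhibitor potential of 0.8 Mt", {
  tab <- read_livestock_table()
  ivs <- read_interventions()
  expect_equal(mitigation_potential(tab, ivs$inhibitor_tmr), 0.8, tolerance = 1e-12)
  # the synthetic table totals the scenario 2010 livestock level (~112.9 Mt)
  expect_equal(sum(tab$mt_ch4_2010), 112.9, tolerance = 1e-3)
  # every bundled potential respects the growth x baseline cap
  for (iv in ivs) {
    pot <- mitigation_potential(tab, iv)
    applicable <- tab$system %in% iv$systems & tab$income_group %in% iv$income_groups
    expect_lte(pot, iv$growth * sum(tab$mt_ch4_2010[applicable]))
    expect_gte(pot, 0)
  }
})

test_that("potential is monotone in efficacy, adoption and emissions", {
  tab <- livestock_table(
    c("intensive_grazing", "extensive"), c("high", "low"), c(20, 30)
  )
  base <- intervention("m", c("intensive_grazing", "extensive"), c("high", "low"),
    efficacy = 0.2, adoption = 0.5
  )
  p0 <- mitigation_potential(tab, base)
  more_eff <- intervention("m", c("intensive_grazing", "extensive"), c("high", "low"),
    efficacy = 0.4, adoption = 0.5
  )
  more_adopt <- intervention("m", c("intensive_grazing", "extensive"), c("high", "low"),
    efficacy = 0.2, adoption = 0.9
  )
  tab2 <- tab
  tab2$mt_ch4_2010 <- tab2$mt_ch4_2010 + 5
  expect_gt(mitigation_potential(tab, more_eff), p0)
  expect_gt(mitigation_potential(tab, more_adopt), p0)
  expect_gt(mitigation_potential(tab2, base), p0)
})

test_that("the mitigation wedge ramps linearly and clips at zero", {
  expect_identical(apply_to_pathway(bau_ch4, 0)$values, bau_ch4$values)
  w <- apply_to_pathway(bau_ch4, 10, ramp_start = 2025, full_year = 2050)
  expect_equal(pathway_value(w, 2050), pathway_value(bau_ch4, 2050) - 10)
  expect_equal(pathway_value(w, 2100), pathway_value(bau_ch4, 2100) - 10)
  # mid-ramp years carry the linearly interpolated wedge
  expect_equal(
    pathway_value(w, 2037) + pathway_value(w, 2038),
    pathway_value(bau_ch4, 2037) + pathway_value(bau_ch4, 2038) - 10
  )
  expect_identical(w$values[w$years <= 2025], bau_ch4$values[bau_ch4$years <= 2025])
  expect_warning(big <- apply_to_pathway(bau_ch4, 500), "clipping")
  expect_true(all(big$values >= 0))
})
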