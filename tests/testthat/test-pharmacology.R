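# Drug regimens, transporter modulation, transmitter levels.

test_that("effective transporter efficacy composes blockades multiplicatively", {
  expect_equal(effective_transporter(0.7), 0.7)
  expect_equal(effective_transporter(0.7, 1), 0)
  expect_equal(effective_transporter(0.8, 0.5), 0.4)
  expect_equal(effective_transporter(0.9, c(0.5, 0.5)), 0.225)
  expect_error(effective_transporter(1.2), "\\[0, 1\\]")
  expect_error(effective_transporter(0.5, -0.1), "\\[0, 1\\]")
  # monotone non-increasing in each blockade magnitude
  taus <- effective_transporter(0.8, 0.3)
  for (b in seq(0.3, 1, by = 0.1)) {
    t2 <- effective_transporter(0.8, b)
    expect_lte(t2, taus)
    taus <- t2
  }
})

test_that("presented amounts follow the release/reuptake/releaser formula", {
  ps <- ref_params()
  # gal/glu/CRF pass through unchanged
  expect_equal(presented_amount(0.37, "gal", ps), 0.37)
  expect_equal(presented_amount(0.37, "CRF", ps, regimen("esc")), 0.37)
  expect_equal(presented_amount(0, "5HT", ps), 0)
  # hand evaluation: tau 0.5, full blockade -> amount = activity
  p2 <- ps
  p2$transporters[["5HT"]] <- 0.5
  p2$drug_magnitudes[["esc.SERT"]] <- 1.0
  expect_equal(presented_amount(0.4, "5HT", p2, regimen("esc")), 0.4)
  # no drug: activity * (1 - tau)
  expect_equal(presented_amount(0.4, "5HT", p2), 0.4 * 0.5)
  expect_error(presented_amount(0.4, "ACh", ps), "unknown transmitter")
  # releaser adds pre-reuptake
  pb <- ps
  pb$transporters[["NE"]] <- 0.5
  m <- pb$drug_magnitudes[["bup.NE"]]
  expect_equal(presented_amount(0.2, "NE", pb, regimen("bup")), (0.2 + m) * 0.5)
})

test_that("blocking reuptake never decreases the presented monoamine amount", {
  ps <- ref_params()
  prev <- -Inf
  for (b in seq(0, 1, by = 0.125)) {
    p <- ps
    p$drug_magnitudes[["esc.SERT"]] <- b
    amt <- presented_amount(0.4, "5HT", p, regimen("esc"))
    expect_gte(amt, prev)
    prev <- amt
  }
})

test_that("receptor drives apply polarity, strength, antagonism, and agonism", {
  ps <- ref_params()
  ps$receptors[["DR.5HT1AR"]] <- 3
  # polarity -1, strength 3, amount 0.5, no drug -> -1.5
  expect_equal(receptor_drive("DR", "5HT1AR", 0.5, ps), -1.5)
  # full antagonist blocks the transmitter-bound term
  p2 <- ps
  p2$drug_magnitudes[["trz.DR.5HT1AR"]] <- 1.0
  p2$drug_magnitudes[["trz.SERT"]] <- 0
  p2$drug_magnitudes[["trz.LC.AR2"]] <- 0
  p2$drug_magnitudes[["trz.VTA.AR2"]] <- 0
  expect_equal(receptor_drive("DR", "5HT1AR", 0.5, p2, regimen("trz")), 0)
  # agonist adds polarity * strength * magnitude at zero transmitter
  p3 <- ps
  p3$receptors[["DR.D2R"]] <- 2
  p3$drug_magnitudes[["arp.DR.D2R.ago"]] <- 0.2
  p3$drug_magnitudes[["arp.DR.D2R.ant"]] <- 0
  for (id in grep("^arp\\.(LC|VTA)", names(p3$drug_magnitudes), value = TRUE)) {
    p3$drug_magnitudes[[id]] <- 0
  }
  expect_equal(receptor_drive("DR", "D2R", 0, p3, regimen("arp")), +0.4)
  expect_error(receptor_drive("DR", "NOPE", 0.1, ps), "unknown receptor site")
})

test_that("transmitter levels derive from DR/LC/VTA window averages", {
  ps <- ref_params()
  s <- ref_baseline()
  lv <- transmitter_levels(s, ps)
  tau <- ps$transporters
  expect_equal(lv[["5HT"]], s$means[["DR"]] * (1 - tau[["5HT"]]))
  expect_equal(lv[["NE"]], s$means[["LC"]] * (1 - tau[["NE"]]))
  expect_equal(lv[["DA"]], s$means[["VTA"]] * (1 - tau[["DA"]]))
  # zero activations give zero levels
  s0 <- s
  s0$means[] <- 0
  expect_equal(unname(transmitter_levels(s0, ps)), c(0, 0, 0))
})

test_that("percent of baseline is a guarded ratio", {
  expect_equal(percent_of_baseline(0.1, 0.1), 100)
  expect_equal(percent_of_baseline(0.42, 0.10), 420)
  expect_equal(percent_of_baseline(0, 0.1), 0)
  expect_error(percent_of_baseline(0.1, 0), "positive")
})

test_that("the empty regimen equals the drug-free pipeline and combinations commute", {
  ps <- ref_params()
  tr0 <- simulate_network(ps)
  tr_empty <- simulate_network(ps, regimen())
  expect_identical(tr0$activities, tr_empty$activities)
  ab <- simulate_network(ps, regimen("esc", "arp"))
  ba <- simulate_network(ps, regimen("arp", "esc"))
  expect_identical(ab$activities, ba$activities)
  alias <- simulate_network(ps, regimen("EsArp"))
  expect_identical(ab$activities, alias$activities)
})

test_that("regimens reject unknown drugs and more than two drugs", {
  expect_error(regimen("nosuchdrug"), "unknown drug")
  expect_error(regimen("esc", "reb", "bup"), "at most two")
})
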