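# Calibration: error functions, GA optimization, screening.

test_that("activation error is the monoaminergic L1 seminorm", {
  s <- ref_baseline()
  expect_equal(activation_error(s, s), 0)
  s2 <- s
  s2$means[["DR"]] <- s$means[["DR"]] + 0.1
  expect_equal(activation_error(s2, s), 0.1)
  s3 <- s
  s3$means[c("DR", "LC", "VTA")] <- s$means[c("DR", "LC", "VTA")] + c(0.05, -0.02, 0.03)
  expect_equal(activation_error(s3, s), 0.10)
  # symmetric; ignores non-monoaminergic units
  expect_equal(activation_error(s, s3), activation_error(s3, s))
  s4 <- s
  s4$means[["Tgal"]] <- 0.99
  expect_equal(activation_error(s4, s), 0)
})

test_that("self-generated targets give zero error; single residuals follow the RMS rule", {
  ps <- ref_params()
  targets <- make_calibration_targets(ps, regimens = c("esc", "reb"))
  expect_equal(calibration_error(ps, targets), 0)
  # one residual r among k rows -> |r| / sqrt(k)
  t2 <- targets
  t2$value[3] <- t2$value[3] + 4
  expect_equal(calibration_error(ps, t2), 4 / sqrt(nrow(t2)))
  expect_error(calibration_error(ps, targets[0, ]), "empty")
  t3 <- targets
  t3$regimen[1] <- "ghost"
  expect_error(calibration_error(ps, t3), "unknown drug|unresolvable")
})

test_that("calibration error matches an independent two-pass recomputation", {
  ps <- ref_params()
  targets <- make_calibration_targets(ps, regimens = c("esc", "bup"))
  perturbed <- ps
  perturbed$receptors[["DR.5HT1AR"]] <- 2.0
  perturbed$transporters[["DA"]] <- 0.6
  got <- calibration_error(perturbed, targets)
  # oracle: naive loop, one simulation per row, window means by loop
  base_tr <- simulate_network(perturbed)
  base <- naive_window_mean(base_tr, 75, 150)
  ss <- 0
  for (i in seq_len(nrow(targets))) {
    rg <- targets$regimen[i]
    reg_obj <- if (rg == "none") regimen() else regimen(rg)
    m <- naive_window_mean(simulate_network(perturbed, reg_obj), 75, 150)
    model <- switch(targets$metric[i],
      pct_change = 100 * (m[[targets$unit[i]]] - base[[targets$unit[i]]]) /
        base[[targets$unit[i]]],
      baseline_activation = base[[targets$unit[i]]],
      level = {
        su <- structure(list(means = m, window = c(75, 150)), class = "activation_summary")
        transmitter_levels(su, perturbed, reg_obj)[[targets$unit[i]]]
      })
    ss <- ss + (model - targets$value[i])^2
  }
  expect_equal(got, sqrt(ss / nrow(targets)), tolerance = 1e-12)
})

test_that("GA runs are seed-reproducible and ranked ascending", {
  ps <- ref_params()
  targets <- make_calibration_targets(ps, regimens = "esc")
  free <- c("R.DR.5HT1AR", "D.esc.SERT")
  cfg <- ga_config(population = 20, max_generations = 15, restarts = 3, seed = 99)
  r1 <- calibrate_params(ps, targets, free = free, cfg = cfg)
  r2 <- calibrate_params(ps, targets, free = free, cfg = cfg)
  e1 <- vapply(r1$fits, `[[`, numeric(1), "error")
  e2 <- vapply(r2$fits, `[[`, numeric(1), "error")
  expect_identical(e1, e2)
  expect_identical(flatten_params(r1$fits[[1]]$params), flatten_params(r2$fits[[1]]$params))
  expect_true(all(diff(e1) >= 0))
  # more restarts can only improve the best error (shared restart seeds)
  cfg5 <- ga_config(population = 20, max_generations = 15, restarts = 5, seed = 99)
  r5 <- calibrate_params(ps, targets, free = free, cfg = cfg5)
  expect_lte(r5$fits[[1]]$error, r1$fits[[1]]$error)
})

test_that("the GA recovers two free parameters of a truth-generated fixture", {
  ps <- ref_params()
  targets <- make_calibration_targets(ps, regimens = "esc")
  res <- calibrate_params(
    ps, targets, free = c("R.DR.5HT1AR", "D.esc.SERT"),
    cfg = ga_config(population = 40, max_generations = 120, restarts = 1, seed = 3)
  )
  expect_lt(res$fits[[1]]$error, 1e-3)
})

test_that("screening diagnostics report offset and amplitude shifts", {
  ps <- ref_params()
  scr <- screen_parameterization(ps, receptors = c("DR.5HT1AR", "LC.AR2"))
  expect_identical(scr$diagnostics$receptor, c("DR.5HT1AR", "LC.AR2"))
  expect_true(all(is.finite(scr$diagnostics$offset_shift)))
  expect_true(all(is.finite(scr$diagnostics$amplitude_shift)))
  # the reference fixture is offset-dominant for the autoreceptors
  expect_false(scr$amplitude_dominant)
})

test_that("screening shifts match an independently stepped before/after simulation", {
  toy <- make_toy_model(n_units = 2)
  ps <- toy$params
  scr <- screen_parameterization(ps, receptors = "DR.galR1")
  # oracle: iterate step_network() by hand before and after the decrement
  run <- function(p) {
    x <- stats::setNames(rep(0, 6), mono_units())
    out <- matrix(NA_real_, 150, 6, dimnames = list(NULL, mono_units()))
    for (t in 1:150) {
      x <- step_network(x, p)
      out[t, ] <- x
    }
    out[75:150, c("DR", "LC", "VTA"), drop = FALSE]
  }
  w1 <- run(ps)
  p2 <- ps
  p2$receptors[["DR.galR1"]] <- p2$receptors[["DR.galR1"]] - 1
  w2 <- run(p2)
  off <- max(abs(colMeans(w2) - colMeans(w1)))
  amp <- max(abs(apply(w2, 2, function(v) max(v) - min(v)) -
                 apply(w1, 2, function(v) max(v) - min(v))))
  expect_equal(scr$diagnostics$offset_shift, off, tolerance = 1e-6)
  expect_equal(scr$diagnostics$amplitude_shift, amp, tolerance = 1e-6)
  # a no-op probe (strength already 0 stays 0) yields zero shifts
  p0 <- ps
  p0$receptors[["VTA.AMPAR"]] <- 0
  scr0 <- screen_parameterization(p0, receptors = "VTA.AMPAR")
  expect_equal(scr0$diagnostics$offset_shift, 0)
  expect_equal(scr0$diagnostics$amplitude_shift, 0)
})

test_that("targets CSV round-trips", {
  targets <- make_calibration_targets(ref_params(), regimens = "esc")
  path <- withr::local_tempfile(fileext = ".csv")
  write_targets_csv(targets, path)
  t2 <- read_targets_csv(path)
  expect_equal(as.data.frame(t2), as.data.frame(targets), tolerance = 1e-12)
})
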