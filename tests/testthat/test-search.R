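# Exhaustive adjustment-tree elaboration, classification, reporting.

test_that("reduced-model trees match the brute-force nested-loop oracle node-for-node", {
  toy <- make_toy_model(n_adjustable = 2, n_units = 6)
  ps <- toy$params
  ps$receptors[toy$adjustable] <- 5
  nodes <- enumerate_tree(ps, regimen("esc"), depth = 2, receptors = toy$adjustable)
  got <- sort(paste0(nodes$level, ":", nodes$key))
  expect_identical(got, oracle_sequences(ps, toy$adjustable, 2))
  # interior start with 2 adjustable receptors: 4 moves per level
  expect_equal(as.vector(table(nodes$level)), c(1, 4, 16))
  # three receptors, depth 3
  toy3 <- make_toy_model(n_adjustable = 3, n_units = 6)
  ps3 <- toy3$params
  ps3$receptors[toy3$adjustable] <- 5
  nodes3 <- enumerate_tree(ps3, regimen("reb"), depth = 3, receptors = toy3$adjustable)
  expect_identical(sort(paste0(nodes3$level, ":", nodes3$key)),
                   oracle_sequences(ps3, toy3$adjustable, 3))
  expect_equal(as.vector(table(nodes3$level)), c(1, 6, 36, 216))
})

test_that("trees starting at a bound lose the blocked branches", {
  toy <- make_toy_model(n_adjustable = 2, n_units = 6)
  ps <- toy$params
  ps$receptors[toy$adjustable] <- c(10, 5)
  nodes <- enumerate_tree(ps, regimen("esc"), depth = 1, receptors = toy$adjustable)
  expect_equal(sum(nodes$level == 1), 3)  # one increase blocked
  expect_identical(sort(paste0(nodes$level, ":", nodes$key)),
                   oracle_sequences(ps, toy$adjustable, 1))
})

test_that("the resource cap rejects oversized trees", {
  ps <- ref_params()
  expect_error(enumerate_tree(ps, regimen("esc"), depth = 5, max_nodes = 1e4),
               "max_nodes")
  expect_error(enumerate_tree(ps, regimen("esc"), depth = 0), "depth")
})

test_that("the adapted threshold is the minimum level-1 error and labeling is strict", {
  fake <- data.frame(
    level = c(0L, 1L, 1L, 1L, 2L, 2L, 3L, 3L),
    key = as.character(1:8),
    path = "",
    error = c(0.9, 0.3, 0.2, 0.5, 0.2, 0.19, 0.05, 0.6),
    pct_5HT = 100, pct_NE = 100, pct_DA = 100
  )
  thr <- adapted_threshold(fake)
  expect_equal(thr, 0.2)
  lab <- classify_adapted(fake)
  # oracle: linear scan with the strict rule
  expect_identical(lab$adapted,
                   fake$level >= 2 & fake$error < min(fake$error[fake$level == 1]))
  # a node exactly at the threshold is NOT adapted; level-1 nodes never are
  expect_false(lab$adapted[5])  # error 0.2 == threshold
  expect_true(lab$adapted[6])
  expect_false(any(lab$adapted[lab$level <= 1]))
  expect_error(adapted_threshold(fake[fake$level != 1, ]), "level-1")
  # all level-1 errors equal -> that value
  f2 <- fake
  f2$error[f2$level == 1] <- 0.4
  expect_equal(adapted_threshold(f2), 0.4)
  # loosening the threshold never decreases the adapted count
  n1 <- sum(classify_adapted(fake, 0.2)$adapted)
  n2 <- sum(classify_adapted(fake, 0.5)$adapted)
  expect_gte(n2, n1)
})

test_that("therapeutic classification uses strict 400/200/200 percent cutoffs", {
  expect_identical(classify_therapeutic(c("5HT" = 422, "NE" = 100, "DA" = 100)), "5HT")
  expect_identical(classify_therapeutic(c("5HT" = 100, "NE" = 212, "DA" = 100)), "NE")
  expect_identical(classify_therapeutic(c("5HT" = 100, "NE" = 100, "DA" = 140)), character())
  expect_identical(classify_therapeutic(c("5HT" = 400, "NE" = 200, "DA" = 200)), character())
  expect_identical(classify_therapeutic(c("5HT" = 401, "NE" = 201, "DA" = 201)),
                   c("5HT", "NE", "DA"))
})

test_that("report tallies match an independent recount and respect subset monotonicity", {
  toy <- make_toy_model(n_adjustable = 3, n_units = 6)
  ps <- toy$params
  ps$receptors[toy$adjustable] <- 5
  nodes <- classify_adapted(enumerate_tree(ps, regimen("esc"), depth = 3,
                                           receptors = toy$adjustable))
  rep <- tabulate_report(nodes)
  # recount oracle over the node list
  ad <- nodes[nodes$adapted, ]
  for (i in seq_len(nrow(rep$combinations))) {
    amines <- strsplit(rep$combinations$combo[i], "/")[[1]]
    cnt <- 0
    for (j in seq_len(nrow(ad))) {
      hit <- classify_therapeutic(c("5HT" = ad$pct_5HT[j], "NE" = ad$pct_NE[j],
                                    "DA" = ad$pct_DA[j]))
      if (all(amines %in% hit)) cnt <- cnt + 1
    }
    expect_equal(rep$combinations$count[i], cnt)
  }
  cmb <- function(x) rep$combinations$count[rep$combinations$combo == x]
  expect_lte(cmb("5HT/DA/NE"), cmb("5HT/DA"))
  expect_lte(cmb("5HT/DA"), cmb("5HT"))
  expect_lte(cmb("5HT/DA/NE"), cmb("DA/NE"))
  # percentages are count / adapted * 100
  if (rep$adapted_sequences > 0) {
    expect_equal(rep$combinations$pct,
                 100 * rep$combinations$count / rep$adapted_sequences)
  }
  # per-level sequence counts never exceed the analytic bound
  m <- 2 * length(toy$adjustable)
  expect_true(all(rep$levels$sequences <= m^rep$levels$level))
  expect_true(all(rep$levels$configurations <= rep$levels$sequences))
})

test_that("zero adapted nodes yield a zero report without division errors", {
  fake <- data.frame(
    level = c(0L, 1L, 1L, 2L), key = as.character(1:4), path = "",
    error = c(0.5, 0.3, 0.4, 0.9), pct_5HT = 500, pct_NE = 300, pct_DA = 300
  )
  rep <- tabulate_report(classify_adapted(fake))
  expect_equal(rep$adapted_sequences, 0)
  expect_true(all(rep$combinations$count == 0))
  expect_true(all(rep$combinations$pct == 0))
})

test_that("reports serialize to JSON and a drug-by-combination CSV table", {
  toy <- make_toy_model(n_adjustable = 2, n_units = 6)
  ps <- toy$params
  ps$receptors[toy$adjustable] <- 5
  rep1 <- tabulate_report(enumerate_tree(ps, regimen("esc"), depth = 2,
                                         receptors = toy$adjustable))
  jp <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep1, jp)
  back <- jsonlite::fromJSON(jp)
  expect_equal(back$adapted_sequences, rep1$adapted_sequences)
  cp <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(list(rep1), cp)
  tab <- read.csv(cp, check.names = FALSE)
  expect_identical(names(tab),
                   c("regimen", "adapted_states", "5HT", "DA", "NE",
                     "5HT/DA", "5HT/NE", "DA/NE", "5HT/DA/NE"))
  expect_equal(nrow(tab), 1)
})
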