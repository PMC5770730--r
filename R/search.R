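# Exhaustive elaboration of the receptor-adjustment tree.
#
# Starting from the calibrated configuration, every legal sequence of
# single receptor adjustments up to a depth (default 3) is enumerated
# breadth-first, whether or not each step reduces activation error --
# low-error configurations may be reachable only through higher-error
# ones. Each node carries the activation error and the three monoamine
# levels as percent of the no-drug baseline. Many sequences reach the
# same configuration, so node evaluation is memoized on the exact
# integer-delta identity.

#' Enumerate the receptor-adjustment tree
#'
#' @param params A calibrated `mono_params` object.
#' @param reg The maintained `mono_regimen`.
#' @param depth Maximum sequence length (`>= 1`, default 3).
#' @param receptors Adjustable subset (default: all 11).
#' @param T,window Simulation settings.
#' @param max_nodes Resource cap: an error is raised if the analytic
#'   sequence-count bound `sum((2 m)^l, l = 0..depth)` exceeds it.
#' @return A data.frame of class `config_nodes`, one row per adjustment
#'   sequence: `level`, `key` (integer-delta identity), `path`
#'   (";"-separated `receptor:direction` steps), `error`, and `pct_5HT`,
#'   `pct_NE`, `pct_DA` (percent of no-drug baseline). The root (level 0)
#'   carries the acute, unadapted error under the regimen. Attributes:
#'   `regimen`, `depth`, `receptors`, `baseline_levels`.
#' @export
enumerate_tree <- function(params, reg, depth = 3,
                           receptors = adjustable_receptors(),
                           T = 150, window = c(75, 150), max_nodes = 2e5) {
  if (depth < 1) stop("depth must be >= 1")
  m <- 2 * length(receptors)
  bound <- sum(m^(0:depth))
  if (bound > max_nodes) {
    stop(sprintf("sequence bound %d exceeds max_nodes = %d; raise max_nodes explicitly",
                 bound, max_nodes))
  }
  ev <- make_error_evaluator(params, reg, T, window)
  root <- receptor_configuration(params, receptors)
  node_row <- function(config, level, path) {
    res <- ev$evaluate(config)
    data.frame(
      level = level, key = config_key(config), path = path,
      error = res$error,
      pct_5HT = unname(res$levels_pct[["5HT"]]),
      pct_NE = unname(res$levels_pct[["NE"]]),
      pct_DA = unname(res$levels_pct[["DA"]]),
      stringsAsFactors = FALSE
    )
  }
  rows <- list(node_row(root, 0L, ""))
  frontier <- list(list(config = root, path = ""))
  for (lv in seq_len(depth)) {
    nxt <- vector("list", 0L)
    for (nd in frontier) {
      mv <- legal_moves(nd$config)
      for (i in seq_len(nrow(mv))) {
        child <- apply_adjustment(nd$config, mv$receptor[i], mv$direction[i])
        step <- sprintf("%s:%+d", mv$receptor[i], mv$direction[i])
        path <- if (nzchar(nd$path)) paste(nd$path, step, sep = ";") else step
        rows[[length(rows) + 1L]] <- node_row(child, lv, path)
        nxt[[length(nxt) + 1L]] <- list(config = child, path = path)
      }
    }
    frontier <- nxt
  }
  nodes <- do.call(rbind, rows)
  attr(nodes, "regimen") <- vapply(reg$drugs, `[[`, "", "name")
  attr(nodes, "depth") <- depth
  attr(nodes, "receptors") <- receptors
  attr(nodes, "baseline_levels") <- ev$baseline_levels
  class(nodes) <- c("config_nodes", "data.frame")
  nodes
}

#' Adapted-state error threshold
#'
#' The drug-specific criterion for calling a configuration adapted: the
#' minimum activation error among the level-1 nodes of its tree.
#'
#' @param nodes A `config_nodes` data.frame (or any data.frame with
#'   `level` and `error`).
#' @return The lowest level-1 error.
#' @export
adapted_threshold <- function(nodes) {
  e <- nodes$error[nodes$level == 1L]
  if (!length(e)) stop("no level-1 nodes: cannot set the adapted threshold")
  min(e)
}

#' Label adapted configurations
#'
#' A node is adapted iff its level is 2 or greater and its activation
#' error is strictly lower than the threshold (the lowest level-1 error).
#' Level-0 and level-1 nodes are never adapted.
#'
#' @param nodes A `config_nodes` data.frame.
#' @param threshold Error threshold (default: computed by
#'   [adapted_threshold()]).
#' @return `nodes` with a logical `adapted` column added.
#' @export
classify_adapted <- function(nodes, threshold = adapted_threshold(nodes)) {
  nodes$adapted <- nodes$level >= 2L & nodes$error < threshold
  attr(nodes, "threshold") <- threshold
  nodes
}

#' Therapeutic monoamine elevations
#'
#' A monoamine is therapeutically elevated when its level exceeds the
#' literature-anchored percent-of-baseline criterion: strictly above 400
#' for 5HT, strictly above 200 for NE and for DA.
#'
#' @param pct Named numeric vector (or 1-row slice) with elements
#'   `5HT`, `NE`, `DA` as percent of the no-drug baseline.
#' @return Character vector: the subset of `c("5HT", "NE", "DA")` that is
#'   therapeutically elevated.
#' @export
classify_therapeutic <- function(pct) {
  out <- character()
  if (pct[["5HT"]] > 400) out <- c(out, "5HT")
  if (pct[["NE"]] > 200) out <- c(out, "NE")
  if (pct[["DA"]] > 200) out <- c(out, "DA")
  out
}

# Table-style column order for monoamine combinations
therapeutic_combos <- function() {
  c("5HT", "DA", "NE", "5HT/DA", "5HT/NE", "DA/NE", "5HT/DA/NE")
}

#' Tabulate a search into an efficacy report
#'
#' Counts, over the adapted configurations, how many also show
#' therapeutic elevation of each monoamine combination (a combination
#' column counts nodes in which *all* of its listed monoamines are
#' elevated, whatever the others do), with percentages relative to the
#' adapted count. Reported both over raw adjustment sequences and over
#' deduplicated configurations (exact integer-delta identity).
#'
#' @param nodes A `config_nodes` data.frame, classified or not (the
#'   adapted labels are computed if absent).
#' @return An object of class `search_report`: regimen, depth,
#'   thresholds, per-level sequence and unique-configuration counts,
#'   adapted counts, and the 7-column combination table (`count`, `pct`,
#'   `count_dedup`, `pct_dedup`).
#' @export
tabulate_report <- function(nodes) {
  if (is.null(nodes$adapted)) nodes <- classify_adapted(nodes)
  threshold <- attr(nodes, "threshold")
  levels_tab <- do.call(rbind, lapply(sort(unique(nodes$level)), function(l) {
    sub <- nodes[nodes$level == l, ]
    data.frame(level = l, sequences = nrow(sub),
               configurations = length(unique(sub$key)))
  }))
  ad <- nodes[nodes$adapted, , drop = FALSE]
  ad_dd <- ad[!duplicated(ad$key), , drop = FALSE]
  elevated <- function(df, amines) {
    ok <- rep(TRUE, nrow(df))
    if ("5HT" %in% amines) ok <- ok & df$pct_5HT > 400
    if ("NE" %in% amines) ok <- ok & df$pct_NE > 200
    if ("DA" %in% amines) ok <- ok & df$pct_DA > 200
    sum(ok)
  }
  pct0 <- function(k, n) if (n > 0) 100 * k / n else 0
  combos <- therapeutic_combos()
  tab <- do.call(rbind, lapply(combos, function(cb) {
    amines <- strsplit(cb, "/")[[1]]
    k <- elevated(ad, amines)
    kd <- elevated(ad_dd, amines)
    data.frame(combo = cb,
               count = k, pct = pct0(k, nrow(ad)),
               count_dedup = kd, pct_dedup = pct0(kd, nrow(ad_dd)),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(
      regimen = attr(nodes, "regimen"), depth = attr(nodes, "depth"),
      adapted_threshold = threshold,
      therapeutic_thresholds = c("5HT" = 400, "NE" = 200, "DA" = 200),
      levels = levels_tab,
      acute_error = nodes$error[nodes$level == 0L][1],
      adapted_sequences = nrow(ad), adapted_configurations = nrow(ad_dd),
      combinations = tab
    ),
    class = "search_report"
  )
}

#' @export
print.search_report <- function(x, ...) {
  cat("<search_report>:", paste(x$regimen, collapse = " + "),
      "| depth", x$depth, "\n")
  cat(sprintf("  acute error %.6f, adapted threshold %.6f\n",
              x$acute_error, x$adapted_threshold))
  cat("  adapted states:", x$adapted_configurations, "configurations /",
      x$adapted_sequences, "sequences\n")
  tb <- x$combinations
  cat("  therapeutic (dedup): ",
      paste(sprintf("%s %d (%.0f%%)", tb$combo, tb$count_dedup, tb$pct_dedup),
            collapse = "  "), "\n")
  invisible(x)
}

#' Write search reports
#'
#' `write_report_json()` serializes one report; `reports_to_table()`
#' flattens one or more reports into a data.frame (one row per regimen,
#' columns: adapted states plus the 7 monoamine-combination columns as
#' `"count (pct%)"` strings) which `write_report_csv()` writes out.
#'
#' @param report A `search_report`.
#' @param path Output path.
#' @param dedup Use deduplicated-configuration counts (default) or raw
#'   sequence counts.
#' @return `path` invisibly, or the flattened data.frame.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' @rdname write_report_json
#' @param reports A list of `search_report` objects.
#' @export
reports_to_table <- function(reports, dedup = TRUE) {
  rows <- lapply(reports, function(rp) {
    tb <- rp$combinations
    k <- if (dedup) tb$count_dedup else tb$count
    p <- if (dedup) tb$pct_dedup else tb$pct
    n <- if (dedup) rp$adapted_configurations else rp$adapted_sequences
    cells <- stats::setNames(sprintf("%d (%.0f%%)", k, p), tb$combo)
    cbind(
      data.frame(regimen = paste(rp$regimen, collapse = "+"),
                 adapted_states = n, stringsAsFactors = FALSE),
      as.data.frame(as.list(cells), check.names = FALSE)
    )
  })
  do.call(rbind, rows)
}

#' @rdname write_report_json
#' @export
write_report_csv <- function(reports, path, dedup = TRUE) {
  if (inherits(reports, "search_report")) reports <- list(reports)
  utils::write.csv(reports_to_table(reports, dedup), path, row.names = FALSE)
  invisible(path)
}
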