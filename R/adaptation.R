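# Receptor-strength adaptation.
#
# A receptor configuration holds the 11 adjustable receptor strengths as
# calibrated base values plus an integer count of unit adjustments; the
# realized strength is clamp(base + delta, 0, 10), so a step that would
# cross a bound moves by exactly the fraction needed to land on 0 or 10.
# Configurations compare equal by their integer deltas alone -- no
# floating-point tolerance is ever needed.

#' Receptor configuration: base strengths plus integer adjustment deltas
#'
#' @param params A `mono_params` object supplying the base strengths.
#' @param receptors Which receptor populations are adjustable (default:
#'   the canonical 11; a subset reproduces restricted-adaptation
#'   experiments such as 5HT1A-only adjustment).
#' @param delta Integer vector of adjustment counts (default all 0).
#' @return An object of class `receptor_config` with fields `base`,
#'   `delta`, `receptors`.
#' @export
receptor_configuration <- function(params, receptors = adjustable_receptors(),
                                   delta = integer(length(receptors))) {
  bad <- setdiff(receptors, adjustable_receptors())
  if (length(bad)) stop("not adjustable receptor(s): ", paste(bad, collapse = ", "))
  structure(
    list(
      base = stats::setNames(params$receptors[receptors], receptors),
      delta = stats::setNames(as.integer(delta), receptors),
      receptors = receptors
    ),
    class = "receptor_config"
  )
}

#' @rdname receptor_configuration
#' @param config A `receptor_config`.
#' @return `config_strengths()` returns the realized strengths
#'   `clamp(base + delta, 0, 10)` as a named numeric vector.
#' @export
config_strengths <- function(config) {
  pmin(pmax(config$base + config$delta, 0), 10)
}

# exact identity key: integer deltas only
config_key <- function(config) paste(config$delta, collapse = ",")

#' @rdname receptor_configuration
#' @return `apply_config()` returns `params` with the adjustable receptor
#'   strengths replaced by the configuration's realized strengths.
#' @export
apply_config <- function(params, config) {
  params$receptors[config$receptors] <- config_strengths(config)
  params
}

#' @export
print.receptor_config <- function(x, ...) {
  s <- config_strengths(x)
  cat("<receptor_config> (", length(x$receptors), " adjustable)\n", sep = "")
  print(data.frame(base = x$base, delta = x$delta, strength = s))
  invisible(x)
}

#' Apply a single receptor-strength adjustment
#'
#' A strength moves up or down by 1, or by exactly the fraction needed to
#' land on a bound (0 or 10) when it is within 1 of that bound. A move is
#' illegal -- and rejected with a condition of class
#' `monoadapt_illegal_move` -- when the strength already sits on the
#' blocking bound.
#'
#' @param config A `receptor_config`.
#' @param receptor Adjustable receptor name.
#' @param direction `+1` (sensitize) or `-1` (desensitize).
#' @return The adjusted `receptor_config`, with attribute `"realized"`
#'   giving the realized change magnitude in `(0, 1]`.
#' @export
apply_adjustment <- function(config, receptor, direction) {
  if (!receptor %in% config$receptors) stop("receptor not in the adjustable set: ", receptor)
  if (!direction %in% c(-1L, 1L)) stop("direction must be +1 or -1")
  cur <- config_strengths(config)[[receptor]]
  if ((direction > 0 && cur >= 10) || (direction < 0 && cur <= 0)) {
    stop(structure(
      class = c("monoadapt_illegal_move", "error", "condition"),
      list(message = sprintf("illegal move: %s at bound %g cannot move %+d",
                             receptor, cur, direction),
           call = sys.call(-1))
    ))
  }
  out <- config
  out$delta[[receptor]] <- out$delta[[receptor]] + as.integer(direction)
  realized <- abs(config_strengths(out)[[receptor]] - cur)
  attr(out, "realized") <- realized
  out
}

#' Enumerate the legal single adjustments from a configuration
#'
#' All and only the (receptor, direction) moves not blocked by the
#' strength bounds. From a strictly interior configuration with the full
#' adjustable set this is 22 moves (11 receptors x 2 directions).
#'
#' @param config A `receptor_config`.
#' @return A data.frame with columns `receptor`, `direction`.
#' @export
legal_moves <- function(config) {
  s <- config_strengths(config)
  up <- config$receptors[s < 10]
  down <- config$receptors[s > 0]
  data.frame(
    receptor = c(up, down),
    direction = c(rep(1L, length(up)), rep(-1L, length(down))),
    stringsAsFactors = FALSE
  )
}

# run expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# memoizing activation-error evaluator under a fixed regimen.
# Baseline is always the same parameter set's own no-drug summary with
# unadjusted receptors, recomputed here, never cached across sets.
make_error_evaluator <- function(params, reg, T = 150, window = c(75, 150)) {
  baseline <- evaluate_regimen(params, regimen(), T, window)
  baseline_levels <- transmitter_levels(baseline, params, regimen())
  memo <- new.env(parent = emptyenv())
  evaluate <- function(config) {
    key <- config_key(config)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    p <- apply_config(params, config)
    s <- evaluate_regimen(p, reg, T, window)
    res <- list(
      error = activation_error(s, baseline),
      levels = transmitter_levels(s, p, reg),
      summary = s
    )
    res$levels_pct <- percent_of_baseline(res$levels, baseline_levels)
    memo[[key]] <- res
    res
  }
  list(evaluate = evaluate, baseline = baseline, baseline_levels = baseline_levels,
       memo = memo)
}

new_trajectory <- function(steps, start, config, ev, acute, final, seed, reg,
                           terminal = FALSE, certificate = NULL) {
  structure(
    list(
      steps = steps,
      n_proposals = nrow(steps), n_accepted = sum(steps$accepted),
      accepted_errors = steps$error[steps$accepted],
      acute_error = acute$error, final_error = final$error,
      acute_levels = acute$levels, final_levels = final$levels,
      acute_levels_pct = acute$levels_pct, final_levels_pct = final$levels_pct,
      baseline = ev$baseline, baseline_levels = ev$baseline_levels,
      start_config = start, config = config,
      seed = seed, rng = RNGkind()[1],
      regimen = vapply(reg$drugs, `[[`, "", "name"),
      terminal = terminal, certificate = certificate
    ),
    class = "adapt_trajectory"
  )
}

#' @export
print.adapt_trajectory <- function(x, ...) {
  cat("<adapt_trajectory>: ", x$n_proposals, " proposals, ", x$n_accepted,
      " accepted", if (isTRUE(x$terminal)) ", terminally adapted" else "", "\n", sep = "")
  cat(sprintf("  activation error: acute %.6f -> final %.6f\n", x$acute_error, x$final_error))
  cat(sprintf("  monoamines (%% baseline): %s\n",
              paste(sprintf("%s=%.0f%%", names(x$final_levels_pct), x$final_levels_pct),
                    collapse = " ")))
  invisible(x)
}

#' Single-pathway stochastic neuroadaptation
#'
#' Simulated chronic drug administration perturbs the monoaminergic unit
#' activations away from their no-drug baselines; neuroadaptation
#' proposes, at each step, a uniformly random legal (receptor, direction)
#' adjustment and retains it only if it strictly reduces the activation
#' error. `max_steps` counts proposals, accepted or not.
#'
#' @param params A calibrated `mono_params` object.
#' @param reg The maintained `mono_regimen`.
#' @param max_steps Number of random proposals (`>= 1`).
#' @param seed Optional integer seed (recorded in the trajectory).
#' @param receptors Adjustable subset (default: all 11).
#' @param T,window Simulation length and averaging window.
#' @return An `adapt_trajectory`: per-proposal records, the strictly
#'   decreasing accepted-error series, acute and final monoamine levels
#'   (absolute and as percent of the no-drug baseline), and the start and
#'   end configurations.
#' @export
adapt_path <- function(params, reg, max_steps = 100, seed = NULL,
                       receptors = adjustable_receptors(),
                       T = 150, window = c(75, 150)) {
  if (max_steps < 1) stop("max_steps must be >= 1")
  ev <- make_error_evaluator(params, reg, T, window)
  config <- receptor_configuration(params, receptors)
  start <- config
  acute <- ev$evaluate(config)
  cur <- acute
  steps <- vector("list", max_steps)
  with_seed(seed, {
    for (k in seq_len(max_steps)) {
      mv <- legal_moves(config)
      pick <- mv[sample.int(nrow(mv), 1L), ]
      cand <- apply_adjustment(config, pick$receptor, pick$direction)
      res <- ev$evaluate(cand)
      accept <- res$error < cur$error
      steps[[k]] <- data.frame(
        proposal = k, receptor = pick$receptor, direction = pick$direction,
        magnitude = attr(cand, "realized"), error = res$error, accepted = accept,
        stringsAsFactors = FALSE
      )
      if (accept) {
        config <- cand
        cur <- res
      }
    }
  })
  new_trajectory(do.call(rbind, steps), start, config, ev, acute, cur, seed, reg)
}

#' Adaptation to terminal completion
#'
#' Random error-reducing adjustments continue until no legal single move
#' further reduces the activation error. Termination is certified by an
#' exhaustive evaluation of every legal move from the terminal
#' configuration, stored in the trajectory's `certificate`.
#'
#' @inheritParams adapt_path
#' @param max_proposals Safety cap on total proposals.
#' @return An `adapt_trajectory` with `terminal = TRUE` and a
#'   `certificate` data.frame (one row per legal terminal move with its
#'   error, all `>=` the terminal error).
#' @export
terminal_adapt <- function(params, reg, seed = NULL,
                           receptors = adjustable_receptors(),
                           T = 150, window = c(75, 150), max_proposals = 100000) {
  ev <- make_error_evaluator(params, reg, T, window)
  config <- receptor_configuration(params, receptors)
  start <- config
  acute <- ev$evaluate(config)
  cur <- acute
  steps <- list()
  with_seed(seed, {
    tried <- character()
    k <- 0L
    repeat {
      mv <- legal_moves(config)
      keys <- paste(mv$receptor, mv$direction)
      open <- which(!keys %in% tried)
      if (!length(open)) break  # every legal move already rejected
      k <- k + 1L
      if (k > max_proposals) stop("terminal_adapt() exceeded max_proposals")
      i <- open[sample.int(length(open), 1L)]
      cand <- apply_adjustment(config, mv$receptor[i], mv$direction[i])
      res <- ev$evaluate(cand)
      accept <- res$error < cur$error
      steps[[k]] <- data.frame(
        proposal = k, receptor = mv$receptor[i], direction = mv$direction[i],
        magnitude = attr(cand, "realized"), error = res$error, accepted = accept,
        stringsAsFactors = FALSE
      )
      if (accept) {
        config <- cand
        cur <- res
        tried <- character()
      } else {
        tried <- c(tried, keys[i])
      }
    }
  })
  # exhaustive one-step certificate at termination
  mv <- legal_moves(config)
  cert <- do.call(rbind, lapply(seq_len(nrow(mv)), function(i) {
    cand <- apply_adjustment(config, mv$receptor[i], mv$direction[i])
    data.frame(receptor = mv$receptor[i], direction = mv$direction[i],
               error = ev$evaluate(cand)$error, stringsAsFactors = FALSE)
  }))
  if (any(cert$error < cur$error)) {
    stop("internal error: terminal certificate violated")  # unreachable
  }
  new_trajectory(do.call(rbind, steps), start, config, ev, acute, cur, seed, reg,
                 terminal = TRUE, certificate = cert)
}

#' Write an adaptation trajectory as JSON lines
#'
#' One JSON object per proposal (receptor, direction, realized magnitude,
#' resulting error, accepted flag), preceded by a header object with the
#' seed, generator, and regimen.
#'
#' @param traj An `adapt_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_jsonl <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- list(
    type = "header", seed = traj$seed, rng = traj$rng,
    regimen = traj$regimen, acute_error = traj$acute_error,
    final_error = traj$final_error, terminal = traj$terminal
  )
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA, null = "null"), con)
  for (i in seq_len(nrow(traj$steps))) {
    writeLines(jsonlite::toJSON(as.list(traj$steps[i, ]), auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
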