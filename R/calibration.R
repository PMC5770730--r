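# Calibration: the activation-error seminorm, the composite RMS error
# against acute-response targets, GA optimization, and the
# offset-vs-amplitude screening diagnostic used to vet parameterizations.

#' Activation error of the monoaminergic nuclei
#'
#' The homeostat's objective: the sum of the absolute differences of the
#' window-averaged DR, LC, and VTA activations from their no-drug
#' baseline activations. Non-monoaminergic units are excluded.
#'
#' @param summary,baseline `activation_summary` objects from the same
#'   parameter set (drug and no-drug conditions respectively).
#' @return Non-negative error.
#' @export
activation_error <- function(summary, baseline) {
  nuc <- mono_nuclei()
  sum(abs(summary$means[nuc] - baseline$means[nuc]))
}

#' Calibration target tables
#'
#' A target table is a data.frame with columns `regimen` (a drug name,
#' combination alias, or `"none"`), `unit` (a unit id, or a transmitter
#' id for `level` rows), `metric`, `value`, and `weight` (default 1).
#' Metrics:
#' \describe{
#'   \item{`pct_change`}{percent change from the no-drug baseline of the
#'     unit's window-averaged activation under the regimen,
#'     `100 * (a - a0) / a0`.}
#'   \item{`baseline_activation`}{the unit's no-drug activation.}
#'   \item{`level`}{the extracellular transmitter level (absolute, in
#'     model units) under the regimen; `unit` names the transmitter.}
#' }
#'
#' @param df A data.frame with the columns above (`weight` optional).
#' @return A validated `calibration_targets` data.frame.
#' @export
calibration_targets <- function(df) {
  need <- c("regimen", "unit", "metric", "value")
  if (!all(need %in% names(df))) {
    stop("targets need columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$weight)) df$weight <- 1
  if (any(!is.finite(df$value))) stop("target values must be finite")
  if (any(df$weight < 0)) stop("target weights must be non-negative")
  ok <- df$metric %in% c("pct_change", "baseline_activation", "level")
  if (any(!ok)) stop("unknown metric(s): ", paste(unique(df$metric[!ok]), collapse = ", "))
  class(df) <- c("calibration_targets", "data.frame")
  df
}

#' @rdname calibration_targets
#' @param path CSV file path (columns `regimen, unit, metric, value,
#'   weight`).
#' @export
read_targets_csv <- function(path) {
  calibration_targets(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname calibration_targets
#' @param targets A `calibration_targets` table.
#' @export
write_targets_csv <- function(targets, path) {
  utils::write.csv(as.data.frame(targets), path, row.names = FALSE)
  invisible(path)
}

# model values for every row of a target table (shared by the error
# function and by synthetic target generation)
model_target_values <- function(params, targets, registry = drug_registry(),
                                T = 150, window = c(75, 150)) {
  base <- evaluate_regimen(params, regimen(), T, window)
  regs <- setdiff(unique(targets$regimen), "none")
  summaries <- list(none = base)
  for (r in regs) {
    summaries[[r]] <- evaluate_regimen(params, regimen(r, registry = registry), T, window)
  }
  vapply(seq_len(nrow(targets)), function(i) {
    rg <- targets$regimen[i]
    u <- targets$unit[i]
    s <- summaries[[rg]]
    if (is.null(s)) stop("unresolvable regimen id: ", rg)
    switch(targets$metric[i],
      pct_change = {
        a0 <- base$means[[u]]
        100 * (s$means[[u]] - a0) / a0
      },
      baseline_activation = base$means[[u]],
      level = {
        reg_obj <- if (rg == "none") regimen() else regimen(rg, registry = registry)
        transmitter_levels(s, params, reg_obj)[[u]]
      }
    )
  }, numeric(1))
}

#' Composite RMS calibration error
#'
#' Simulates every regimen referenced by the target table (plus the
#' no-drug baseline), computes the model value for each row, and returns
#' the weighted root-mean-square of the residuals (model minus target):
#' `sqrt(sum(w * r^2) / sum(w))`. Rows are equally weighted by default.
#'
#' @param params A `mono_params` object.
#' @param targets A `calibration_targets` table (non-empty).
#' @param registry Drug registry for resolving regimen ids.
#' @param T,window Simulation length and averaging window.
#' @return Non-negative RMS error.
#' @export
calibration_error <- function(params, targets, registry = drug_registry(),
                              T = 150, window = c(75, 150)) {
  if (!nrow(targets)) stop("target table is empty")
  mod <- model_target_values(params, targets, registry, T, window)
  r <- mod - targets$value
  sqrt(sum(targets$weight * r^2) / sum(targets$weight))
}

# box bounds for a named flat parameter (receptor strengths [0,10],
# weights [-10,10] with positive self-weights, biases [-10,10],
# transporter efficacies and drug magnitudes [0,1])
flat_bounds <- function(flat_names) {
  selfw <- paste0("W.", paste(c("tCRF", "Tgal", "Tglu"), c("tCRF", "Tgal", "Tglu"), sep = "."))
  lower <- ifelse(grepl("^R\\.", flat_names), 0,
           ifelse(flat_names %in% selfw, 1e-6,
           ifelse(grepl("^W\\.|^B\\.", flat_names), -10, 0)))
  upper <- ifelse(grepl("^R\\.", flat_names), 10,
           ifelse(grepl("^W\\.|^B\\.", flat_names), 10, 1))
  list(lower = lower, upper = upper)
}

#' Calibrate model parameters by repeated GA minimization
#'
#' Runs `cfg$restarts` independent genetic-algorithm searches minimizing
#' [calibration_error()] over the chosen free parameters (all others stay
#' frozen at the template's values) and returns every restart's best
#' result, sorted by ascending error. With a fixed seed the ranked list
#' is reproducible, and increasing the number of restarts can only
#' improve the best error.
#'
#' @param template A `mono_params` object: frozen values plus structure.
#' @param targets A `calibration_targets` table.
#' @param free Character vector of flat parameter names (see
#'   [flatten_params()]) to optimize; default: all.
#' @param cfg A [ga_config()].
#' @param registry Drug registry.
#' @param T,window Simulation settings.
#' @return A list of class `calibration_result`: `fits` (each with
#'   `params`, `error`, `log`, `seed`), sorted ascending by error, plus
#'   the configuration and free-parameter names.
#' @export
calibrate_params <- function(template, targets, free = NULL, cfg = ga_config(),
                             registry = drug_registry(), T = 150, window = c(75, 150)) {
  flat0 <- flatten_params(template)
  if (is.null(free)) free <- names(flat0)
  bad <- setdiff(free, names(flat0))
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  b <- flat_bounds(free)
  objective <- function(x) {
    flat <- flat0
    flat[free] <- x
    ps <- try(unflatten_params(flat, template), silent = TRUE)
    if (inherits(ps, "try-error")) return(Inf)
    calibration_error(ps, targets, registry, T, window)
  }
  fits <- lapply(seq_len(cfg$restarts), function(i) {
    run <- ga_minimize(objective, b$lower, b$upper, cfg, seed = cfg$seed + i)
    flat <- flat0
    flat[free] <- run$par
    list(params = unflatten_params(flat, template), error = run$error,
         log = run$log, generations = run$generations, seed = run$seed)
  })
  fits <- fits[order(vapply(fits, `[[`, numeric(1), "error"))]
  structure(list(fits = fits, free = free, config = cfg), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  err <- vapply(x$fits, `[[`, numeric(1), "error")
  cat("<calibration_result>: ", length(err), " restart(s), ",
      length(x$free), " free parameter(s)\n", sep = "")
  cat(sprintf("  best error %.6g (range %.6g .. %.6g)\n",
              min(err), min(err), max(err)))
  invisible(x)
}

#' Write a GA run log as JSON
#'
#' Records the seed, generator, operator settings, and the
#' per-generation best-error series of every restart, for reproducibility
#' audits.
#'
#' @param result A `calibration_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ga_log <- function(result, path) {
  obj <- list(
    rng = RNGkind()[1],
    config = unclass(result$config),
    free = result$free,
    runs = lapply(result$fits, function(f) {
      list(seed = f$seed, error = f$error, generations = f$generations,
           best_by_generation = f$log)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Offset-vs-amplitude screening of a parameterization
#'
#' The unit activities oscillate about a constant offset. For a
#' parameterization to be usable, receptor adjustments should act mainly
#' by shifting that offset (which moves the window average), not by
#' reshaping the oscillation amplitude. For each adjustable receptor this
#' diagnostic simulates the network before and after a unit strength
#' decrement and reports, over the monoaminergic units, the largest
#' absolute change in windowed mean (offset shift) and in windowed
#' peak-to-trough range (amplitude shift). Parameterizations whose
#' typical amplitude shift dominates the offset shift are flagged.
#'
#' @param params A `mono_params` object.
#' @param reg Regimen under which to probe (default: no drug).
#' @param receptors Adjustable receptors to probe.
#' @param T,window Simulation settings.
#' @return An object of class `screening_diagnostics`: a data.frame with
#'   per-receptor `offset_shift`, `amplitude_shift`, `dominance_ratio`,
#'   and an overall `amplitude_dominant` flag (median ratio > 1).
#' @export
screen_parameterization <- function(params, reg = regimen(),
                                    receptors = adjustable_receptors(),
                                    T = 150, window = c(75, 150)) {
  idx <- window[1]:window[2]
  probe <- function(p) {
    tr <- simulate_network(p, reg, T)
    w <- tr$activities[idx, mono_nuclei(), drop = FALSE]
    list(offset = colMeans(w), amp = apply(w, 2, function(v) max(v) - min(v)))
  }
  ref <- probe(params)
  rows <- lapply(receptors, function(r) {
    p2 <- params
    p2$receptors[[r]] <- max(0, p2$receptors[[r]] - 1)
    alt <- probe(p2)
    off <- max(abs(alt$offset - ref$offset))
    amp <- max(abs(alt$amp - ref$amp))
    data.frame(receptor = r, offset_shift = off, amplitude_shift = amp,
               dominance_ratio = amp / max(off, .Machine$double.eps),
               stringsAsFactors = FALSE)
  })
  diag <- do.call(rbind, rows)
  structure(
    list(diagnostics = diag,
         amplitude_dominant = stats::median(diag$dominance_ratio) > 1),
    class = "screening_diagnostics"
  )
}

#' @export
print.screening_diagnostics <- function(x, ...) {
  cat("<screening_diagnostics>",
      if (x$amplitude_dominant) "(FLAGGED: amplitude-dominant)" else "(offset-dominant)", "\n")
  print(transform(x$diagnostics,
                  offset_shift = signif(offset_shift, 4),
                  amplitude_shift = signif(amplitude_shift, 4),
                  dominance_ratio = signif(dominance_ratio, 3)))
  invisible(x)
}

#' Representative-fit report over ranked calibration results
#'
#' For each fit: its error rank, whether acute and adapted escitalopram
#' raise the 5HT level (the robustness check used when picking a
#' representative parameterization), and the amplitude-dominance
#' screening flag. The final choice among acceptable fits is left to the
#' user.
#'
#' @param result A `calibration_result`.
#' @param registry Drug registry (must define `esc`).
#' @param seed Seed for the adaptation probe.
#' @return A data.frame, one row per fit.
#' @export
representative_report <- function(result, registry = drug_registry(), seed = 1) {
  rows <- lapply(seq_along(result$fits), function(i) {
    f <- result$fits[[i]]
    reg <- regimen("esc", registry = registry)
    traj <- adapt_path(f$params, reg, max_steps = 50, seed = seed,
                       receptors = "DR.5HT1AR")
    scr <- screen_parameterization(f$params)
    data.frame(
      rank = i, error = f$error,
      acute_5HT_rise = unname(traj$acute_levels_pct[["5HT"]] > 100),
      adapted_5HT_above_acute =
        unname(traj$final_levels[["5HT"]] > traj$acute_levels[["5HT"]]),
      amplitude_dominant = scr$amplitude_dominant,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
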