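# Discrete-time simulation of the 6-unit recurrent network.
#
# Each time step, every unit synchronously sums its inputs -- receptor
# drives for the monoaminergic nuclei, generic weighted activities for the
# non-monoaminergic units -- adds its bias, and passes the result through
# the logistic squashing function. All drug and transporter effects are
# affine in the source activities, so a (parameter set, regimen) pair
# compiles once to an affine map x -> squash(M x + c) that the simulator
# iterates; the explicit per-connection form is kept in step_network() and
# cross-checked against the compiled path in the test suite.

#' Logistic squashing function
#'
#' Bounds unit activations smoothly and strictly between 0 and 1:
#' `squash(x) = 1 / (1 + exp(-x))`. Symmetric about `squash(0) = 0.5`.
#'
#' @param x Finite numeric input (vectorized).
#' @return Activation(s) in `(0, 1)`.
#' @export
squash <- function(x) {
  if (any(!is.finite(x))) stop("squash() requires finite input")
  1 / (1 + exp(-x))
}

# Compile (params, regimen) to the affine update x' = squash(M x + c).
# Returns M (6x6, unit order mono_units()), c (length 6, includes biases),
# and the presented-amount coefficients reused for transmitter levels.
compile_network <- function(params, reg = regimen()) {
  validate_params(params)
  units <- mono_units()
  n <- length(units)
  M <- matrix(0, n, n, dimnames = list(units, units))
  cc <- stats::setNames(numeric(n), units)

  eff <- regimen_effects(params, reg)
  # presented amount for transmitter m from source activity a:
  #   a * gain_m + add_m
  gain <- stats::setNames(rep(1, length(mono_transmitters())), mono_transmitters())
  add <- stats::setNames(numeric(length(mono_transmitters())), mono_transmitters())
  for (m in transported_transmitters()) {
    tau_eff <- effective_transporter(params$transporters[[m]], eff$blockade[[m]])
    gain[[m]] <- 1 - tau_eff
    add[[m]] <- eff$releaser[[m]] * (1 - tau_eff)
  }

  tab <- receptor_table()
  conn <- mono_connections()
  site <- paste(conn$target, conn$receptor, sep = ".")
  keep <- rep(1, length(site))
  if (length(eff$antagonist)) {
    hit <- match(site, names(eff$antagonist))
    keep[!is.na(hit)] <- unlist(eff$antagonist)[hit[!is.na(hit)]]
  }
  coef <- conn$polarity * unname(params$receptors[site]) * keep
  dM <- coef * gain[conn$transmitter]
  dc <- coef * add[conn$transmitter]
  ij <- cbind(match(conn$target, units), match(conn$source, units))
  for (i in seq_along(coef)) {  # duplicated (target, source) pairs accumulate
    M[ij[i, 1], ij[i, 2]] <- M[ij[i, 1], ij[i, 2]] + dM[i]
  }
  cc <- cc + vapply(units, function(u) sum(dc[conn$target == u]), numeric(1))
  # direct agonist occupancy: once per site
  for (site in names(eff$agonist)) {
    u <- tab[site, "unit"]
    cc[u] <- cc[u] + tab[site, "polarity"] * params$receptors[[site]] * eff$agonist[[site]]
  }
  # generic weights onto non-monoaminergic units
  for (tgt in c("tCRF", "Tgal", "Tglu")) {
    for (src in units) {
      M[tgt, src] <- params$weights[[paste(tgt, src, sep = ".")]]
    }
  }
  cc <- cc + params$biases[units]
  list(M = M, c = cc, gain = gain, add = add)
}

#' Advance the network by one synchronous time step
#'
#' Monoaminergic units sum their receptor drives over all incoming
#' connections (with transmitter amounts given by [presented_amount()] and
#' drug terms per [receptor_drive()]); non-monoaminergic units sum generic
#' weight times source activity. Each unit adds its bias and squashes.
#'
#' @param activities Named numeric vector of 6 unit activities in
#'   `[0, 1)` (the all-zero initial state is allowed).
#' @param params A `mono_params` object (validated before stepping).
#' @param reg A `mono_regimen`.
#' @return Named numeric vector of 6 updated activities in `(0, 1)`.
#' @export
step_network <- function(activities, params, reg = regimen()) {
  validate_params(params)
  units <- mono_units()
  a <- activities[units]
  if (any(!is.finite(a)) || any(a < 0) || any(a >= 1)) {
    if (!all(a == 0)) stop("activities must lie in [0, 1) ")
  }
  eff <- regimen_effects(params, reg)
  conn <- mono_connections()
  tab <- receptor_table()
  inp <- stats::setNames(numeric(length(units)), units)
  for (i in seq_len(nrow(conn))) {
    amt <- presented_amount(a[[conn$source[i]]], conn$transmitter[i], params, reg)
    inp[conn$target[i]] <- inp[conn$target[i]] +
      receptor_drive(conn$target[i], conn$receptor[i], amt, params, reg,
                     include_agonist = FALSE)
  }
  for (site in names(eff$agonist)) {
    u <- tab[site, "unit"]
    inp[u] <- inp[u] + tab[site, "polarity"] * params$receptors[[site]] * eff$agonist[[site]]
  }
  for (tgt in c("tCRF", "Tgal", "Tglu")) {
    inp[tgt] <- sum(params$weights[paste(tgt, units, sep = ".")] * a)
  }
  squash(inp + params$biases[units])
}

#' Simulate the network from the all-zero initial state
#'
#' All unit activities start at 0 and the units influence each other for
#' `T` synchronous time steps (default 150). The run is fully
#' deterministic. Time-step length is arbitrary: the model reproduces
#' average activations, not oscillation frequencies.
#'
#' @param params A `mono_params` object.
#' @param reg A `mono_regimen` maintained for the whole run.
#' @param T Number of time steps (`>= 2`).
#' @param compiled Optional pre-compiled network (internal reuse).
#' @return An object of class `sim_trace`: a `T` x 6 matrix of activities
#'   (`$activities`, rows = steps) plus the regimen.
#' @export
simulate_network <- function(params, reg = regimen(), T = 150, compiled = NULL) {
  if (T < 2) stop("T must be at least 2")
  net <- if (is.null(compiled)) compile_network(params, reg) else compiled
  units <- mono_units()
  out <- matrix(NA_real_, T, length(units), dimnames = list(NULL, units))
  x <- numeric(length(units))
  M <- net$M; cc <- net$c
  for (t in seq_len(T)) {
    x <- 1 / (1 + exp(-(drop(M %*% x) + cc)))
    out[t, ] <- x
  }
  structure(list(activities = out, regimen = reg, T = T), class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat("<sim_trace>:", x$T, "steps x", ncol(x$activities), "units\n")
  s <- average_activation(x)
  cat("  window means:", paste(sprintf("%s=%.4f", names(s$means), s$means), collapse = " "), "\n")
  invisible(x)
}

#' Window-averaged unit activations
#'
#' The activation of a unit is the arithmetic mean of its activity over
#' the second half of the run, time steps 75 to 150 inclusive by default
#' (76 samples). In the no-drug condition these means are the normative
#' baseline activations.
#'
#' @param trace A `sim_trace`.
#' @param window Inclusive integer bounds `c(lo, hi)` with
#'   `lo < hi <= T`.
#' @return An object of class `activation_summary` with fields `means`
#'   (named numeric, 6 units) and `window`.
#' @export
average_activation <- function(trace, window = c(75, 150)) {
  stopifnot(inherits(trace, "sim_trace"))
  lo <- window[1]; hi <- window[2]
  if (lo >= hi || lo < 1 || hi > trace$T) stop("averaging window must satisfy 1 <= lo < hi <= T")
  means <- colMeans(trace$activities[lo:hi, , drop = FALSE])
  structure(list(means = means, window = c(lo, hi)), class = "activation_summary")
}

#' @export
print.activation_summary <- function(x, ...) {
  cat("<activation_summary> window [", x$window[1], ",", x$window[2], "]:\n")
  print(round(x$means, 4))
  invisible(x)
}

#' Export a simulation trace as CSV
#'
#' Columns: `step`, then one column per unit (`DR`, `LC`, `VTA`, `tCRF`,
#' `Tgal`, `Tglu`).
#'
#' @param trace A `sim_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(step = seq_len(trace$T), trace$activities, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# convenience: simulate a regimen and summarize in one call
evaluate_regimen <- function(params, reg = regimen(), T = 150, window = c(75, 150),
                             compiled = NULL) {
  average_activation(simulate_network(params, reg, T, compiled = compiled), window)
}
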