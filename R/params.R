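# ParameterSet: every tunable quantity of the model in one validated
# container. Receptor strengths are absolute values in [0, 10] (their sign
# comes from the fixed connection polarity); generic weights are signed;
# transporter efficacies are the fraction of released monoamine removed by
# reuptake; drug magnitudes are per drug-target effect sizes in [0, 1].

#' Construct a model parameter set
#'
#' @param receptors Named numeric vector of receptor strengths, one per
#'   (nucleus, receptor) population listed by [receptor_table()], each in
#'   `[0, 10]`.
#' @param weights Named numeric vector of the 18 generic connection
#'   weights onto the non-monoaminergic units (`"tCRF.DR"`, ...); the
#'   self-weights (`tCRF.tCRF`, `Tgal.Tgal`, `Tglu.Tglu`) must be
#'   positive.
#' @param biases Named numeric vector of 6 unit biases.
#' @param transporters Named numeric vector `c("5HT"=, "NE"=, "DA"=)` of
#'   transporter efficacies in `[0, 1]`.
#' @param drug_magnitudes Named numeric vector of drug-target effect
#'   magnitudes in `[0, 1]`; names must match the target ids of the drug
#'   registry (see [drug_registry()]).
#'
#' @return An object of class `mono_params`.
#' @seealso [validate_params()], [flatten_params()], [write_params()]
#' @export
parameter_set <- function(receptors, weights, biases, transporters,
                          drug_magnitudes = numeric()) {
  ps <- structure(
    list(
      receptors = unlist(receptors), weights = unlist(weights),
      biases = unlist(biases), transporters = unlist(transporters),
      drug_magnitudes = unlist(drug_magnitudes)
    ),
    class = "mono_params"
  )
  validate_params(ps)
  ps
}

#' Validate a parameter set against the model's structural invariants
#'
#' Checks completeness of the parameter names against the model topology
#' and the registry, the `[0, 10]` receptor-strength bounds, positivity of
#' the non-monoaminergic self-weights, and the `[0, 1]` bounds on
#' transporter efficacies and drug magnitudes.
#'
#' @param ps A `mono_params` object.
#' @return `ps`, invisibly; an error is signalled on any violation.
#' @export
validate_params <- function(ps) {
  stopifnot(inherits(ps, "mono_params"))
  tab <- receptor_table()
  if (!setequal(names(ps$receptors), tab$name)) {
    stop("receptor strengths must cover exactly the (nucleus, receptor) populations of the model")
  }
  if (any(!is.finite(ps$receptors)) || any(ps$receptors < 0) || any(ps$receptors > 10)) {
    stop("receptor strengths must be finite and within [0, 10]")
  }
  if (!setequal(names(ps$weights), generic_weight_names())) {
    stop("generic weights must cover exactly the 18 (non-monoaminergic target, source) pairs")
  }
  if (any(!is.finite(ps$weights))) stop("generic weights must be finite")
  selfw <- paste(c("tCRF", "Tgal", "Tglu"), c("tCRF", "Tgal", "Tglu"), sep = ".")
  if (any(ps$weights[selfw] <= 0)) {
    stop("self-weights of the non-monoaminergic units must be positive")
  }
  if (!setequal(names(ps$biases), mono_units())) stop("biases must name all 6 units")
  if (any(!is.finite(ps$biases))) stop("biases must be finite")
  if (!setequal(names(ps$transporters), transported_transmitters())) {
    stop("transporter efficacies must name 5HT, NE, DA")
  }
  if (any(ps$transporters < 0) || any(ps$transporters > 1)) {
    stop("transporter efficacies must lie in [0, 1]")
  }
  if (length(ps$drug_magnitudes)) {
    if (any(ps$drug_magnitudes < 0) || any(ps$drug_magnitudes > 1)) {
      stop("drug-target magnitudes must lie in [0, 1]")
    }
    known <- registry_target_ids()
    bad <- setdiff(names(ps$drug_magnitudes), known)
    if (length(bad)) stop("unknown drug-target magnitude id(s): ", paste(bad, collapse = ", "))
  }
  invisible(ps)
}

# canonical flattening order: receptors, weights, biases, transporters,
# drug magnitudes (registry order)
flat_order <- function(ps) {
  list(
    receptors = receptor_table()$name,
    weights = generic_weight_names(),
    biases = mono_units(),
    transporters = transported_transmitters(),
    drug_magnitudes = intersect(registry_target_ids(), names(ps$drug_magnitudes))
  )
}

#' Flatten a parameter set to a named numeric vector
#'
#' The canonical flat representation (receptor strengths, generic weights,
#' biases, transporter efficacies, drug magnitudes, in that order) used by
#' the genetic-algorithm calibrator. With the shipped drug registry the
#' vector has 76 elements.
#'
#' @param ps A `mono_params` object.
#' @return Named numeric vector.
#' @export
flatten_params <- function(ps) {
  ord <- flat_order(ps)
  out <- c(
    ps$receptors[ord$receptors], ps$weights[ord$weights],
    ps$biases[ord$biases], ps$transporters[ord$transporters],
    ps$drug_magnitudes[ord$drug_magnitudes]
  )
  names(out) <- c(
    paste0("R.", ord$receptors), paste0("W.", ord$weights),
    paste0("B.", ord$biases), paste0("T.", ord$transporters),
    paste0("D.", ord$drug_magnitudes)
  )
  out
}

#' @rdname flatten_params
#' @param flat Named numeric vector as produced by `flatten_params()`.
#' @param template A `mono_params` object supplying the structure.
#' @return For `unflatten_params()`, a `mono_params` object.
#' @export
unflatten_params <- function(flat, template) {
  ord <- flat_order(template)
  ps <- template
  take <- function(prefix, nm) {
    v <- flat[paste0(prefix, nm)]
    names(v) <- nm
    v
  }
  ps$receptors <- take("R.", ord$receptors)
  ps$weights <- take("W.", ord$weights)
  ps$biases <- take("B.", ord$biases)
  ps$transporters <- take("T.", ord$transporters)
  ps$drug_magnitudes <- take("D.", ord$drug_magnitudes)
  validate_params(ps)
  ps
}

#' @export
print.mono_params <- function(x, ...) {
  cat("<mono_params>: ", length(flatten_params(x)), " parameters\n", sep = "")
  cat("  receptor strengths:", length(x$receptors),
      sprintf("(%d adjustable)", sum(receptor_table()$adjustable)), "\n")
  cat("  generic weights:   ", length(x$weights), "\n")
  cat("  biases:            ", length(x$biases), "\n")
  cat("  transporters:      ", paste(sprintf("%s=%.3g", names(x$transporters), x$transporters),
                                     collapse = ", "), "\n")
  cat("  drug magnitudes:   ", length(x$drug_magnitudes), "\n")
  invisible(x)
}

#' Read and write parameter sets
#'
#' Parameter sets serialize to YAML or JSON (chosen by file extension)
#' with named fields mirroring the receptor, weight, bias, transporter,
#' and drug-magnitude labels. The round trip is lossless.
#'
#' @param ps A `mono_params` object.
#' @param path File path ending in `.yaml`, `.yml`, or `.json`.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns a validated `mono_params` object.
#' @export
write_params <- function(ps, path) {
  validate_params(ps)
  obj <- list(
    receptors = as.list(ps$receptors), weights = as.list(ps$weights),
    biases = as.list(ps$biases), transporters = as.list(ps$transporters),
    drug_magnitudes = as.list(ps$drug_magnitudes)
  )
  if (grepl("\\.ya?ml$", path)) {
    # 22 significant digits: more than the 17 needed to identify a double
    yaml::write_yaml(obj, path, precision = 22)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  } else {
    stop("unsupported parameter file extension: ", path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported parameter file extension: ", path)
  }
  parameter_set(
    receptors = unlist(obj$receptors), weights = unlist(obj$weights),
    biases = unlist(obj$biases), transporters = unlist(obj$transporters),
    drug_magnitudes = unlist(obj$drug_magnitudes)
  )
}
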