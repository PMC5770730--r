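# Pharmacology: the drug registry, maintained-drug regimens, transporter
# modulation, and extracellular transmitter levels.
#
# A drug is a set of targets, each one of:
#   reuptake_block     -- site is a monoamine transporter (named by its
#                         transmitter: 5HT/NE/DA); magnitude is the
#                         fraction of transporter efficacy removed.
#   releaser           -- site is a monoamine; magnitude adds to the
#                         pre-reuptake released amount.
#   receptor_agonist   -- site is a "unit.receptor" population; magnitude
#                         adds a direct occupancy term with the receptor's
#                         polarity and strength.
#   receptor_antagonist-- site is a "unit.receptor" population; magnitude
#                         scales the transmitter-bound drive by (1 - m).
# Partial agonists (aripiprazole at D2) are modeled as an agonist +
# antagonist pair at the same site. Every magnitude is a member of the
# ParameterSet (optimized during calibration), keyed by the target id.

drug_target <- function(id, mechanism, site) {
  list(id = id, mechanism = mechanism, site = site)
}

#' The shipped drug registry
#'
#' Mechanistic descriptions of the eight antidepressant and antipsychotic
#' drugs handled by the model: escitalopram (`esc`, SSRI), nomifensine
#' (`nom`, triple reuptake blocker with a dominant NE/DA action),
#' reboxetine (`reb`, NERI), trazodone (`trz`, SERT blocker plus 5HT1A and
#' alpha-adrenergic antagonist), asenapine (`asn`, D2/5HT2A antagonist),
#' aripiprazole (`arp`, D2 partial agonist), bupropion (`bup`, NE and DA
#' releaser), and quetiapine (`quet`, D2/alpha2 antagonist whose active
#' metabolite norquetiapine blocks the NE transporter). Magnitudes are *not* stored here: each target carries an
#' id that keys into the `drug_magnitudes` field of the parameter set, so
#' effect sizes are calibrated quantities. Users can extend or replace the
#' registry (see [read_drug_registry()]).
#'
#' @return Named list of drugs; each drug is a list with `name`, `label`,
#'   and `targets` (a list of `(id, mechanism, site)` records).
#' @export
drug_registry <- function() {
  list(
    esc = list(
      name = "esc", label = "Escitalopram",
      targets = list(drug_target("esc.SERT", "reuptake_block", "5HT"))
    ),
    nom = list(
      name = "nom", label = "Nomifensine",
      targets = list(
        drug_target("nom.SERT", "reuptake_block", "5HT"),
        drug_target("nom.NET", "reuptake_block", "NE"),
        drug_target("nom.DAT", "reuptake_block", "DA")
      )
    ),
    reb = list(
      name = "reb", label = "Reboxetine",
      targets = list(drug_target("reb.NET", "reuptake_block", "NE"))
    ),
    trz = list(
      name = "trz", label = "Trazodone",
      targets = list(
        drug_target("trz.SERT", "reuptake_block", "5HT"),
        drug_target("trz.DR.5HT1AR", "receptor_antagonist", "DR.5HT1AR"),
        drug_target("trz.LC.AR2", "receptor_antagonist", "LC.AR2"),
        drug_target("trz.VTA.AR2", "receptor_antagonist", "VTA.AR2")
      )
    ),
    asn = list(
      name = "asn", label = "Asenapine",
      targets = list(
        drug_target("asn.DR.D2R", "receptor_antagonist", "DR.D2R"),
        drug_target("asn.LC.D2R", "receptor_antagonist", "LC.D2R"),
        drug_target("asn.VTA.D2R", "receptor_antagonist", "VTA.D2R"),
        drug_target("asn.LC.5HT2AR", "receptor_antagonist", "LC.5HT2AR"),
        drug_target("asn.VTA.5HT2AR", "receptor_antagonist", "VTA.5HT2AR")
      )
    ),
    arp = list(
      name = "arp", label = "Aripiprazole",
      targets = list(
        drug_target("arp.DR.D2R.ago", "receptor_agonist", "DR.D2R"),
        drug_target("arp.DR.D2R.ant", "receptor_antagonist", "DR.D2R"),
        drug_target("arp.LC.D2R.ago", "receptor_agonist", "LC.D2R"),
        drug_target("arp.LC.D2R.ant", "receptor_antagonist", "LC.D2R"),
        drug_target("arp.VTA.D2R.ago", "receptor_agonist", "VTA.D2R"),
        drug_target("arp.VTA.D2R.ant", "receptor_antagonist", "VTA.D2R")
      )
    ),
    bup = list(
      name = "bup", label = "Bupropion",
      targets = list(
        drug_target("bup.NE", "releaser", "NE"),
        drug_target("bup.DA", "releaser", "DA")
      )
    ),
    quet = list(
      name = "quet", label = "Quetiapine",
      targets = list(
        drug_target("quet.NET", "reuptake_block", "NE"),
        drug_target("quet.LC.D2R", "receptor_antagonist", "LC.D2R"),
        drug_target("quet.VTA.D2R", "receptor_antagonist", "VTA.D2R"),
        drug_target("quet.LC.AR2", "receptor_antagonist", "LC.AR2")
      )
    )
  )
}

# all magnitude parameter ids defined by the active registry
registry_target_ids <- function(registry = drug_registry()) {
  unlist(lapply(registry, function(d) vapply(d$targets, `[[`, "", "id")),
         use.names = FALSE)
}

#' @rdname drug_registry
#' @param path YAML or JSON file describing drugs in the registry layout.
#' @return `read_drug_registry()` / `write_drug_registry()` read and write
#'   a registry file (the structure of [drug_registry()]).
#' @export
read_drug_registry <- function(path) {
  reg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = FALSE)
  stats::setNames(reg, vapply(reg, `[[`, "", "name"))
}

#' @rdname drug_registry
#' @param registry A registry list.
#' @export
write_drug_registry <- function(registry, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(unname(registry), path)
  } else {
    jsonlite::write_json(unname(registry), path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

# combination aliases matching the usual regimen abbreviations
regimen_aliases <- function() {
  list(
    EsNom = c("esc", "nom"), EsReb = c("esc", "reb"), EsTrz = c("esc", "trz"),
    EsAsn = c("esc", "asn"), EsArp = c("esc", "arp"), EsBup = c("esc", "bup"),
    EsQuet = c("esc", "quet")
  )
}

#' Build a maintained-drug regimen
#'
#' A regimen is the set of drugs (none, one, or two) maintained over the
#' whole simulated evaluation; the empty regimen is the no-drug baseline.
#' Drug names are registry keys (`"esc"`, `"reb"`, ...) or combination
#' aliases (`"EsArp"` = escitalopram + aripiprazole). Target magnitudes
#' are resolved from the parameter set at simulation time, never stored in
#' the regimen.
#'
#' @param ... Drug names and/or aliases (character).
#' @param registry Drug registry to resolve names in.
#' @return An object of class `mono_regimen`.
#' @export
regimen <- function(..., registry = drug_registry()) {
  nm <- unlist(list(...), use.names = FALSE)
  al <- regimen_aliases()
  nm <- unlist(lapply(nm, function(x) if (x %in% names(al)) al[[x]] else x))
  bad <- setdiff(nm, names(registry))
  if (length(bad)) stop("unknown drug(s): ", paste(bad, collapse = ", "))
  if (length(nm) > 2) stop("a regimen holds at most two maintained drugs")
  structure(list(drugs = registry[nm]), class = "mono_regimen")
}

#' @export
print.mono_regimen <- function(x, ...) {
  if (!length(x$drugs)) {
    cat("<mono_regimen>: no drug (baseline)\n")
  } else {
    cat("<mono_regimen>:", paste(vapply(x$drugs, `[[`, "", "label"), collapse = " + "), "\n")
  }
  invisible(x)
}

# gather regimen effects with magnitudes resolved from the parameter set:
# blockade/releaser per transmitter, antagonist factor and agonist sum per
# receptor site. Drugs compose symmetrically, so regimens commute.
regimen_effects <- function(params, reg) {
  eff <- list(
    blockade = stats::setNames(numeric(3), transported_transmitters()),
    releaser = stats::setNames(numeric(3), transported_transmitters()),
    antagonist = list(), agonist = list()
  )
  block_keep <- stats::setNames(rep(1, 3), transported_transmitters())
  for (d in reg$drugs) {
    for (tg in d$targets) {
      m <- params$drug_magnitudes[[tg$id]]
      if (is.null(m) || is.na(m)) stop("no magnitude in parameter set for drug target ", tg$id)
      switch(tg$mechanism,
        reuptake_block = {
          block_keep[tg$site] <- block_keep[tg$site] * (1 - m)
        },
        releaser = {
          eff$releaser[tg$site] <- eff$releaser[tg$site] + m
        },
        receptor_antagonist = {
          prev <- eff$antagonist[[tg$site]]
          eff$antagonist[[tg$site]] <- if (is.null(prev)) (1 - m) else prev * (1 - m)
        },
        receptor_agonist = {
          prev <- eff$agonist[[tg$site]]
          eff$agonist[[tg$site]] <- if (is.null(prev)) m else prev + m
        },
        stop("unknown drug mechanism: ", tg$mechanism)
      )
    }
  }
  eff$blockade <- 1 - block_keep
  eff
}

#' Effective transporter efficacy under reuptake blockade
#'
#' Blockades compose multiplicatively on the surviving efficacy:
#' `tau_eff = tau * prod(1 - b_i)`, so full blockade by any drug abolishes
#' reuptake and the effective efficacy never exceeds the drug-free one.
#'
#' @param tau Transporter efficacy in `[0, 1]`.
#' @param blockades Numeric vector of blockade magnitudes in `[0, 1]`.
#' @return Effective efficacy in `[0, tau]`.
#' @export
effective_transporter <- function(tau, blockades = numeric()) {
  if (!is.finite(tau) || tau < 0 || tau > 1) stop("transporter efficacy must lie in [0, 1]")
  if (length(blockades) && (any(!is.finite(blockades)) || any(blockades < 0) || any(blockades > 1))) {
    stop("blockade magnitudes must lie in [0, 1]")
  }
  tau * prod(1 - blockades)
}

#' Amount of transmitter presented to receptors
#'
#' Each unit releases its transmitter(s) in proportion to its activation.
#' For the transported monoamines (5HT, NE, DA) the presented amount is
#' `(activity + sum of releaser magnitudes) * (1 - tau_eff)`: reuptake
#' removes the fraction `tau_eff` of what was released, and releaser drugs
#' add to the pre-reuptake amount. Co-released galanin and glutamate and
#' CRF are presented at the releasing unit's activity unchanged.
#'
#' @param activity Source-unit activation in `[0, 1)`.
#' @param transmitter Transmitter id.
#' @param params A `mono_params` object.
#' @param reg A `mono_regimen` (default: no drug).
#' @return Non-negative presented amount.
#' @export
presented_amount <- function(activity, transmitter, params, reg = regimen()) {
  if (!transmitter %in% mono_transmitters()) stop("unknown transmitter: ", transmitter)
  if (!transmitter %in% transported_transmitters()) return(activity)
  eff <- regimen_effects(params, reg)
  tau_eff <- effective_transporter(params$transporters[[transmitter]],
                                   eff$blockade[[transmitter]])
  (activity + eff$releaser[[transmitter]]) * (1 - tau_eff)
}

#' Signed drive of one receptor connection
#'
#' The transmitter-bound drive is `polarity * strength * amount`, scaled
#' by `(1 - m)` for each antagonist bound at the site; direct agonists add
#' `polarity * strength * magnitude` independent of the transmitter.
#'
#' @param unit Target nucleus id.
#' @param receptor Receptor name at that nucleus.
#' @param amount Presented transmitter amount (non-negative).
#' @param params A `mono_params` object.
#' @param reg A `mono_regimen`.
#' @param include_agonist Whether to add the direct agonist occupancy term
#'   (set `FALSE` when summing a multi-source site where the term must be
#'   counted once).
#' @return Signed drive contribution.
#' @export
receptor_drive <- function(unit, receptor, amount, params, reg = regimen(),
                           include_agonist = TRUE) {
  site <- paste(unit, receptor, sep = ".")
  tab <- receptor_table()
  if (!site %in% tab$name) stop("unknown receptor site: ", site)
  pol <- tab[site, "polarity"]
  s <- params$receptors[[site]]
  eff <- regimen_effects(params, reg)
  keep <- eff$antagonist[[site]]
  if (is.null(keep)) keep <- 1
  drive <- pol * s * amount * keep
  if (include_agonist && !is.null(eff$agonist[[site]])) {
    drive <- drive + pol * s * eff$agonist[[site]]
  }
  drive
}

#' Extracellular monoamine levels from window-averaged activations
#'
#' The window-averaged activations of DR, LC, and VTA, together with the
#' effective transporter efficacies and any releaser drugs, determine the
#' average extracellular amounts of 5HT, NE, and DA respectively.
#'
#' @param summary An `activation_summary` (see [average_activation()]).
#' @param params A `mono_params` object.
#' @param reg The `mono_regimen` under which the summary was produced.
#' @return Named numeric vector `c("5HT"=, "NE"=, "DA"=)` of non-negative
#'   levels (arbitrary units).
#' @export
transmitter_levels <- function(summary, params, reg = regimen()) {
  act <- summary$means[mono_nuclei()]
  lv <- c(
    presented_amount(act[["DR"]], "5HT", params, reg),
    presented_amount(act[["LC"]], "NE", params, reg),
    presented_amount(act[["VTA"]], "DA", params, reg)
  )
  stats::setNames(lv, transported_transmitters())
}

#' Express a level as a percentage of its no-drug baseline
#'
#' @param level Non-negative level(s).
#' @param baseline Positive baseline level(s).
#' @return `100 * level / baseline` (vectorized).
#' @export
percent_of_baseline <- function(level, baseline) {
  if (any(baseline <= 0)) {
    stop("baseline level must be positive (degenerate parameterization)")
  }
  100 * level / baseline
}
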