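# Model topology: units, transmitters, receptor-mediated connections.
#
# The network has six units. Three are monoaminergic brain nuclei -- the
# dorsal raphe (DR, releases 5HT and co-releases galanin and glutamate),
# the locus coeruleus (LC, releases NE and co-releases galanin), and the
# ventral tegmental area (VTA, releases DA). Three are non-monoaminergic
# transmitter systems, each standing for the heterogeneous set of regions
# that release one transmitter: tCRF (CRF), Tgal (galanin), Tglu
# (glutamate). Connections onto monoaminergic units are mediated by the
# predominant receptor for each arriving transmitter and carry a signed
# strength; connections onto non-monoaminergic units are generic signed
# weights, one per source unit.

#' Unit identifiers of the monoamine network
#'
#' The six model units in canonical order: the three monoaminergic nuclei
#' (`DR`, `LC`, `VTA`) followed by the three non-monoaminergic transmitter
#' systems (`tCRF`, `Tgal`, `Tglu`).
#'
#' @return Character vector of length 6.
#' @export
mono_units <- function() c("DR", "LC", "VTA", "tCRF", "Tgal", "Tglu")

#' @rdname mono_units
#' @return For `mono_nuclei()`, the three monoaminergic unit ids.
#' @export
mono_nuclei <- function() c("DR", "LC", "VTA")

#' @rdname mono_units
#' @return For `mono_transmitters()`, the six transmitter ids.
#' @export
mono_transmitters <- function() c("5HT", "NE", "DA", "CRF", "gal", "glu")

# transmitters removed by a plasma-membrane transporter (reuptake)
transported_transmitters <- function() c("5HT", "NE", "DA")

# which transmitters each unit releases (amount proportional to activation)
released_by <- function() {
  list(
    DR   = c("5HT", "gal", "glu"),
    LC   = c("NE", "gal"),
    VTA  = "DA",
    tCRF = "CRF",
    Tgal = "gal",
    Tglu = "glu"
  )
}

#' Receptor-mediated connections onto the monoaminergic units
#'
#' Every transmitter-specific connection onto DR, LC, or VTA: the target
#' nucleus, the source unit, the transmitter carried, the receptor
#' mediating the effect, and the polarity of that effect (+1 excitatory,
#' -1 inhibitory). A receptor population on a nucleus has a single
#' strength parameter even when its transmitter arrives from more than one
#' source (e.g. galanin reaches DR galR1 from both LC and Tgal).
#'
#' @return A data.frame with columns `target`, `source`, `transmitter`,
#'   `receptor`, `polarity`.
#' @export
mono_connections <- function() {
  hit <- .topology_cache$connections
  if (!is.null(hit)) return(hit)
  conn <- rbind(
    # onto DR
    c("DR", "DR",   "5HT", "5HT1AR", -1),
    c("DR", "LC",   "NE",  "AR1",    +1),
    c("DR", "LC",   "gal", "galR1",  -1),
    c("DR", "LC",   "gal", "galR2",  +1),
    c("DR", "VTA",  "DA",  "D2R",    +1),
    c("DR", "tCRF", "CRF", "CRF1R",  -1),
    c("DR", "tCRF", "CRF", "CRF2R",  +1),
    c("DR", "Tgal", "gal", "galR1",  -1),
    c("DR", "Tgal", "gal", "galR2",  +1),
    c("DR", "Tglu", "glu", "AMPAR",  +1),
    # onto LC
    c("LC", "DR",   "glu", "AMPAR",  +1),
    c("LC", "DR",   "5HT", "5HT2AR", -1),
    c("LC", "DR",   "gal", "galR1",  -1),
    c("LC", "LC",   "NE",  "AR2",    -1),
    c("LC", "VTA",  "DA",  "D1R",    -1),
    c("LC", "VTA",  "DA",  "D2R",    +1),
    c("LC", "tCRF", "CRF", "CRF1R",  +1),
    c("LC", "Tgal", "gal", "galR1",  -1),
    c("LC", "Tglu", "glu", "AMPAR",  +1),
    # onto VTA
    c("VTA", "DR",   "glu", "AMPAR",  +1),
    c("VTA", "DR",   "5HT", "5HT2AR", +1),
    c("VTA", "DR",   "5HT", "5HT2CR", -1),
    c("VTA", "LC",   "NE",  "AR1",    +1),
    c("VTA", "LC",   "NE",  "AR2",    -1),
    c("VTA", "LC",   "gal", "galR1",  -1),
    c("VTA", "VTA",  "DA",  "D2R",    -1),
    c("VTA", "tCRF", "CRF", "CRF1R",  +1),
    c("VTA", "Tgal", "gal", "galR1",  -1),
    c("VTA", "Tglu", "glu", "AMPAR",  +1)
  )
  out <- data.frame(
    target = conn[, 1], source = conn[, 2], transmitter = conn[, 3],
    receptor = conn[, 4], polarity = as.numeric(conn[, 5]),
    stringsAsFactors = FALSE
  )
  .topology_cache$connections <- out
  out
}

# topology tables are immutable; build once per session
.topology_cache <- new.env(parent = emptyenv())

#' Receptor populations and the adjustable subset
#'
#' One row per (nucleus, receptor) strength parameter. Eleven receptor
#' populations are adjustable during neuroadaptation: the three
#' monoaminergic autoreceptors (DR 5HT1AR, LC AR2, VTA D2R) and specific
#' CRF, galanin, and glutamate receptors known to change strength under
#' chronic antidepressants (galR1 on DR and LC, galR2 on DR, CRF1R on DR,
#' LC, and VTA, CRF2R on DR, AMPAR on VTA).
#'
#' @return A data.frame with columns `unit`, `receptor`, `polarity`,
#'   `name` (the `unit.receptor` parameter label), and logical
#'   `adjustable`.
#' @export
receptor_table <- function() {
  hit <- .topology_cache$receptors
  if (!is.null(hit)) return(hit)
  conn <- mono_connections()
  key <- !duplicated(paste(conn$target, conn$receptor))
  tab <- data.frame(
    unit = conn$target[key], receptor = conn$receptor[key],
    polarity = conn$polarity[key], stringsAsFactors = FALSE
  )
  tab$name <- paste(tab$unit, tab$receptor, sep = ".")
  tab$adjustable <- tab$name %in% adjustable_receptors()
  rownames(tab) <- tab$name
  .topology_cache$receptors <- tab
  tab
}

#' @rdname receptor_table
#' @return For `adjustable_receptors()`, the names of the 11 adjustable
#'   receptor populations in canonical order: the three autoreceptors
#'   first, then the galanin, CRF, and glutamate receptors.
#' @export
adjustable_receptors <- function() {
  c(
    "DR.5HT1AR", "LC.AR2", "VTA.D2R",
    "DR.galR1", "LC.galR1", "DR.galR2",
    "DR.CRF1R", "LC.CRF1R", "VTA.CRF1R", "DR.CRF2R",
    "VTA.AMPAR"
  )
}

# names of the 18 generic weights onto the non-monoaminergic units
generic_weight_names <- function() {
  as.vector(t(outer(c("tCRF", "Tgal", "Tglu"), mono_units(), paste, sep = ".")))
}
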