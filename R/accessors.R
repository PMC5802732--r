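#' Accessors for atdkit S4 classes
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x an atdkit S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname accessors
#' @export
setMethod("structureId", "MacroStructure", function(x) x@id)

#' @rdname accessors
#' @export
setGeneric("atomRecords", function(x) standardGeneric("atomRecords"))

#' @rdname accessors
#' @export
setMethod("atomRecords", "MacroStructure", function(x) x@atoms)

#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' @rdname accessors
#' @export
setMethod("chainIds", "MacroStructure", function(x)
  unique(x@atoms$chain[!x@atoms$het]))

#' Count polymer residues across all chains
#'
#' Counts distinct (chain, resno, icode) triples among non-het atoms; the
#' number a crystallographic table reports as "No. of residues".
#'
#' @param x a `MacroStructure`.
#' @return integer(1)
#' @export
polymerResidueCount <- function(x) {
  stopifnot(is(x, "MacroStructure"))
  a <- x@atoms[!x@atoms$het, , drop = FALSE]
  if (!nrow(a)) return(0L)
  nrow(unique(a[, c("chain", "resno", "icode")]))
}

#' @rdname accessors
#' @export
setGeneric("rmsd", function(x) standardGeneric("rmsd"))

#' @rdname accessors
#' @export
setMethod("rmsd", "SuperpositionReport", function(x) x@rmsd)

#' @rdname accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname accessors
#' @export
setMethod("nPairs", "SuperpositionReport", function(x) x@n_pairs)

#' @rdname accessors
#' @export
setGeneric("rotationMatrix", function(x) standardGeneric("rotationMatrix"))

#' @rdname accessors
#' @export
setMethod("rotationMatrix", "SuperpositionReport", function(x) x@rotation)

#' @rdname accessors
#' @export
setGeneric("kObs", function(x) standardGeneric("kObs"))

#' @rdname accessors
#' @export
setMethod("kObs", "DecayFit", function(x) x@k_obs)

#' @rdname accessors
#' @export
setGeneric("familyOf", function(x) standardGeneric("familyOf"))

#' @rdname accessors
#' @export
setMethod("familyOf", "FamilyCall", function(x) x@family)

#' @rdname accessors
#' @export
setGeneric("motifOmega", function(x) standardGeneric("motifOmega"))

#' @rdname accessors
#' @export
setMethod("motifOmega", "MotifSite", function(x) x@omega)

#' @rdname accessors
#' @export
setGeneric("bondConformation", function(x) standardGeneric("bondConformation"))

#' @rdname accessors
#' @export
setMethod("bondConformation", "MotifSite", function(x) x@conformation)

#' @rdname accessors
#' @export
setGeneric("isCrossSubunit", function(x) standardGeneric("isCrossSubunit"))

#' @rdname accessors
#' @export
setMethod("isCrossSubunit", "MotifSite", function(x) x@cross_subunit)
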