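#' @import methods
NULL

#' MacroStructure: a macromolecular coordinate set
#'
#' Container for a parsed structure: one flat atom table plus free-form
#' header metadata. Polymer atoms, waters and other heteroatoms are kept in
#' the same table and distinguished by the `het` flag, so parse-level counts
#' remain available while all geometric operations work on the polymer only.
#'
#' The atom table has one row per atom with columns
#' `chain`, `resno` (author numbering), `icode`, `resname`, `atom`
#' (PDB atom label, e.g. `"CA"`), `element`, `x`, `y`, `z` (Angstrom),
#' `occ`, `b` (Angstrom^2), `altloc`, `het` (logical).
#'
#' @slot id character(1) structure identifier.
#' @slot atoms data.frame, one row per atom (columns above).
#' @slot meta list of free-form header fields.
#'
#' @seealso [readStructure()], [backboneTorsions()], [findGlyProMotifs()]
#' @export
setClass("MacroStructure",
  representation(id = "character", atoms = "data.frame", meta = "list"),
  prototype(id = NA_character_, meta = list())
)

.validMacroStructure <- function(object) {
  msg <- character()
  a <- object@atoms
  need <- c("chain", "resno", "icode", "resname", "atom", "element",
            "x", "y", "z", "occ", "b", "altloc", "het")
  miss <- setdiff(need, names(a))
  if (length(miss))
    msg <- c(msg, paste("atom table lacks columns:", paste(miss, collapse = ", ")))
  if (!length(msg)) {
    xyz <- as.matrix(a[, c("x", "y", "z")])
    if (nrow(a) && !all(is.finite(xyz)))
      msg <- c(msg, "non-finite coordinates")
    if (nrow(a) && any(a$occ < 0 | a$occ > 1, na.rm = TRUE))
      msg <- c(msg, "occupancy outside [0,1]")
    if (nrow(a) && any(a$b < 0, na.rm = TRUE))
      msg <- c(msg, "negative B-factor")
  }
  if (length(msg)) msg else TRUE
}
setValidity("MacroStructure", .validMacroStructure)

#' @describeIn MacroStructure compact display
#' @param object a `MacroStructure`
#' @export
setMethod("show", "MacroStructure", function(object) {
  a <- object@atoms
  pol <- a[!a$het, , drop = FALSE]
  ch <- unique(pol$chain)
  cat("MacroStructure", sQuote(object@id), "\n")
  cat(" ", length(ch), "polymer chain(s):", paste(ch, collapse = " "), "\n")
  cat(" ", nrow(pol), "polymer atoms,", sum(a$het), "heteroatoms (incl. waters)\n")
  cat(" ", polymerResidueCount(object), "polymer residues\n")
  invisible(object)
})

#' MotifSite: a located (possibly cross-subunit) Gly-Pro dipeptide
#'
#' Records a Gly immediately followed by Pro in a donor chain, the chain
#' whose active-site pocket receives it, and the cis/trans call on the
#' Gly-Pro peptide bond (the omega torsion of the Pro).
#'
#' @slot donor_chain chain contributing the Gly-Pro.
#' @slot acceptor_chain chain whose pocket (signature-motif match) is nearest.
#' @slot gly_resno,pro_resno author residue numbers of Gly and Pro.
#' @slot gly_icode,pro_icode insertion codes.
#' @slot cross_subunit logical; `TRUE` iff acceptor differs from donor.
#' @slot omega degrees in (-180, 180].
#' @slot conformation `"cis"` or `"trans"`.
#' @export
setClass("MotifSite",
  representation(donor_chain = "character", acceptor_chain = "character",
                 gly_resno = "integer", pro_resno = "integer",
                 gly_icode = "character", pro_icode = "character",
                 cross_subunit = "logical", omega = "numeric",
                 conformation = "character")
)

setValidity("MotifSite", function(object) {
  msg <- character()
  if (length(object@omega) == 1 && is.finite(object@omega) &&
      (object@omega <= -180 || object@omega > 180))
    msg <- c(msg, "omega outside (-180, 180]")
  if (!object@conformation %in% c("cis", "trans"))
    msg <- c(msg, "conformation must be 'cis' or 'trans'")
  if (!identical(object@cross_subunit,
                 !identical(object@donor_chain, object@acceptor_chain)))
    msg <- c(msg, "cross_subunit inconsistent with donor/acceptor chains")
  if (length(msg)) msg else TRUE
})

#' @describeIn MotifSite compact display
#' @param object a `MotifSite`
#' @export
setMethod("show", "MotifSite", function(object) {
  cat(sprintf("MotifSite: Gly%d-%sPro%d  donor %s -> acceptor %s%s  (omega %.1f deg)\n",
              object@gly_resno, object@conformation, object@pro_resno,
              object@donor_chain, object@acceptor_chain,
              if (object@cross_subunit) " [cross-subunit]" else "",
              object@omega))
  invisible(object)
})

#' SuperpositionReport: result of a (possibly iterative) Kabsch fit
#'
#' @slot rotation 3x3 proper rotation matrix (det = +1).
#' @slot translation length-3 numeric, Angstrom.
#' @slot rmsd root-mean-square deviation over retained pairs, Angstrom.
#' @slot n_pairs number of atom pairs retained.
#' @slot n_iterations pruning iterations performed (1 for a plain fit).
#' @export
setClass("SuperpositionReport",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric", n_pairs = "integer",
                 n_iterations = "integer")
)

setValidity("SuperpositionReport", function(object) {
  msg <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3, 3))) msg <- c(msg, "rotation must be 3x3")
  else {
    if (abs(det(R) - 1) > 1e-6) msg <- c(msg, "rotation must be proper (det = +1)")
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      msg <- c(msg, "rotation must be orthonormal")
  }
  if (object@rmsd < 0) msg <- c(msg, "rmsd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn SuperpositionReport compact display
#' @param object a `SuperpositionReport`
#' @export
setMethod("show", "SuperpositionReport", function(object) {
  cat(sprintf("SuperpositionReport: rmsd %.3f A over %d pairs (%d iteration%s)\n",
              object@rmsd, object@n_pairs, object@n_iterations,
              if (object@n_iterations == 1) "" else "s"))
  invisible(object)
})

#' FamilyCall: DTD/ATD classification of a protein sequence
#'
#' @slot family `"DTD"`, `"ATD"` or `"unknown"` (unknown iff score is 0).
#' @slot score integer; ATD-motif best hits minus DTD-motif best hits
#'   (each at most 1 mismatch).
#' @slot hits data.frame of motif hits (family, motif_index, pattern, start,
#'   matched, mismatches, best).
#' @slot anchors data.frame of located anchor residues (may have 0 rows).
#' @export
setClass("FamilyCall",
  representation(family = "character", score = "integer",
                 hits = "data.frame", anchors = "data.frame")
)

setValidity("FamilyCall", function(object) {
  msg <- character()
  if (!object@family %in% c("DTD", "ATD", "unknown"))
    msg <- c(msg, "family must be DTD, ATD or unknown")
  if ((object@score == 0L) != (object@family == "unknown"))
    msg <- c(msg, "family must be 'unknown' iff score is 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn FamilyCall compact display
#' @param object a `FamilyCall`
#' @export
setMethod("show", "FamilyCall", function(object) {
  cat(sprintf("FamilyCall: %s (score %+d, %d motif hit%s)\n",
              object@family, object@score, nrow(object@hits),
              if (nrow(object@hits) == 1) "" else "s"))
  invisible(object)
})

#' DecayFit: first-order deacylation fit S(t) = S0 * exp(-k t)
#'
#' @slot k_obs observed first-order rate constant, per minute (>= 0).
#' @slot s0 fitted initial fraction, in (0, 1.2].
#' @slot rmse root-mean-square residual on the fraction scale.
#' @slot converged logical; `FALSE` if the optimiser hit its iteration cap.
#' @export
setClass("DecayFit",
  representation(k_obs = "numeric", s0 = "numeric",
                 rmse = "numeric", converged = "logical")
)

setValidity("DecayFit", function(object) {
  msg <- character()
  if (object@k_obs < 0) msg <- c(msg, "k_obs must be >= 0")
  if (object@s0 <= 0 || object@s0 > 1.2) msg <- c(msg, "s0 must lie in (0, 1.2]")
  if (length(msg)) msg else TRUE
})

#' @describeIn DecayFit compact display
#' @param object a `DecayFit`
#' @export
setMethod("show", "DecayFit", function(object) {
  cat(sprintf("DecayFit: k_obs %.4g /min, S0 %.3f, rmse %.3g%s\n",
              object@k_obs, object@s0, object@rmse,
              if (object@converged) "" else " (not converged)"))
  invisible(object)
})
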