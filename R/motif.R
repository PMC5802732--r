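#' Locate Gly-Pro dipeptide motifs and assign their acceptor pockets
#'
#' Finds every Gly immediately followed by Pro (with an intact peptide bond)
#' in each polymer chain, classifies the bond cis/trans from the Pro omega
#' torsion, and assigns the acceptor chain as the chain whose active-site
#' pocket (the centroid of its signature motif-1 match) lies nearest the
#' Gly-Pro centroid. In the homodimeric deacylases this flags the motif as
#' cross-subunit: the dipeptide of one protomer sits in the pocket of the
#' other. Chains without a pocket-motif match fall back to their C-alpha
#' centroid.
#'
#' @param x a [MacroStructure-class].
#' @param pocket_motif character vector of degenerate patterns defining the
#'   pocket; defaults to the family motif-1 patterns (PQATL, SQFTL).
#' @param max_mismatch mismatch allowance for the pocket patterns.
#' @return list of [MotifSite-class] objects (possibly empty). Sites whose
#'   omega torsion is undefined are dropped with a warning.
#' @export
findGlyProMotifs <- function(x, pocket_motif = c("PQATL", "SQFTL"),
                             max_mismatch = 1L) {
  stopifnot(is(x, "MacroStructure"))
  chains <- chainIds(x)
  if (!length(chains)) stop("structure has no polymer chains")
  pockets <- lapply(chains, function(ch)
    .pocketCentroid(x, ch, pocket_motif, max_mismatch))
  names(pockets) <- chains
  sites <- list()
  for (ch in chains) {
    res <- .chainBackbone(x, ch)
    tor <- backboneTorsions(x, ch)
    n <- length(res)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      if (res[[i]]$resname != "GLY" || res[[i + 1]]$resname != "PRO") next
      om <- tor$omega[i + 1]
      if (is.na(om)) {
        warning("Gly-Pro at ", ch, res[[i]]$resno,
                " skipped: omega undefined")
        next
      }
      gp_cent <- .rowMeanNA(rbind(res[[i]]$CA, res[[i + 1]]$CA))
      d <- vapply(chains, function(cc) {
        p <- pockets[[cc]]
        if (is.null(p)) Inf else sqrt(sum((gp_cent - p)^2))
      }, numeric(1))
      acceptor <- chains[which.min(d)]
      sites[[length(sites) + 1L]] <- new("MotifSite",
        donor_chain = ch, acceptor_chain = acceptor,
        gly_resno = res[[i]]$resno, pro_resno = res[[i + 1]]$resno,
        gly_icode = res[[i]]$icode, pro_icode = res[[i + 1]]$icode,
        cross_subunit = !identical(acceptor, ch),
        omega = om, conformation = classifyPeptideBond(om))
    }
  }
  sites
}

.rowMeanNA <- function(m) {
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (!nrow(m)) return(rep(NA_real_, 3))
  colMeans(m)
}

# C-alpha centroid of the best pocket-motif match on a chain (NULL if none)
.pocketCentroid <- function(x, chain, patterns, max_mismatch = 1L) {
  seq <- chainSequence(x, chain)
  res <- .chainBackbone(x, chain)
  best <- NULL
  for (p in patterns) {
    hits <- .motifScan(seq, p, max_mismatch)
    if (!nrow(hits)) next
    h <- hits[which.min(hits$mismatches), ]
    if (is.null(best) || h$mismatches < best$mismatches)
      best <- list(start = h$start, len = nchar(p), mismatches = h$mismatches)
  }
  if (is.null(best)) {
    cas <- do.call(rbind, lapply(res, `[[`, "CA"))
    cent <- .rowMeanNA(cas)
    return(if (anyNA(cent)) NULL else cent)
  }
  idx <- (best$start + 1L):(best$start + best$len)
  cas <- do.call(rbind, lapply(res[idx], `[[`, "CA"))
  cent <- .rowMeanNA(cas)
  if (anyNA(cent)) NULL else cent
}

.siteResidues <- function(x, site) {
  res <- .chainBackbone(x, site@donor_chain)
  key <- paste(vapply(res, `[[`, integer(1), "resno"),
               vapply(res, `[[`, character(1), "icode"))
  gly <- res[[match(paste(site@gly_resno, site@gly_icode), key)]]
  pro <- res[[match(paste(site@pro_resno, site@pro_icode), key)]]
  list(gly = gly, pro = pro)
}

#' Carbonyl orientation of a Gly-Pro motif relative to its acceptor pocket
#'
#' The defining geometric difference between the two deacylase families:
#' with a cis bond the Gly and Pro carbonyl oxygens point in parallel into
#' the acceptor pocket ("outward parallel", the chiral-selectivity filter);
#' the trans bond flips them to point in parallel away from the pocket into
#' the protein core ("inward parallel"). The pocket axis is the unit vector
#' from the midpoint of the two carbonyl C atoms to the C-alpha centroid of
#' the acceptor chain's pocket-motif match; the label is `"non-parallel"`
#' when the two C=O unit vectors diverge by more than `parallel_threshold`,
#' otherwise outward/inward by the sign of their mean projection on the
#' pocket axis.
#'
#' @param site a [MotifSite-class].
#' @param x the [MacroStructure-class] containing it.
#' @param pocket_motif,max_mismatch pocket definition (as in
#'   [findGlyProMotifs()]).
#' @param parallel_threshold degrees; default 45.
#' @return list with `parallelism_angle` (degrees, in `[0, 180]`),
#'   `mean_projection` (dimensionless) and `label`.
#' @export
carbonylOrientation <- function(site, x, pocket_motif = c("PQATL", "SQFTL"),
                                max_mismatch = 1L, parallel_threshold = 45) {
  stopifnot(is(site, "MotifSite"), is(x, "MacroStructure"))
  sr <- .siteResidues(x, site)
  if (anyNA(sr$gly$O) || anyNA(sr$pro$O) || anyNA(sr$gly$C) || anyNA(sr$pro$C))
    stop("orientation undefined: missing carbonyl C/O atoms")
  u1 <- .unit(sr$gly$O - sr$gly$C)
  u2 <- .unit(sr$pro$O - sr$pro$C)
  pocket <- .pocketCentroid(x, site@acceptor_chain, pocket_motif, max_mismatch)
  if (is.null(pocket)) stop("orientation undefined: acceptor pocket unresolvable")
  mid <- (sr$gly$C + sr$pro$C) / 2
  axis <- .unit(pocket - mid)
  ang <- acos(max(-1, min(1, sum(u1 * u2)))) * 180 / pi
  proj <- mean(c(sum(u1 * axis), sum(u2 * axis)))
  label <- if (ang > parallel_threshold) "non-parallel"
           else if (proj > 0) "outward-parallel" else "inward-parallel"
  list(parallelism_angle = ang, mean_projection = proj, label = label)
}

.unit <- function(v) v / sqrt(sum(v^2))

#' B-factor rigidity of a Gly-Pro motif
#'
#' Compares the mean backbone B-factor of the motif (Gly + Pro, atoms
#' N/CA/C/O) with the backbone of the whole donor chain, as a z-score.
#' Negative values indicate the motif is more rigid than its chain, the
#' signature of the conformationally locked Gly-Pro in both families.
#'
#' @param x a [MacroStructure-class] with B-factors.
#' @param site a [MotifSite-class].
#' @return list with `motif_mean_b`, `chain_mean_b`, `chain_sd_b`, `motif_z`.
#' @export
motifRigidity <- function(x, site) {
  stopifnot(is(x, "MacroStructure"), is(site, "MotifSite"))
  a <- x@atoms
  bb <- a[!a$het & a$chain == site@donor_chain &
            a$atom %in% c("N", "CA", "C", "O"), , drop = FALSE]
  if (!nrow(bb)) stop("no backbone atoms in donor chain")
  in_motif <- (bb$resno == site@gly_resno & bb$icode == site@gly_icode) |
              (bb$resno == site@pro_resno & bb$icode == site@pro_icode)
  if (all(bb$b == 0))
    stop("all-zero B-factors: rigidity undefined")
  chain_sd <- stats::sd(bb$b)
  motif_mean <- mean(bb$b[in_motif])
  chain_mean <- mean(bb$b)
  # a uniform (nonzero) B-field carries no rigidity signal: z is 0 there
  z <- if (is.finite(chain_sd) && chain_sd > 0)
    (motif_mean - chain_mean) / chain_sd else 0
  list(motif_mean_b = motif_mean, chain_mean_b = chain_mean,
       chain_sd_b = chain_sd, motif_z = z)
}

#' Side-chain contacts between a probe residue and a Gly-Pro motif
#'
#' Reports every side-chain heavy atom of the probe residue within `cutoff`
#' of a backbone atom (N/CA/C/O) of the motif's Gly or Pro, with a flag for
#' whether the probe belongs to the motif's own donor chain (same monomer)
#' or to the dimeric counterpart. This is the interaction that locks the
#' motif conformation: in DTD an arginine of the same monomer, in ATD an
#' arginine of the partner subunit.
#'
#' @param x a [MacroStructure-class].
#' @param probe_chain,probe_resno,probe_icode the probe residue.
#' @param site a [MotifSite-class].
#' @param cutoff Angstrom, default 3.5.
#' @return data.frame with columns `donor_atom`, `acceptor_residue`,
#'   `acceptor_atom`, `distance`, `same_chain` (0 rows if none).
#' @export
motifContacts <- function(x, probe_chain, probe_resno, probe_icode = "",
                          site, cutoff = 3.5) {
  stopifnot(is(x, "MacroStructure"), is(site, "MotifSite"))
  a <- x@atoms[!x@atoms$het, , drop = FALSE]
  probe <- a[a$chain == probe_chain & a$resno == probe_resno &
               a$icode == probe_icode, , drop = FALSE]
  if (!nrow(probe)) stop("probe residue not found: ",
                         probe_chain, probe_resno)
  side <- probe[!probe$atom %in% c("N", "CA", "C", "O") &
                  probe$element != "H", , drop = FALSE]
  motif <- a[a$chain == site@donor_chain &
               ((a$resno == site@gly_resno & a$icode == site@gly_icode) |
                (a$resno == site@pro_resno & a$icode == site@pro_icode)) &
               a$atom %in% c("N", "CA", "C", "O"), , drop = FALSE]
  out <- data.frame(donor_atom = character(0), acceptor_residue = character(0),
                    acceptor_atom = character(0), distance = numeric(0),
                    same_chain = logical(0), stringsAsFactors = FALSE)
  if (!nrow(side) || !nrow(motif)) return(out)
  for (i in seq_len(nrow(side))) for (j in seq_len(nrow(motif))) {
    d <- sqrt((side$x[i] - motif$x[j])^2 + (side$y[i] - motif$y[j])^2 +
                (side$z[i] - motif$z[j])^2)
    if (d <= cutoff)
      out <- rbind(out, data.frame(
        donor_atom = side$atom[i],
        acceptor_residue = paste0(motif$resname[j], motif$resno[j]),
        acceptor_atom = motif$atom[j], distance = d,
        same_chain = identical(probe_chain, site@donor_chain),
        stringsAsFactors = FALSE))
  }
  out
}
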