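#' Signed dihedral angle of four points
#'
#' Standard IUPAC convention: looking along the p2->p3 bond, the angle from
#' the (p1,p2,p3) plane to the (p2,p3,p4) plane, positive clockwise; the
#' sign comes from the scalar triple product. A planar cis arrangement
#' (p1 and p4 on the same side) gives 0, anti gives 180.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates (Angstrom).
#' @return angle in degrees, in (-180, 180].
#' @examples
#' dihedralAngle(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)) # 0 (cis)
#' dihedralAngle(c(0,0,0), c(1,0,0), c(1,1,0), c(2,1,0)) # 180 (anti)
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sum(b1^2) == 0 || sum(b2^2) == 0 || sum(b3^2) == 0)
    stop("undefined angle: coincident consecutive points")
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("undefined angle: collinear consecutive bonds")
  m1 <- .cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Backbone atom coordinates for one chain: list with per-residue matrices.
# Returns residues in file order with N/CA/C/O coordinate rows (NA if absent).
.chainBackbone <- function(x, chain) {
  a <- x@atoms
  a <- a[!a$het & a$chain == chain, , drop = FALSE]
  if (!nrow(a)) stop("chain not found: ", chain)
  key <- paste(a$resno, a$icode, sep = "\r")
  resk <- unique(key)
  get1 <- function(sub, nm) {
    i <- which(sub$atom == nm)
    if (length(i)) c(sub$x[i[1]], sub$y[i[1]], sub$z[i[1]]) else rep(NA_real_, 3)
  }
  res <- lapply(resk, function(k) {
    sub <- a[key == k, , drop = FALSE]
    list(resno = sub$resno[1], icode = sub$icode[1], resname = sub$resname[1],
         N = get1(sub, "N"), CA = get1(sub, "CA"),
         C = get1(sub, "C"), O = get1(sub, "O"))
  })
  res
}

#' Backbone torsion angles (phi, psi, omega) of a chain
#'
#' One row per residue. Conventions: `phi(i)` = C(i-1)-N(i)-CA(i)-C(i);
#' `psi(i)` = N(i)-CA(i)-C(i)-N(i+1); `omega(i)` = CA(i-1)-C(i-1)-N(i)-CA(i),
#' i.e. omega belongs to the peptide bond *preceding* residue i, so the
#' cis/trans state of a Gly-Pro bond is the omega of the Pro. Angles are
#' undefined (`NA`) at chain termini, where backbone atoms are missing, and
#' across chain breaks (C(i-1)-N(i) distance > 2.5 Angstrom).
#'
#' @param x a [MacroStructure-class].
#' @param chain chain identifier.
#' @return data.frame with columns `chain`, `resno`, `icode`, `resname`,
#'   `phi`, `psi`, `omega` (degrees in (-180, 180] or `NA`).
#' @seealso [classifyPeptideBond()]
#' @export
backboneTorsions <- function(x, chain) {
  stopifnot(is(x, "MacroStructure"))
  res <- .chainBackbone(x, chain)
  n <- length(res)
  ang <- function(a, b, c_, d) {
    if (anyNA(c(a, b, c_, d))) return(NA_real_)
    tryCatch(dihedralAngle(a, b, c_, d), error = function(e) NA_real_)
  }
  linked <- function(i) { # peptide bond between residue i-1 and i intact?
    if (i < 2) return(FALSE)
    ci <- res[[i - 1]]$C; ni <- res[[i]]$N
    if (anyNA(ci) || anyNA(ni)) return(FALSE)
    sqrt(sum((ci - ni)^2)) <= 2.5
  }
  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r <- res[[i]]
    if (linked(i)) {
      phi[i] <- ang(res[[i - 1]]$C, r$N, r$CA, r$C)
      omega[i] <- ang(res[[i - 1]]$CA, res[[i - 1]]$C, r$N, r$CA)
    }
    if (i < n && linked(i + 1))
      psi[i] <- ang(r$N, r$CA, r$C, res[[i + 1]]$N)
  }
  data.frame(
    chain = chain,
    resno = vapply(res, `[[`, integer(1), "resno"),
    icode = vapply(res, `[[`, character(1), "icode"),
    resname = vapply(res, `[[`, character(1), "resname"),
    phi = phi, psi = psi, omega = omega,
    stringsAsFactors = FALSE
  )
}

#' Classify a peptide bond as cis or trans from its omega torsion
#'
#' cis iff omega lies in (-90, +90]; trans otherwise. The boundary is the
#' symmetric midpoint between the ideal cis (0) and trans (180) geometries,
#' making the call a total function of omega on (-180, 180].
#'
#' @param omega torsion in degrees (vectorised).
#' @return character vector, `"cis"` or `"trans"`.
#' @examples
#' classifyPeptideBond(c(5, -178)) # "cis" "trans"
#' @export
classifyPeptideBond <- function(omega) {
  if (any(is.na(omega)))
    stop("classification refused: omega undefined")
  ifelse(omega > -90 & omega <= 90, "cis", "trans")
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares optimal proper rotation and translation mapping `coords_b`
#' onto `coords_a`, via SVD of the covariance matrix with the usual sign
#' correction that excludes reflections.
#'
#' @param coords_a,coords_b n x 3 numeric matrices of paired points.
#' @return a [SuperpositionReport-class] with `n_iterations = 1`.
#' @export
kabschSuperpose <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  stopifnot(ncol(A) == 3, ncol(B) == 3, nrow(A) == nrow(B))
  if (nrow(A) < 3) stop("underdetermined: need >= 3 paired points")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  if (min(svd(Ac)$d[2], svd(Bc)$d[2]) < 1e-8)
    stop("underdetermined: collinear point set")
  H <- crossprod(Bc, Ac)       # maps B-frame onto A-frame
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Brot <- Bc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Ac - Brot)^2)))
  new("SuperpositionReport",
      rotation = R, translation = as.numeric(ca - R %*% cb),
      rmsd = rmsd, n_pairs = nrow(A), n_iterations = 1L)
}

.AA321 <- c(ALA="A", ARG="R", ASN="N", ASP="D", CYS="C", GLN="Q", GLU="E",
            GLY="G", HIS="H", ILE="I", LEU="L", LYS="K", MET="M", PHE="F",
            PRO="P", SER="S", THR="T", TRP="W", TYR="Y", VAL="V", MSE="M")

.AA123 <- structure(names(.AA321)[1:20], names = .AA321[1:20])

#' One-letter amino-acid sequence of a chain
#'
#' @param x a [MacroStructure-class].
#' @param chain chain identifier.
#' @return character(1); unknown residue types become `"X"`.
#' @export
chainSequence <- function(x, chain) {
  res <- .chainBackbone(x, chain)
  aa <- .AA321[vapply(res, `[[`, character(1), "resname")]
  paste(ifelse(is.na(aa), "X", aa), collapse = "")
}

#' Sequence-guided iterative superposition of two structures
#'
#' Pairs C-alpha atoms by global sequence alignment (BLOSUM62, affine gaps)
#' of the chain sequences, matching chains greedily by alignment score, then
#' alternates Kabsch superposition with pruning of pairs deviating by more
#' than `prune_cutoff` until the retained set is stable. The rmsd and pair
#' count are non-increasing across pruning iterations.
#'
#' @param a,b [MacroStructure-class] objects (b is fitted onto a).
#' @param prune_cutoff per-pair deviation cutoff in Angstrom (default 3.5);
#'   `Inf` disables pruning.
#' @param max_iter iteration cap.
#' @return a [SuperpositionReport-class].
#' @export
alignSuperpose <- function(a, b, prune_cutoff = 3.5, max_iter = 50L) {
  stopifnot(is(a, "MacroStructure"), is(b, "MacroStructure"))
  cha <- chainIds(a); chb <- chainIds(b)
  # score all chain pairs, match greedily
  combos <- expand.grid(ca = cha, cb = chb, stringsAsFactors = FALSE)
  combos$score <- -Inf
  alns <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sa <- gsub("X", "A", chainSequence(a, combos$ca[i]))
    sb <- gsub("X", "A", chainSequence(b, combos$cb[i]))
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(sa), Biostrings::AAString(sb), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    combos$score[i] <- Biostrings::score(al)
    alns[[i]] <- al
  }
  pairs_a <- NULL; pairs_b <- NULL
  used_a <- character(); used_b <- character()
  for (i in order(-combos$score)) {
    if (combos$ca[i] %in% used_a || combos$cb[i] %in% used_b) next
    used_a <- c(used_a, combos$ca[i]); used_b <- c(used_b, combos$cb[i])
    m <- .alignedIndexPairs(alns[[i]])
    if (!nrow(m)) next
    ra <- .chainBackbone(a, combos$ca[i]); rb <- .chainBackbone(b, combos$cb[i])
    for (j in seq_len(nrow(m))) {
      caa <- ra[[m[j, 1]]]$CA; cab <- rb[[m[j, 2]]]$CA
      if (!anyNA(caa) && !anyNA(cab)) {
        pairs_a <- rbind(pairs_a, caa); pairs_b <- rbind(pairs_b, cab)
      }
    }
  }
  if (is.null(pairs_a) || nrow(pairs_a) < 3)
    stop("alignment failure: no alignable residues with C-alpha atoms")
  keep <- seq_len(nrow(pairs_a))
  fit <- NULL
  for (iter in seq_len(max_iter)) {
    fit <- kabschSuperpose(pairs_a[keep, , drop = FALSE],
                           pairs_b[keep, , drop = FALSE])
    if (!is.finite(prune_cutoff)) break
    moved <- sweep(pairs_b[keep, , drop = FALSE] %*% t(fit@rotation), 2,
                   fit@translation, `+`)
    dev <- sqrt(rowSums((pairs_a[keep, , drop = FALSE] - moved)^2))
    retain <- dev <= prune_cutoff
    if (all(retain) || sum(retain) < 3) break
    keep <- keep[retain]
  }
  new("SuperpositionReport",
      rotation = fit@rotation, translation = fit@translation,
      rmsd = fit@rmsd, n_pairs = length(keep), n_iterations = iter)
}

# residue-index pairs (pattern, subject) for non-gap aligned columns
.alignedIndexPairs <- function(al) {
  pa <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  su <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  ia <- Biostrings::start(Biostrings::pattern(al)) - 1L
  ib <- Biostrings::start(Biostrings::subject(al)) - 1L
  out <- matrix(integer(0), ncol = 2)
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ia <- ia + 1L
    if (su[k] != "-") ib <- ib + 1L
    if (pa[k] != "-" && su[k] != "-") out <- rbind(out, c(ia, ib))
  }
  out
}
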