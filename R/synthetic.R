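#' @name synthetic
#' @title Synthetic-data generators
#' @description
#' Generators for every input the analysis stages consume: peptide/dimer
#' structures with prescribed backbone dihedrals, family sequences with
#' embedded signature motifs, tRNA gene sets with controlled G4:U69
#' frequency, exponential-decay time courses, and presence/absence tables
#' with controlled concordance. All are deterministic given their seed and
#' use an isolated RNG stream, so adding draws in one generator never
#' perturbs another.
NULL

# run expr under a local RNG stream seeded with `seed`
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Ideal backbone geometry (Angstrom / degrees). Exact values only affect
# round-trip stability, not any biological conclusion.
.IDEAL <- list(
  b_N_CA = 1.458, b_CA_C = 1.525, b_C_N = 1.329, b_C_O = 1.231,
  b_CA_CB = 1.530,
  a_N_CA_C = 111.2, a_CA_C_N = 116.2, a_C_N_CA = 121.7,
  a_CA_C_O = 120.5, a_C_CA_CB = 110.1, t_N_C_CA_CB = -122.6
)

# Natural-extension reference frame: place D given A-B-C with bond |CD| = r,
# angle B-C-D = theta, torsion A-B-C-D = chi (degrees).
.nerf <- function(a, b, c_, r, theta, chi) {
  th <- theta * pi / 180; ch <- -chi * pi / 180
  bc <- .unit(c_ - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d_local <- r * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  c_ + cbind(bc, m, n) %*% d_local
}

#' Build a peptide chain (or dimer) from backbone dihedrals
#'
#' Sequential internal-coordinate (NeRF) construction with ideal bond
#' lengths and angles; recomputing torsions with [backboneTorsions()]
#' returns the prescribed values to better than 1e-6 degrees. Conventions
#' match [backboneTorsions()]: `omega[i]` is the bond preceding residue i
#' (so `omega[1]` and `phi[1]` are unused, as is `psi[n]` except to place
#' the terminal carbonyl O). Atoms built: N, CA, C, O and (except Gly) CB.
#'
#' With `dimer = TRUE` a second chain is added as a rigid copy, placed by a
#' two-fold rotation that drops each chain's first Gly-Pro dipeptide next to
#' the partner chain's pocket (its signature motif-1 match), emulating the
#' cross-subunit motif of the homodimeric deacylases.
#'
#' @param sequence one-letter amino-acid string (or vector of 3-letter
#'   codes).
#' @param phi,psi,omega per-residue torsions in degrees, recycled to the
#'   sequence length.
#' @param bfactor per-residue B-factors, recycled (default 20).
#' @param chain chain id for the (first) chain.
#' @param dimer logical; add the rigid-copy partner chain `"B"`.
#' @param dimer_offset Angstrom separation added along the dyad axis
#'   (default 5).
#' @param id structure identifier.
#' @return a [MacroStructure-class].
#' @examples
#' helix <- buildPeptide("AAAAA", phi = -57, psi = -47, omega = 180)
#' backboneTorsions(helix, "A")
#' @export
buildPeptide <- function(sequence, phi = -120, psi = 130, omega = 180,
                         bfactor = 20, chain = "A", dimer = FALSE,
                         dimer_offset = 5, id = "synthetic") {
  res3 <- if (all(toupper(sequence) %in% names(.AA321))) {
    toupper(sequence)                       # vector of 3-letter codes
  } else {
    unname(.AA123[strsplit(paste(sequence, collapse = ""), "")[[1]]])
  }
  if (anyNA(res3)) stop("unknown residue letter in sequence")
  n <- length(res3)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  bfactor <- rep_len(bfactor, n)
  g <- .IDEAL
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_N_CA, 0, 0)
  a1 <- (180 - g$a_N_CA_C) * pi / 180
  C[1, ] <- CA[1, ] + g$b_CA_C * c(cos(a1), sin(a1), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- .nerf(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                      g$b_C_N, g$a_CA_C_N, psi[i - 1])
      CA[i, ] <- .nerf(CA[i - 1, ], C[i - 1, ], N[i, ],
                       g$b_N_CA, g$a_C_N_CA, omega[i])
      C[i, ] <- .nerf(C[i - 1, ], N[i, ], CA[i, ],
                      g$b_CA_C, g$a_N_CA_C, phi[i])
    }
    O[i, ] <- .nerf(N[i, ], CA[i, ], C[i, ],
                    g$b_C_O, g$a_CA_C_O, psi[i] + 180)
    if (res3[i] != "GLY")
      CB[i, ] <- .nerf(N[i, ], C[i, ], CA[i, ],
                       g$b_CA_CB, g$a_C_CA_CB, g$t_N_C_CA_CB)
  }
  rows <- list()
  emit <- function(i, nm, el, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = i, icode = "", resname = res3[i], atom = nm,
      element = el, x = xyz[1], y = xyz[2], z = xyz[3], occ = 1,
      b = bfactor[i], altloc = "", het = FALSE, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    emit(i, "N", "N", N[i, ]); emit(i, "CA", "C", CA[i, ])
    emit(i, "C", "C", C[i, ]); emit(i, "O", "O", O[i, ])
    if (res3[i] != "GLY") emit(i, "CB", "C", CB[i, ])
  }
  atoms <- do.call(rbind, rows)
  x <- new("MacroStructure", id = id, atoms = atoms, meta = list())
  if (dimer) x <- .addDimerPartner(x, dimer_offset)
  x
}

# Two-fold ("C2") placement of the partner chain: rotate 180 degrees about
# an axis through the midpoint of chain A's Gly-Pro and pocket centroids,
# perpendicular to their connecting vector, then shift along the axis. This
# maps each chain's Gly-Pro next to the other chain's pocket.
.addDimerPartner <- function(x, offset = 5) {
  a <- x@atoms
  ch <- a$chain[1]
  seq1 <- chainSequence(x, ch)
  gp_at <- regexpr("GP", seq1)[1]
  if (gp_at < 0) stop("dimer placement needs a Gly-Pro dipeptide in the chain")
  res <- .chainBackbone(x, ch)
  gp <- .rowMeanNA(rbind(res[[gp_at]]$CA, res[[gp_at + 1]]$CA))
  pk <- .pocketCentroid(x, ch, c("PQATL", "SQFTL"), 1L)
  v <- pk - gp
  if (sqrt(sum(v^2)) < 1e-6) stop("degenerate pocket/motif geometry")
  e <- if (abs(v[1]) < 0.9 * sqrt(sum(v^2))) c(1, 0, 0) else c(0, 1, 0)
  u <- .unit(.cross3(v, e))
  m <- (gp + pk) / 2
  R <- 2 * tcrossprod(u) - diag(3)           # 180-degree rotation, det +1
  b <- a
  xyz <- t(R %*% (t(as.matrix(a[, c("x", "y", "z")])) - m) + m + offset * u)
  b$x <- xyz[, 1]; b$y <- xyz[, 2]; b$z <- xyz[, 3]
  b$chain <- "B"
  out <- x
  out@atoms <- rbind(a, b)
  out
}

#' Generate protein sequences of a deacylase family
#'
#' Random background sequences with the family's two signature motifs
#' embedded at fixed offsets (motif 1 at position 41, motif 2 at 71,
#' 1-based). Point mutations at `mutation_rate` are applied to background
#' positions only, so motifs stay within the classifier's mismatch
#' allowance.
#'
#' @param n number of sequences.
#' @param family `"DTD"` or `"ATD"`.
#' @param mutation_rate per-site substitution probability in `[0, 0.3]`.
#' @param seed integer seed.
#' @param length sequence length (default 160).
#' @return data.frame with columns `id`, `family`, `sequence`.
#' @export
genFamilySequences <- function(n, family = c("ATD", "DTD"),
                               mutation_rate = 0, seed = 1, length = 160) {
  family <- match.arg(family)
  stopifnot(mutation_rate >= 0, mutation_rate <= 0.3, length >= 80)
  pats <- defaultMotifPatterns()
  m1 <- pats$pattern[pats$family == family & pats$motif_index == 1]
  m2 <- sub("\\.", "A", pats$pattern[pats$family == family &
                                       pats$motif_index == 2])
  aa <- strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1]]  # no P: avoid stray GP/motifs
  .withSeed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      s <- sample(aa, length, replace = TRUE)
      mut <- stats::runif(length) < mutation_rate
      s[mut] <- sample(aa, sum(mut), replace = TRUE)
      s[41:(40 + nchar(m1))] <- strsplit(m1, "")[[1]]
      s[71:(70 + nchar(m2))] <- strsplit(m2, "")[[1]]
      paste(s, collapse = "")
    }, character(1))
    data.frame(id = sprintf("%s_synth_%03d", family, seq_len(n)),
               family = family, sequence = seqs, stringsAsFactors = FALSE)
  })
}

.ANTICODON <- c(Ala = "AGC", Cys = "GCA", Gly = "GCC", Thr = "AGU",
                Ser = "AGA", Leu = "AAG", Val = "AAC", Ile = "AAU")

.WC <- c(A = "U", U = "A", G = "C", C = "G")

#' Generate a synthetic tRNA gene set with controlled G4:U69 frequency
#'
#' Canonical 73-nt mature genes (72 numbered positions plus discriminator,
#' no 3' CCA): a 7-bp Watson-Crick acceptor stem, with the pair-4 G:U
#' wobble inserted with the stated per-isotype probability, and random
#' filler for the D/T/anticodon arms (no attempt at full cloverleaf
#' realism). Scores are Gaussian.
#'
#' @param n_per_isotype named integer vector, genes per isotype.
#' @param wobble_prob named numeric vector, per-isotype probability that a
#'   gene carries G4:U69 (missing isotypes default to 0).
#' @param score_dist `c(mean, sd)` of tRNAscan-SE-like scores (default
#'   70, 10).
#' @param organism organism label.
#' @param seed integer seed.
#' @return data.frame in [readTRNATable()] layout.
#' @export
genTRNASet <- function(n_per_isotype, wobble_prob = numeric(0),
                       score_dist = c(70, 10), organism = "Synthetic organism",
                       seed = 1) {
  stopifnot(!is.null(names(n_per_isotype)))
  if (length(wobble_prob))
    stopifnot(all(wobble_prob >= 0), all(wobble_prob <= 1))
  nt <- c("A", "C", "G", "U")
  .withSeed(seed, {
    rows <- list()
    for (iso in names(n_per_isotype)) {
      p <- if (iso %in% names(wobble_prob)) wobble_prob[[iso]] else 0
      for (j in seq_len(n_per_isotype[[iso]])) {
        s <- sample(nt, 73, replace = TRUE)
        # avoid stems whose 3' end happens to spell CCA: the numbering
        # convention would strip it as a mature-tRNA CCA tail
        repeat {
          stem5 <- sample(nt, 7, replace = TRUE)
          if (!(stem5[1] == "G" && stem5[2] == "G")) break
        }
        s[1:7] <- stem5
        s[73 - (1:7)] <- .WC[stem5]          # pair i <-> 73 - i
        if (stats::runif(1) < p) { s[4] <- "G"; s[69] <- "U" }
        s[73] <- "A"                          # discriminator
        rows[[length(rows) + 1L]] <- data.frame(
          organism = organism, isotype = iso,
          anticodon = .ANTICODON[[iso]] %||% "NNN",
          score = stats::rnorm(1, score_dist[1], score_dist[2]),
          sequence = paste(s, collapse = ""), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate exponential-decay time courses with Gaussian noise
#'
#' Fractions are s0 * exp(-k t) plus Gaussian noise, clipped to `[0, 1.2]`.
#'
#' @param k first-order rate constant, per minute.
#' @param s0 initial fraction (default 1).
#' @param timepoints minutes.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param n_rep number of replicate series.
#' @param seed integer seed.
#' @return data.frame with columns `rep`, `t_min`, `fraction_remaining`.
#' @export
genDecaySeries <- function(k, s0 = 1, timepoints = 0:7 * 2, noise_sd = 0,
                           n_rep = 1, seed = 1) {
  stopifnot(noise_sd >= 0, k >= 0)
  .withSeed(seed, {
    out <- lapply(seq_len(n_rep), function(r) {
      y <- s0 * exp(-k * timepoints) +
        stats::rnorm(length(timepoints), 0, noise_sd)
      data.frame(rep = r, t_min = timepoints,
                 fraction_remaining = pmin(1.2, pmax(0, y)))
    })
    do.call(rbind, out)
  })
}

#' Generate a deacylation dose ladder for one substrate
#'
#' Long-format kinetics table across enzyme concentrations with a rate
#' proportional to enzyme concentration, k(c) = `k_per_nM` * c, optionally
#' scaled down by an EF-Tu protection factor (EF-Tu occupancy shielding the
#' substrate reduces the accessible fraction and hence the observed rate).
#'
#' @param substrate substrate label.
#' @param concs enzyme concentrations, nM.
#' @param k_per_nM rate per nM of enzyme, per minute.
#' @param timepoints minutes.
#' @param eftu `"none"`, `"unactivated"` or `"activated"`.
#' @param protection fold reduction of k when EF-Tu is present (default 1).
#' @param noise_sd Gaussian noise sd.
#' @param seed integer seed.
#' @return long-format data.frame (`substrate`, `enzyme_conc_nM`, `eftu`,
#'   `t_min`, `fraction_remaining`).
#' @export
genDoseSeries <- function(substrate, concs, k_per_nM,
                          timepoints = 0:6 * 5, eftu = "none",
                          protection = 1, noise_sd = 0, seed = 1) {
  stopifnot(protection >= 1)
  .withSeed(seed, {
    out <- lapply(concs, function(cc) {
      k <- k_per_nM * cc / (if (eftu == "none") 1 else protection)
      y <- exp(-k * timepoints) + stats::rnorm(length(timepoints), 0, noise_sd)
      data.frame(substrate = substrate, enzyme_conc_nM = cc, eftu = eftu,
                 t_min = timepoints,
                 fraction_remaining = pmin(1.2, pmax(0, y)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Generate an organism presence/enrichment table with known concordance
#'
#' Each organism is assigned an "enriched" state (fair coin) and an ATD
#' presence state that agrees with it with probability `concordance`.
#' Enriched organisms get tRNA-Thr G4:U69 gene fractions in the 20-40%
#' band observed across chordates; non-enriched ones 0-5%.
#'
#' @param n_organisms number of organisms (>= 1).
#' @param concordance probability in `[0, 1]` that the two states agree.
#' @param n_genes tRNA-Thr genes per organism (default 20).
#' @param seed integer seed.
#' @return list with `enrichment` (data.frame as from [wobbleEnrichment()])
#'   and `presence` (named logical vector).
#' @export
genPresenceTable <- function(n_organisms, concordance = 1, n_genes = 20,
                             seed = 1) {
  stopifnot(concordance >= 0, concordance <= 1, n_organisms >= 1)
  .withSeed(seed, {
    orgs <- sprintf("Organism_%03d", seq_len(n_organisms))
    enriched <- stats::runif(n_organisms) < 0.5
    agree <- stats::runif(n_organisms) < concordance
    atd <- ifelse(agree, enriched, !enriched)
    n_wob <- ifelse(enriched,
                    sample(seq(ceiling(0.2 * n_genes), floor(0.4 * n_genes)),
                           n_organisms, replace = TRUE),
                    sample(0:floor(0.05 * n_genes), n_organisms,
                           replace = TRUE))
    enr <- data.frame(organism = orgs, isotype = "Thr",
                      n_total = as.integer(n_genes),
                      n_wobble = as.integer(n_wob),
                      fraction = 100 * n_wob / n_genes,
                      stringsAsFactors = FALSE)
    list(enrichment = enr, presence = stats::setNames(atd, orgs))
  })
}

#' Synthetic mimic of a deacylase homodimer
#'
#' A synthetic stand-in (not derived from any deposited coordinates) for a
#' DTD-like or ATD-like homodimer: the bundled family reference sequence is
#' built as a dimer whose cross-subunit Gly-Pro motif carries the family's
#' hallmark geometry - a cis peptide bond for DTD, trans for ATD, with the
#' Gly/Pro psi torsions flipped by 180 degrees between the two families -
#' and a motif B-factor below the chain baseline (the rigid motif). Useful
#' for exercising the full structure pipeline offline.
#'
#' @param family `"DTD"` or `"ATD"`.
#' @return a [MacroStructure-class] with chains A and B.
#' @export
syntheticDeacylaseDimer <- function(family = c("DTD", "ATD")) {
  family <- match.arg(family)
  seqaa <- referenceSequence(family)
  n <- nchar(seqaa)
  gp <- regexpr("GP", seqaa)[1]
  phi <- rep(-120, n); psi <- rep(130, n); omega <- rep(180, n)
  if (family == "DTD") {
    omega[gp + 1] <- 0                       # Gly-cisPro
    psi[gp] <- -30; psi[gp + 1] <- -40
  } else {
    omega[gp + 1] <- 180                     # Gly-transPro
    psi[gp] <- 150; psi[gp + 1] <- 140       # ~180-degree psi flip vs DTD
  }
  b <- 20 + 6 * sin(seq_len(n) / 3)          # varied baseline, sd > 0
  b[c(gp, gp + 1)] <- 8                      # rigid motif
  buildPeptide(seqaa, phi = phi, psi = psi, omega = omega, bfactor = b,
               dimer = TRUE, id = paste0("synthetic_", family, "_dimer"))
}
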