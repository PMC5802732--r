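# hand-built two-chain structure with a Gly-Pro whose carbonyl geometry is
# fully controlled; chain B (poly-Ala, no pocket motif) supplies the pocket
# through its C-alpha centroid fallback
make_orientation_fixture <- function(gly_o = c(0, 0, 1), pro_o = c(2, 0, 1),
                                     pocket_z = 10, motif_b = 20, base_b = 20) {
  row <- function(chain, resno, resname, atom, el, xyz, b) {
    data.frame(chain = chain, resno = as.integer(resno), icode = "",
               resname = resname, atom = atom, element = el,
               x = xyz[1], y = xyz[2], z = xyz[3], occ = 1, b = b,
               altloc = "", het = FALSE, stringsAsFactors = FALSE)
  }
  atoms <- rbind(
    row("A", 1, "GLY", "N", "N", c(-1.2, 0.5, 0), motif_b),
    row("A", 1, "GLY", "CA", "C", c(-0.7, -0.7, 0), motif_b),
    row("A", 1, "GLY", "C", "C", c(0, 0, 0), motif_b),
    row("A", 1, "GLY", "O", "O", gly_o, motif_b),
    row("A", 2, "PRO", "N", "N", c(1.0, 0.7, 0), motif_b),
    row("A", 2, "PRO", "CA", "C", c(1.4, -0.6, 0), motif_b),
    row("A", 2, "PRO", "C", "C", c(2, 0, 0), motif_b),
    row("A", 2, "PRO", "O", "O", pro_o, motif_b),
    do.call(rbind, lapply(1:5, function(i)
      rbind(row("B", i, "ALA", "CA", "C", c(1 + 0.1 * i, -0.2, pocket_z),
                base_b)))))
  new("MacroStructure", id = "fixture", atoms = atoms, meta = list())
}

make_site <- function(omega = 0) {
  new("MotifSite", donor_chain = "A", acceptor_chain = "B",
      gly_resno = 1L, pro_resno = 2L, gly_icode = "", pro_icode = "",
      cross_subunit = TRUE, omega = omega,
      conformation = classifyPeptideBond(omega))
}

test_that("carbonyl orientation labels follow parallelism and pocket projection", {
  # both C=O along the pocket axis -> outward-parallel
  s <- make_orientation_fixture()
  o <- carbonylOrientation(make_site(), s)
  expect_equal(o$parallelism_angle, 0, tolerance = 1e-9)
  expect_gt(o$mean_projection, 0)
  expect_identical(o$label, "outward-parallel")
  # C=O vectors 90 degrees apart -> non-parallel
  s90 <- make_orientation_fixture(pro_o = c(3, 0, 0))
  expect_identical(carbonylOrientation(make_site(), s90)$label, "non-parallel")
  # missing O -> error
  s_noO <- s
  s_noO@atoms <- s_noO@atoms[s_noO@atoms$atom != "O", ]
  expect_error(carbonylOrientation(make_site(), s_noO), "orientation undefined")
})

test_that("reflecting the carbonyl oxygens through the pocket-normal plane flips outward<->inward", {
  out <- carbonylOrientation(make_site(), make_orientation_fixture())
  refl <- carbonylOrientation(make_site(),
                              make_orientation_fixture(gly_o = c(0, 0, -1),
                                                       pro_o = c(2, 0, -1)))
  expect_identical(out$label, "outward-parallel")
  expect_identical(refl$label, "inward-parallel")
  expect_equal(out$parallelism_angle, refl$parallelism_angle, tolerance = 1e-9)
  expect_equal(out$mean_projection, -refl$mean_projection, tolerance = 1e-9)
})

test_that("Gly-Pro motifs in a synthetic dimer are found, cross-subunit, and correctly typed", {
  for (fam in c("DTD", "ATD")) {
    dimer <- syntheticDeacylaseDimer(fam)
    sites <- findGlyProMotifs(dimer)
    expect_length(sites, 2)
    expect_setequal(vapply(sites, function(s) s@donor_chain, character(1)),
                    c("A", "B"))
    for (st in sites) {
      expect_true(isCrossSubunit(st))
      expect_identical(bondConformation(st),
                       if (fam == "DTD") "cis" else "trans")
    }
  }
})

test_that("chains without a Gly-Pro dipeptide yield no motif sites", {
  s <- buildPeptide("AAWAA", phi = -57, psi = -47, omega = 180)
  expect_length(findGlyProMotifs(s), 0)
})

test_that("motif rigidity z-score reflects the B-factor contrast", {
  uni <- make_orientation_fixture(motif_b = 20, base_b = 20)
  # add backbone atoms to chain B so the donor-chain baseline has spread
  site <- make_site()
  expect_equal(motifRigidity(uni, site)$motif_z, 0)

  rigid <- make_orientation_fixture(motif_b = 10)
  a <- rigid@atoms
  extra <- a[a$chain == "A" & a$resno == 1, ]
  extra$resno <- 3L; extra$resname <- "ALA"; extra$b <- 30
  extra$x <- extra$x + 6
  rigid@atoms <- rbind(a, extra)
  expect_lt(motifRigidity(rigid, site)$motif_z, 0)

  zero <- make_orientation_fixture(motif_b = 0, base_b = 0)
  expect_error(motifRigidity(zero, site), "all-zero B-factors")
})

test_that("motif contacts report side-chain heavy atoms within cutoff with chain parity", {
  s <- make_orientation_fixture()
  # arginine probe on chain A: guanidinium NH1 2.9 A above the Gly carbonyl O
  probe <- data.frame(chain = "A", resno = 10L, icode = "", resname = "ARG",
                      atom = c("N", "CA", "C", "O", "NH1"),
                      element = c("N", "C", "C", "O", "N"),
                      x = c(8, 8.5, 9, 9, 0), y = c(0, 0, 0, 1, 0),
                      z = c(0, 0, 0, 0, 3.9), occ = 1, b = 20, altloc = "",
                      het = FALSE, stringsAsFactors = FALSE)
  s@atoms <- rbind(s@atoms, probe)
  hits <- motifContacts(s, "A", 10L, site = make_site(), cutoff = 3.5)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$donor_atom, "NH1")
  expect_identical(hits$acceptor_atom, "O")
  expect_equal(hits$distance, 2.9)
  expect_true(hits$same_chain)

  far <- s
  far@atoms$z[far@atoms$atom == "NH1"] <- 100
  expect_identical(nrow(motifContacts(far, "A", 10L, site = make_site())), 0L)
  expect_error(motifContacts(s, "C", 1L, site = make_site()), "not found")
})

test_that("cross-subunit contact parity distinguishes same-monomer from partner probes", {
  # in the ATD-like dimer the partner chain's arginine region can be probed
  dimer <- syntheticDeacylaseDimer("ATD")
  sites <- findGlyProMotifs(dimer)
  stA <- sites[[which(vapply(sites, function(s) s@donor_chain, character(1)) == "A")]]
  # any contact found from a chain-B probe must carry same_chain = FALSE
  resB <- atomRecords(dimer)
  resB <- unique(resB[resB$chain == "B", "resno"])
  hits <- motifContacts(dimer, "B", resB[10], site = stA, cutoff = 50)
  if (nrow(hits)) expect_true(all(!hits$same_chain))
  hitsA <- motifContacts(dimer, "A", stA@gly_resno - 2L, site = stA, cutoff = 50)
  if (nrow(hitsA)) expect_true(all(hitsA$same_chain))
})
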