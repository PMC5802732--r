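test_that("dihedral handles planar reference arrangements and rejects degenerate input", {
  expect_equal(dihedralAngle(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0)), 0)
  expect_equal(dihedralAngle(c(0,0,0), c(1,0,0), c(1,1,0), c(2,1,0)), 180)
  expect_error(dihedralAngle(c(0,0,0), c(0,0,0), c(1,1,0), c(0,1,0)),
               "coincident")
  expect_error(dihedralAngle(c(0,0,0), c(1,0,0), c(2,0,0), c(3,1,0)),
               "collinear")
})

test_that("dihedral agrees with the rotation-scan oracle on random quadruples", {
  set.seed(42)
  for (i in 1:100) {
    repeat {
      pts <- matrix(rnorm(12, sd = 3), 4, 3)
      ok <- tryCatch({ dihedralAngle(pts[1,], pts[2,], pts[3,], pts[4,]); TRUE },
                     error = function(e) FALSE)
      if (ok) break
    }
    got <- dihedralAngle(pts[1,], pts[2,], pts[3,], pts[4,])
    want <- oracle_dihedral(pts[1,], pts[2,], pts[3,], pts[4,])
    d <- abs(got - want) %% 360
    expect_lt(min(d, 360 - d), 1e-6)
  }
})

test_that("dihedral is invariant under global rigid motions", {
  set.seed(11)
  for (i in 1:25) {
    pts <- matrix(rnorm(12, sd = 3), 4, 3)
    base <- tryCatch(dihedralAngle(pts[1,], pts[2,], pts[3,], pts[4,]),
                     error = function(e) NULL)
    if (is.null(base)) next
    rm_ <- random_rigid_motion()
    moved <- sweep(pts %*% t(rm_$R), 2, rm_$t, `+`)
    expect_equal(dihedralAngle(moved[1,], moved[2,], moved[3,], moved[4,]),
                 base, tolerance = 1e-9)
  }
})

test_that("peptide-bond classification is total with its single boundary at +/-90", {
  expect_identical(classifyPeptideBond(5), "cis")
  expect_identical(classifyPeptideBond(-178), "trans")
  expect_identical(classifyPeptideBond(90), "cis")      # boundary included
  expect_identical(classifyPeptideBond(-90), "trans")   # boundary excluded
  expect_identical(classifyPeptideBond(90 + 1e-9), "trans")
  expect_identical(classifyPeptideBond(-90 + 1e-9), "cis")
  expect_error(classifyPeptideBond(NA_real_), "refused")
  # total on a fine sweep of the domain
  om <- seq(-179.99, 180, by = 0.37)
  expect_true(all(classifyPeptideBond(om) %in% c("cis", "trans")))
})

test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(3)
  A <- matrix(rnorm(30), 10, 3)
  self <- kabschSuperpose(A, A)
  expect_equal(rmsd(self), 0, tolerance = 1e-12)
  expect_equal(rotationMatrix(self), diag(3), tolerance = 1e-9)
  # rotation 90 degrees about z plus translation
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  B <- sweep(A %*% t(Rz), 2, c(3, -2, 7), `+`)
  fit <- kabschSuperpose(A, B)
  expect_lt(rmsd(fit), 1e-9)
  # random proper rigid motions
  for (i in 1:10) {
    rm_ <- random_rigid_motion()
    B <- sweep(A %*% t(rm_$R), 2, rm_$t, `+`)
    expect_lt(rmsd(kabschSuperpose(A, B)), 1e-9)
    expect_equal(det(rotationMatrix(kabschSuperpose(A, B))), 1,
                 tolerance = 1e-9)
  }
  expect_error(kabschSuperpose(A[1:2, ], A[1:2, ]), "underdetermined")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabschSuperpose(line, line), "underdetermined")
})

test_that("Kabsch rmsd matches the Euler-grid oracle on perturbed point sets", {
  set.seed(9)
  for (i in 1:3) {
    A <- matrix(rnorm(18, sd = 2), 6, 3)
    rm_ <- random_rigid_motion()
    B <- sweep((A + matrix(rnorm(18, sd = 0.3), 6, 3)) %*% t(rm_$R), 2,
               rm_$t, `+`)
    expect_equal(rmsd(kabschSuperpose(A, B)), oracle_min_rmsd(A, B),
                 tolerance = 1e-4)
  }
})

test_that("iterative superposition is self-consistent and prunes monotonically", {
  dimer <- syntheticDeacylaseDimer("ATD")
  self <- alignSuperpose(dimer, dimer)
  expect_equal(rmsd(self), 0, tolerance = 1e-9)
  n_ca <- sum(atomRecords(dimer)$atom == "CA")
  expect_equal(nPairs(self), n_ca)

  # monotone rmsd/pair count across pruning thresholds
  noisy <- dimer
  set.seed(5)
  a <- atomRecords(noisy)
  a$x <- a$x + rnorm(nrow(a), sd = 1.2)
  a$y <- a$y + rnorm(nrow(a), sd = 1.2)
  a$z <- a$z + rnorm(nrow(a), sd = 1.2)
  noisy@atoms <- a
  loose <- alignSuperpose(dimer, noisy, prune_cutoff = Inf)
  tight <- alignSuperpose(dimer, noisy, prune_cutoff = 2.5)
  expect_lte(rmsd(tight), rmsd(loose))
  expect_lte(nPairs(tight), nPairs(loose))
})

test_that("superposition of a Gaussian-perturbed copy gives rmsd near sigma*sqrt(3)", {
  base <- buildPeptide(strrep("A", 60), phi = -57, psi = -47, omega = 180)
  sigma <- 0.5
  set.seed(21)
  vals <- replicate(20, {
    noisy <- base
    a <- atomRecords(noisy)
    a$x <- a$x + rnorm(nrow(a), sd = sigma)
    a$y <- a$y + rnorm(nrow(a), sd = sigma)
    a$z <- a$z + rnorm(nrow(a), sd = sigma)
    noisy@atoms <- a
    rmsd(alignSuperpose(base, noisy, prune_cutoff = Inf))
  })
  # E[rmsd^2] = 3 sigma^2 for iid coordinate noise (superposition absorbs
  # almost none of it at this size); allow generous sampling slack
  expect_equal(mean(vals), sigma * sqrt(3), tolerance = 0.1)
})
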