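make_trna_tsv <- function(path, n = 3) {
  g <- genTRNASet(c(Thr = n), wobble_prob = c(Thr = 1), seed = 8)
  write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  g
}

test_that("tRNA tables read from TSV and FASTA with schema checks", {
  tf <- tempfile(fileext = ".tsv")
  g <- make_trna_tsv(tf)
  tab <- readTRNATable(tf)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$isotype, rep("Thr", 3))

  # FASTA with structured headers; T normalised to U
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(
    ">trna1 organism=Homo_sapiens isotype=Thr anticodon=AGU score=72.1",
    chartr("U", "T", g$sequence[1])), fa)
  tabf <- readTRNATable(fa, format = "fasta")
  expect_identical(tabf$organism, "Homo sapiens")
  expect_identical(tabf$sequence, g$sequence[1])
  expect_false(grepl("T", tabf$sequence))

  noscore <- tempfile(fileext = ".tsv")
  write.table(g[, setdiff(names(g), "score")], noscore, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readTRNATable(noscore), "schema error.*score")
})

test_that("score filtering is strictly greater-than", {
  g <- genTRNASet(c(Thr = 3), seed = 1)
  g$score <- c(49, 50, 51)
  expect_identical(filterByScore(g, 50)$score, 51)
  expect_identical(nrow(filterByScore(g[0, ], 50)), 0L)
  expect_identical(nrow(filterByScore(g, -Inf)), 3L)
})

test_that("acceptor-stem numbering hits 4:69 and is CCA-stripping invariant", {
  g <- genTRNASet(c(Thr = 1), wobble_prob = c(Thr = 1), seed = 2)
  stem <- acceptorStemPairs(g$sequence[1])
  expect_identical(nrow(stem), 7L)
  expect_identical(stem$five_prime_pos, 1:7)
  expect_identical(stem$five_prime_base[4], "G")
  expect_identical(stem$three_prime_base[4], "U")
  expect_identical(stem$three_prime_pos[4], 69L)

  with_cca <- paste0(g$sequence[1], "CCA")   # 76-nt mature form
  expect_identical(acceptorStemPairs(with_cca), stem)

  wc <- genTRNASet(c(Gly = 1), wobble_prob = c(Gly = 0), seed = 3)
  stem_wc <- acceptorStemPairs(wc$sequence[1])
  comp <- c(A = "U", U = "A", G = "C", C = "G")
  expect_identical(unname(comp[stem_wc$five_prime_base]),
                   stem_wc$three_prime_base)

  expect_error(acceptorStemPairs("ACGU"), "too short")
})

test_that("wobble detection respects G-on-5' directionality", {
  g <- genTRNASet(c(Thr = 1), wobble_prob = c(Thr = 1), seed = 4)
  stem <- acceptorStemPairs(g$sequence[1])
  w <- detectWobble(stem, 4L)
  expect_true(w$is_G4U69)
  expect_false(w$is_U4G69)

  flipped <- stem
  flipped$five_prime_base[4] <- "U"; flipped$three_prime_base[4] <- "G"
  wf <- detectWobble(flipped, 4L)
  expect_false(wf$is_G4U69)
  expect_true(wf$is_U4G69)
  # never both
  expect_false(w$is_G4U69 && w$is_U4G69)

  au <- stem; au$five_prime_base[4] <- "A"; au$three_prime_base[4] <- "U"
  wa <- detectWobble(au, 4L)
  expect_false(wa$is_G4U69 || wa$is_U4G69)
})

test_that("enrichment fractions count per organism and isotype", {
  g5 <- rbind(genTRNASet(c(Thr = 1), wobble_prob = c(Thr = 1), seed = 5),
              genTRNASet(c(Thr = 4), wobble_prob = c(Thr = 0), seed = 6))
  enr <- wobbleEnrichment(g5, "Thr")
  expect_identical(enr$n_total, 5L)
  expect_identical(enr$n_wobble, 1L)
  expect_equal(enr$fraction, 20)

  # order permutation leaves fractions unchanged
  perm <- g5[sample(nrow(g5)), ]
  expect_equal(wobbleEnrichment(perm, "Thr")$fraction, enr$fraction)

  # organisms with no genes of the isotype are omitted with a warning
  g5$organism[1] <- "Other organism"
  g5$isotype[1] <- "Cys"
  expect_warning(wobbleEnrichment(g5, "Thr"), "omitted")
})

test_that("synthetic enrichment falls in the 95% binomial interval of its generating rate", {
  n <- 200; p <- 0.3
  g <- genTRNASet(c(Thr = n), wobble_prob = c(Thr = p), seed = 77)
  enr <- wobbleEnrichment(g, "Thr")
  ci <- qbinom(c(0.025, 0.975), n, p)
  expect_gte(enr$n_wobble, ci[1])
  expect_lte(enr$n_wobble, ci[2])
})

test_that("co-occurrence table, concordance and Fisher p behave as specified", {
  pt <- genPresenceTable(10, concordance = 1, seed = 12)
  co <- cooccurrence(pt$enrichment, pt$presence)
  expect_equal(co$concordance, 1.0)
  expect_identical(sum(co$table), 10L)

  # [[5,0],[0,5]] -> two-sided p = 2/252
  expect_equal(co$fisher_p, oracle_fisher_p(co$table))
  tab5 <- matrix(c(5L, 0L, 0L, 5L), 2)
  expect_equal(oracle_fisher_p(tab5), 2 / 252, tolerance = 1e-12)
  expect_equal(stats::fisher.test(tab5)$p.value, 2 / 252, tolerance = 1e-9)

  one <- genPresenceTable(1, seed = 1)
  expect_error(cooccurrence(one$enrichment, one$presence), ">= 2 organisms")
})

test_that("Fisher p equals exhaustive hypergeometric enumeration on small tables", {
  set.seed(31)
  for (i in 1:200) {
    a <- sample(0:6, 1); b <- sample(0:6, 1)
    c_ <- sample(0:6, 1); d <- sample(0:6, 1)
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) next
    tab <- matrix(c(a, c_, b, d), 2)
    expect_equal(stats::fisher.test(tab)$p.value, oracle_fisher_p(tab),
                 tolerance = 1e-9)
  }
})

test_that("shuffled presence gives near-chance concordance on average", {
  pt <- genPresenceTable(24, concordance = 1, seed = 9)
  n <- 24
  a <- sum(pt$enrichment$fraction >= 10)  # enriched margin
  b <- sum(pt$presence)                   # presence margin
  expected <- (a * b + (n - a) * (n - b)) / n^2  # independence expectation
  set.seed(100)
  mean_conc <- mean(replicate(1000, {
    shuf <- setNames(sample(pt$presence), names(pt$presence))
    cooccurrence(pt$enrichment, shuf)$concordance
  }))
  expect_equal(mean_conc, expected, tolerance = 0.05)
})

test_that("acceptor-stem consensus reports modal pairs and frequencies", {
  g <- genTRNASet(c(Thr = 6), wobble_prob = c(Thr = 1), seed = 15)
  same <- g[rep(1, 4), ]
  cons <- acceptorConsensus(same)
  expect_true(all(cons$frequency == 1))
  expect_identical(cons$modal_pair[4], "G:U")

  # diverge half the genes at pair 6 only
  half <- same
  s <- strsplit(half$sequence[1], "")[[1]]
  s[6] <- setdiff(c("A", "C", "G", "U"), s[6])[1]
  s[73 - 6] <- c(A = "U", U = "A", G = "C", C = "G")[s[6]]
  half$sequence[1:2] <- paste(s, collapse = "")
  cons2 <- acceptorConsensus(half)
  expect_true(all(cons2$frequency[c(1:5, 7)] == 1))
  expect_equal(cons2$frequency[6], 0.5)
  expect_error(acceptorConsensus(g[0, ]), "no genes")
})
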