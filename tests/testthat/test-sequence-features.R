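library(Biostrings)

test_that("codon frequencies count in-frame triplets and exclude stops", {
  cf <- codonFrequencies(DNAStringSet(c(a = "ATGATGATG", b = "ATGAAATAA")))
  expect_equal(unname(cf$frequencies["a", "ATG"]), 1)
  expect_equal(unname(cf$frequencies["b", "ATG"]), 0.5)
  expect_equal(unname(cf$frequencies["b", "AAA"]), 0.5)
  expect_equal(unname(cf$stopCounts["b", "TAA"]), 1)
  # simplex: proportions over the 61 sense codons sum to one
  expect_equal(unname(rowSums(cf$frequencies)), c(1, 1))
  expect_equal(ncol(cf$frequencies), 61)

  # invalid records are skipped with a message
  expect_message(
    out <- codonFrequencies(DNAStringSet(c(ok = "ATGTTT", bad1 = "ATGT",
                                           bad2 = "ATGNNN"))),
    "skipped")
  expect_equal(rownames(out$frequencies), "ok")

  # random 300-codon CDS against brute-force substring counting
  set.seed(9)
  codons <- DecayDynamics:::.senseCodons()
  s <- paste(sample(codons, 300, replace = TRUE), collapse = "")
  cf <- codonFrequencies(DNAStringSet(c(x = s)))
  brute <- table(factor(substring(s, seq(1, 898, 3), seq(3, 900, 3)),
                        levels = codons))
  expect_equal(unname(cf$counts["x", codons]), unname(as.numeric(brute)))
})

test_that("CSC equals the Pearson correlation of frequency with half-life", {
  # frequency proportional to half-life -> csc = 1 for that codon
  hl <- c(10, 20, 30, 40)
  freq <- cbind(AAA = hl / 100, TTT = 0.5 - hl / 100, GGG = rep(0.6, 4))
  rownames(freq) <- paste0("t", 1:4)
  out <- computeCSC(freq, setNames(hl, rownames(freq)))
  expect_equal(out$csc[out$codon == "AAA"], 1)
  expect_equal(out$csc[out$codon == "TTT"], -1)
  expect_true(is.na(out$csc[out$codon == "GGG"]))

  # invariant under affine rescaling of half-lives
  out2 <- computeCSC(freq, setNames(3 * hl + 7, rownames(freq)))
  expect_equal(out2$csc, out$csc)

  # constant half-lives: undefined everywhere, with a warning
  expect_warning(out3 <- computeCSC(freq, setNames(rep(5, 4), rownames(freq))),
                 "constant")
  expect_true(all(is.na(out3$csc)))
})

test_that("a planted stabilising codon is recovered from a synthetic cohort", {
  cohort <- simulateCodonCohort(200, plantedCSC = c(GCT = 0.6), seed = 77)
  cf <- codonFrequencies(cohort$cds)
  expect_length(cf$skipped, 0)
  csc <- computeCSC(cf$frequencies, cohort$halfLives)
  expect_equal(csc$codon[1], "GCT")         # ranks first
  expect_lt(abs(csc$csc[1] - 0.6), 0.1)     # near the planted effect

  # null cohort: CSC estimates centre on zero
  null <- simulateCodonCohort(200, seed = 78)
  cscN <- computeCSC(codonFrequencies(null$cds)$frequencies, null$halfLives)
  expect_lt(max(abs(cscN$csc), na.rm = TRUE), 0.3)
  expect_lt(abs(mean(cscN$csc, na.rm = TRUE)), 0.05)
})

test_that("sign recovery holds for moderate planted effects", {
  planted <- c(GCT = 0.45, CCG = -0.4, TTT = 0.3)
  cohort <- simulateCodonCohort(250, plantedCSC = planted, seed = 101)
  csc <- computeCSC(codonFrequencies(cohort$cds)$frequencies,
                    cohort$halfLives)
  got <- setNames(csc$csc, csc$codon)[names(planted)]
  expect_true(all(sign(got) == sign(planted)))
})

test_that("optimality proportion is a per-transcript codon fraction", {
  cds <- DNAStringSet(c(all = "ATGATG", none = "TTTTTA",
                        half = "ATGTTT"))
  cnt <- codonFrequencies(cds)$counts
  pr <- optimalityProportion(cnt, optimalSet = c("ATG"))
  expect_equal(unname(pr), c(1, 0, 0.5))
  # mixed random CDS against brute-force counting
  set.seed(4)
  codons <- DecayDynamics:::.senseCodons()
  opt <- sample(codons, 20)
  s <- sample(codons, 500, replace = TRUE)
  cds <- DNAStringSet(c(x = paste(s, collapse = "")))
  pr <- optimalityProportion(codonFrequencies(cds)$counts, opt)
  expect_equal(unname(pr), mean(s %in% opt))
  expect_error(optimalityProportion(cnt, "TAA"))
})

test_that("group tests match textbook formulas and detect planted shifts", {
  # hand-built 2x2 table (20,10;10,20): chi-square = n(ad-bc)^2/(r1 r2 c1 c2)
  codons <- DecayDynamics:::.senseCodons()[1:60]
  tab <- data.frame(codon = codons,
                    csc = c(rep(1, 30), rep(-1, 30)) * seq(0.1, 1, length.out = 60),
                    optimal = c(rep(TRUE, 20), rep(FALSE, 10),
                                rep(TRUE, 10), rep(FALSE, 20)))
  set.seed(2)
  prop <- runif(60, 0.2, 0.6)
  cats <- factor(rep(c("short", "medium", "long"), each = 20),
                 levels = c("short", "medium", "long"))
  out <- groupAssociationTests(tab, prop, cats)
  expect_equal(unname(out$chisq$statistic),
               60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30))
  expect_equal(nrow(out$tTests), 3)

  # identical group composition: statistic 0
  tab0 <- tab
  tab0$optimal <- rep(c(TRUE, FALSE), 30)
  out0 <- groupAssociationTests(tab0, prop, cats)
  expect_equal(unname(out0$chisq$statistic), 0)

  # planted difference in optimality proportions: t test detects it
  set.seed(5)
  hits <- vapply(1:60, function(k) {
    a <- rnorm(50, 0.4, 0.08); b <- rnorm(50, 0.6, 0.08)
    t.test(a, b, var.equal = TRUE)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("feature correlations use Pearson r with a two-sided p", {
  hl <- c(3, 9, 14, 22, 31)
  expect_equal(correlateFeature(hl, hl)$r, 1)
  # small hand-computed set against the direct formula
  x <- c(1, 4, 2, 8, 5)
  r <- sum((x - mean(x)) * (hl - mean(hl))) /
    sqrt(sum((x - mean(x))^2) * sum((hl - mean(hl))^2))
  expect_equal(correlateFeature(x, hl)$r, r)
  expect_error(correlateFeature(rep(2, 5), hl), "variance")

  # independent Gaussians are rarely correlated
  set.seed(12)
  rs <- vapply(1:100, function(k)
    abs(correlateFeature(rnorm(200), rnorm(200))$r), numeric(1))
  expect_gte(mean(rs < 0.2), 0.95)
})

test_that("codon usage k-means clusters and the packaged set are usable", {
  cohort <- simulateCodonCohort(60, seed = 13)
  cf <- codonFrequencies(cohort$cds)
  cl <- codonUsageClusters(cf$frequencies, k = 3, cohort$halfLives, seed = 2)
  expect_length(cl$cluster, 60)
  expect_length(cl$meanHalfLife, 3)

  opt <- optimalCodons()
  expect_true(all(opt %in% DecayDynamics:::.senseCodons()))
  expect_gt(length(opt), 10)
})
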