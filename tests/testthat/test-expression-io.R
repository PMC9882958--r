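test_that("modified RPKM matches the formula and rejects bad inputs", {
  # single-count check: 1000 reads, 1 kb, 1e6 mapped -> 1000 RPKM
  tc <- rpkmModified(matrix(c(1000, 0), 1, 2), 1000, c(1e6, 1e6),
                     time = c(95, 105), replicate = c(1, 1))
  expect_equal(unname(exprValues(tc)[1, ]), c(1000, 0))

  # random table against an independently looped hand computation
  set.seed(7)
  cnt <- matrix(rpois(30, 500), 5, 6)
  len <- sample(200:5000, 5)
  tot <- sample(1e6:2e6, 6)
  tc <- rpkmModified(cnt, len, tot, time = rep(c(95, 105, 115), each = 2),
                     replicate = rep(1:2, 3))
  hand <- matrix(0, 5, 6)
  for (i in 1:5) for (j in 1:6)
    hand[i, j] <- as.numeric(cnt[i, j]) * 1e9 /
      (as.numeric(len[i]) * as.numeric(tot[j]))
  expect_equal(unname(exprValues(tc)), hand)

  # linearity in counts
  tc2 <- rpkmModified(3 * cnt, len, tot, time = rep(c(95, 105, 115), each = 2),
                      replicate = rep(1:2, 3))
  expect_equal(exprValues(tc2), 3 * exprValues(tc))

  expect_error(rpkmModified(cnt, c(len[-1], 0), tot,
                            time = rep(c(95, 105, 115), each = 2),
                            replicate = rep(1:2, 3)), "lengths")
  expect_error(rpkmModified(cnt, len, c(tot[-1], -5),
                            time = rep(c(95, 105, 115), each = 2),
                            replicate = rep(1:2, 3)), "totals")
})

test_that("intron-length normalisation divides per gene and drops intronless", {
  v <- matrix(rep(c(10, 20), 15), 1, 30, byrow = TRUE)
  tc <- makeTCM(rbind(g1 = rep(c(10, 20, 30), 10), g2 = rep(5, 30),
                      g3 = rep(7, 30)))
  ann <- data.frame(feature_id = c("g1", "g2", "g3"),
                    gene_id = c("g1", "g2", "g3"),
                    total_intron_length = c(10, 100, NA))
  expect_message(out <- normalizeIntronLengths(tc, ann), "intronless")
  expect_equal(rownames(out), c("g1", "g2"))
  expect_equal(unname(exprValues(out)["g1", 1:3]), c(1, 2, 3))
  expect_equal(unname(exprValues(out)["g2", 1]), 0.05)

  # equal lengths leave the ranking of genes unchanged
  set.seed(1)
  v20 <- matrix(runif(20 * 30, 1, 50), 20, 30,
                dimnames = list(paste0("g", 1:20), NULL))
  ann20 <- data.frame(feature_id = rownames(v20), gene_id = rownames(v20),
                      total_intron_length = rep(250, 20))
  out20 <- normalizeIntronLengths(makeTCM(v20), ann20)
  expect_equal(order(exprValues(out20)[, 5]), order(v20[, 5]))
  # brute-force division
  expect_equal(unname(exprValues(out20)), unname(v20 / 250))
})

test_that("minimum-TPM filter keeps any transcript reaching threshold once", {
  v <- rbind(low = rep(0.5, 30),
             spike = c(rep(0, 29), 1.2),
             high = rep(3, 30))
  tc <- makeTCM(v)
  out <- filterMinTPM(tc)
  expect_setequal(rownames(out), c("spike", "high"))
  # idempotent
  expect_equal(rownames(filterMinTPM(out)), rownames(out))
})

test_that("zygotic filter uses the replicate mean at t = 95", {
  v <- rbind(zyg = c(0.1, 0.2, 0.3, rep(5, 27)),
             mat = c(1, 1, 1, rep(5, 27)))
  tc <- makeTCM(v)
  out <- filterZygotic(tc)
  expect_equal(rownames(out), "zyg")
  expect_equal(rownames(filterZygotic(out)), "zyg")

  # planted cohort: 40 maternal (high at t95), 60 zygotic
  set.seed(3)
  zv <- matrix(runif(60 * 30, 0, 10), 60, 30); zv[, 1:3] <- runif(180, 0, 0.4)
  mv <- matrix(runif(40 * 30, 0, 10), 40, 30); mv[, 1:3] <- runif(120, 1, 10)
  all <- rbind(zv, mv)
  rownames(all) <- paste0("t", 1:100)
  expect_equal(nrow(filterZygotic(makeTCM(all))), 60)

  # grid must start at 95
  bad <- TimeCourseMatrix(matrix(1:4, 1), time = rep(c(100, 110), each = 2),
                          replicate = rep(1:2, 2))
  expect_error(filterZygotic(bad), "95")
})

test_that("intron-signal filter removes all-zero and intronless genes", {
  v <- rbind(zero = rep(0, 30), once = c(rep(0, 15), 1, rep(0, 14)),
             active = rep(2, 30))
  tc <- makeTCM(v)
  expect_setequal(rownames(filterIntronSignal(tc)), c("once", "active"))
  ann <- data.frame(feature_id = rownames(v), gene_id = rownames(v),
                    total_intron_length = c(500, NA, 500))
  expect_equal(rownames(filterIntronSignal(tc, ann)), "active")
})

test_that("correlation filter thresholds the replicate-mean Pearson r", {
  base <- seq(1, 10, length.out = 30)
  tcP <- makeTCM(rbind(a = base, b = base, c = rep(4, 30)))
  tcM <- makeTCM(rbind(a = 2 * base, b = -base + 20, c = base))
  expect_message(out <- filterCorrelation(tcP, tcM), "zero-variance")
  expect_equal(out$pre_id, "a")
  expect_equal(out$correlation, 1)

  # 50 synthetic pairs straddling the threshold vs direct Pearson on means
  set.seed(11)
  n <- 50
  vP <- matrix(rnorm(n * 30, 10), n, 30,
               dimnames = list(paste0("p", 1:n), NULL))
  vM <- matrix(rnorm(n * 30, 10), n, 30,
               dimnames = list(paste0("p", 1:n), NULL))
  p <- makeTCM(vP); m <- makeTCM(vM)
  kept <- filterCorrelation(p, m, minR = 0.4)
  rs <- vapply(seq_len(n), function(i)
    cor(meanByTime(p)[i, ], meanByTime(m)[i, ]), numeric(1))
  expect_setequal(kept$pre_id, paste0("p", which(rs > 0.4)))
  # idempotent on the kept subset
  kept2 <- filterCorrelation(p[kept$pre_id, ], m[kept$mature_id, ], minR = 0.4)
  expect_setequal(kept2$pre_id, kept$pre_id)
})

test_that("long and wide readers round-trip, including gzip", {
  set.seed(5)
  tc <- makeTCM(matrix(runif(60), 2, 30,
                       dimnames = list(c("fx", "fy"), NULL)))
  f <- tempfile(fileext = ".tsv.gz")
  writeTimeCourse(tc, f)
  back <- readTimeCourse(f)
  expect_equal(exprValues(back), exprValues(tc))
  expect_equal(timePoints(back), timePoints(tc))

  fw <- tempfile(fileext = ".tsv")
  df <- data.frame(feature_id = rownames(tc),
                   as.data.frame(exprValues(tc)), check.names = FALSE)
  write.table(df, fw, sep = "\t", quote = FALSE, row.names = FALSE)
  wide <- readTimeCourseWide(fw)
  expect_equal(exprValues(wide), exprValues(tc))
})
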