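test_that("amino-acid composition matches letter counting and excludes X", {
  expect_equal(unname(aac("AAAA")[["A"]]), 1.0)
  expect_equal(unname(aac("ACDE")[c("A", "C", "D", "E")]),
               rep(0.25, 4L), ignore_attr = TRUE)
  set.seed(31)
  s <- rand_seq(100)
  counts <- table(factor(strsplit(s, "")[[1L]], levels = AA))
  expect_equal(as.numeric(aac(s)), as.numeric(counts) / 100, tolerance = 1e-12)

  a <- aac("ACXXA")
  expect_equal(sum(a), 1.0)
  expect_equal(unname(a[["A"]]), 2 / 3)
  expect_error(aac("XXX"), "no standard residues")
})

test_that("k-mer counting is overlapping and bounded", {
  expect_equal(kmer_count("GFVGFV", "GFV"), 2L)
  expect_equal(kmer_count("GGFFVV", "GFV"), 0L)
  expect_equal(kmer_count("AAAA", "AA"), 3L)
  expect_error(kmer_count("GF", "GFV"), "length")
  set.seed(5)
  s <- rand_seq(200)
  k <- "AC"
  brute <- sum(vapply(seq_len(199), function(i)
    substring(s, i, i + 1L) == k, logical(1)))
  expect_equal(kmer_count(s, k), brute)
})

test_that("di/tripeptide compositions normalise by window count", {
  tp <- tripeptide_composition("GFV")
  expect_equal(sum(tp), 1.0)
  expect_equal(unname(tp[["GFV"]]), 1.0)
  dp <- dipeptide_composition("AA")
  expect_equal(unname(dp[["AA"]]), 1.0)
  expect_error(tripeptide_composition("GF"), "shorter")

  set.seed(6)
  s <- rand_seq(50)
  dp <- dipeptide_composition(s)
  words <- substring(s, 1:49, 2:50)
  expect_equal(unname(dp[["AC"]]), sum(words == "AC") / 49)
  expect_equal(sum(dp), 1.0)
})

test_that("Moreau-Broto autocorrelation equals direct summation", {
  toy <- toy_property(c(A = 1, C = -1, D = 0))
  expect_equal(moreau_broto("ACD", toy, 1L), -0.5)
  expect_error(moreau_broto("ACD", toy, 3L), "lag")

  p <- property_table("DAYM780201")
  set.seed(17)
  s <- rand_seq(80)
  v <- p$values[match(strsplit(s, "")[[1L]], AA)]
  for (d in c(1L, 7L, 30L)) {
    expect_equal(moreau_broto(s, p, d),
                 mean(v[seq_len(80 - d)] * v[(d + 1):80]),
                 tolerance = 1e-12)
  }
})

test_that("Moran and Geary autocorrelation match their formulas", {
  p <- property_table("BIGC670101")
  set.seed(18)
  s <- rand_seq(90)
  v <- p$values[match(strsplit(s, "")[[1L]], AA)]
  d <- 4L
  cm <- v - mean(v)
  moran_o <- mean(cm[seq_len(90 - d)] * cm[(d + 1):90]) / mean(cm^2)
  geary_o <- (sum((v[seq_len(90 - d)] - v[(d + 1):90])^2) / (2 * (90 - d))) /
    (sum(cm^2) / 89)
  expect_equal(moran(s, p, d), moran_o, tolerance = 1e-12)
  expect_equal(geary(s, p, d), geary_o, tolerance = 1e-12)
})

test_that("APAAC follows the amphiphilic pseudo-composition formula", {
  s <- "MKTAYIAK"
  expect_equal(as.numeric(apaac(s, lambda = 0L)), as.numeric(aac(s)))
  expect_error(apaac("MKT", lambda = 3L), "lambda")

  h1 <- property_table("ARGP820101")
  h2 <- property_table("HOPT810101")
  idx <- match(strsplit(s, "")[[1L]], AA)
  L <- nchar(s); w <- 0.05
  tau <- numeric(4L)
  for (j in 1:2) {
    tau[2 * j - 1] <- mean(h1$values[idx[seq_len(L - j)]] *
                             h1$values[idx[(j + 1):L]])
    tau[2 * j] <- mean(h2$values[idx[seq_len(L - j)]] *
                         h2$values[idx[(j + 1):L]])
  }
  expected <- c(aac(s) / (1 + w * sum(tau)), w * tau / (1 + w * sum(tau)))
  got <- apaac(s, lambda = 2L, weight = w, h1 = h1, h2 = h2)
  expect_equal(as.numeric(got), as.numeric(expected), tolerance = 1e-12)
  expect_true(all(startsWith(names(got)[1:20], "Pc1.")))
})

test_that("scales auto-cross covariance matches direct summation and naming", {
  sc <- property_scales(3L)
  expect_equal(colMeans(sc), c(scl1 = 0, scl2 = 0, scl3 = 0),
               tolerance = 1e-9)
  zero <- matrix(0, 20L, 1L, dimnames = list(AA, "scl1"))
  expect_true(all(scales_acc("MKTAYIAK", zero, 3L) == 0))

  set.seed(9)
  s <- rand_seq(60)
  idx <- match(strsplit(s, "")[[1L]], AA)
  S <- sc[idx, ]
  got <- scales_acc(s, sc, 4L)
  expect_true("scl3.2lag.4" %in% names(got))
  for (i in 1:3) for (j in 1:3) for (d in 1:4) {
    expect_equal(got[[sprintf("scl%d.%dlag.%d", i, j, d)]],
                 mean(S[seq_len(60 - d), i] * S[(d + 1):60, j]),
                 tolerance = 1e-12)
  }
  expect_error(scales_acc("MK", sc, 5L), "acc_lag")
})

test_that("feature naming covers the signature features of the method", {
  g <- scales_acc("MKTAYIAKQRMKTAYIAK", property_scales(5L), 13L)
  expect_true("scl5.2lag.5" %in% names(g))
  ds <- make_tiny_dataset(n_pos = 2L, n_neg = 1L, len = 70L)
  feats <- extract_all(ds, lean_descriptor())
  expect_true("count.GFV" %in% colnames(feats))
  expect_true(any(grepl("^MBroto\\.DAYM780201\\.lag\\.", colnames(feats))))
  expect_true(any(grepl("^Pc1\\.", colnames(feats))))
})

test_that("descriptors are order-sensitive but id-insensitive", {
  set.seed(12)
  s <- rand_seq(60)
  shuffled <- paste0(sample(strsplit(s, "")[[1L]]), collapse = "")
  p <- property_table("DAYM780201")
  expect_equal(aac(s), aac(shuffled))
  expect_false(isTRUE(all.equal(moreau_broto(s, p, 2L),
                                moreau_broto(shuffled, p, 2L))))
})

test_that("full default configuration yields tens of thousands of features", {
  ds <- make_tiny_dataset(n_pos = 2L, n_neg = 1L, len = 120L)
  feats <- extract_all(ds, descriptor_config())
  expect_gt(ncol(feats), 30000L)
  expect_false(anyDuplicated(colnames(feats)) > 0L)
  expect_true(all(is.finite(feats)))
})

test_that("extraction is deterministic and errors carry the sequence id", {
  ds <- make_tiny_dataset(n_pos = 2L, n_neg = 2L, len = 80L)
  f1 <- extract_all(ds, lean_descriptor())
  f2 <- extract_all(ds, lean_descriptor())
  expect_identical(f1, f2)

  bad <- xt_sequences(c("ok", "short"), c(rand_seq(80), "MK"))
  expect_error(extract_all(bad, lean_descriptor()), "short")
})
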