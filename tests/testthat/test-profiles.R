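test_that("PROSITE patterns compile and scan with overlaps and anchors", {
  expect_length(prosite_match_positions(compile_prosite("G-x-G"), "GAG"), 1L)
  expect_length(prosite_match_positions(compile_prosite("[LIVM]-K"), "LKVK"), 2L)
  expect_length(prosite_match_positions(compile_prosite("A-x(2)-C"), "AGGC"), 1L)
  expect_equal(prosite_match_positions(compile_prosite("A-A"), "AAAA"),
               c(1L, 2L, 3L))
  expect_length(prosite_match_positions(compile_prosite("<M-K"), "MKMK"), 1L)
  expect_length(prosite_match_positions(compile_prosite("M-K>"), "MKMK"), 1L)
  expect_length(prosite_match_positions(compile_prosite("{P}-K"), "PKAK"), 1L)
  expect_error(compile_prosite("A-(2)"), "malformed")
})

test_that("variable-repeat patterns agree with an exhaustive window oracle", {
  pat <- compile_prosite("A-x(1,3)-C")
  set.seed(41)
  for (rep in 1:20) {
    s <- rand_seq(40)
    got <- prosite_match_positions(pat, s)
    brute <- which(vapply(seq_len(40), function(i) {
      any(vapply(1:3, function(g) {
        j <- i + 1L + g
        j <= 40 && substring(s, i, i) == "A" && substring(s, j, j) == "C"
      }, logical(1)))
    }, logical(1)))
    expect_equal(got, brute)
  }
})

test_that("prosite features expose count and presence per pattern", {
  pats <- list(sig1 = compile_prosite("G-F-V"), sig2 = compile_prosite("W-W"))
  f <- prosite_features("GFVGFVA", pats)
  expect_equal(unname(f[["prosite.sig1.count"]]), 2)
  expect_equal(unname(f[["prosite.sig1.present"]]), 1)
  expect_equal(unname(f[["prosite.sig2.count"]]), 0)
  expect_equal(unname(f[["prosite.sig2.present"]]), 0)
})

test_that("region-to-column mapping follows the reference row's gaps", {
  msa <- xt_msa(c("r", "o"), c("A-CD", "AAC-"), reference_id = "r")
  ann <- xt_regions("r", data.frame(start = 2, end = 3,
                                    kind = "non_cytoplasmic"))
  expect_equal(map_regions_to_columns(msa, ann), c(3L, 4L))

  ung <- xt_regions("o", data.frame(start = 1, end = 3,
                                    kind = "non_cytoplasmic"))
  expect_equal(map_regions_to_columns(msa, ung), 1:3)

  expect_error(map_regions_to_columns(
    msa, xt_regions("zz", data.frame(start = 1, end = 2,
                                     kind = "binding_site"))), "missing")
  expect_error(map_regions_to_columns(
    msa, xt_regions("r", data.frame(start = 1, end = 4,
                                    kind = "binding_site"))), "exceeds")

  # random gapped row versus a position-walking oracle
  set.seed(14)
  for (rep in 1:10) {
    chars <- sample(c(AA, "-"), 30L, replace = TRUE, prob = c(rep(1, 20), 8))
    if (!any(chars != "-")) chars[1L] <- "A"
    row <- paste0(chars, collapse = "")
    other <- rand_seq(30)
    msa2 <- xt_msa(c("r", "o"), c(row, other), reference_id = "r")
    reflen <- nchar(degap(row))
    st <- sample(reflen, 1L); en <- min(reflen, st + sample(5L, 1L))
    ann2 <- xt_regions("r", data.frame(start = st, end = en,
                                       kind = "binding_site"))
    walk <- which(chars != "-")[st:en]
    expect_equal(map_regions_to_columns(msa2, ann2), sort(unique(walk)))
  }
})

test_that("PSSM probabilities, log-odds and consensus follow the counts", {
  msa <- xt_msa(c("a", "b", "c"), c("AAA", "AAA", "AAA"))
  ps <- build_pssm(msa, 1:3, alpha = 0)
  expect_equal(unname(ps$probs["A", 1L]), 1.0)
  expect_equal(unname(ps$log_odds["A", 1L]), log2(20), tolerance = 1e-12)
  expect_equal(ps$consensus, "AAA")

  msa2 <- xt_msa(letters[1:4], c("A", "A", "C", "C"))
  ps2 <- build_pssm(msa2, 1L, alpha = 1)
  expect_equal(unname(ps2$probs["A", 1L]), 3 / 24)
  expect_equal(colSums(ps2$probs), 1, ignore_attr = TRUE, tolerance = 1e-9)

  gap <- xt_msa(c("a", "b"), c("-A", "-C"))
  expect_error(build_pssm(gap, 1L, alpha = 0), "no residues")

  # counting oracle on a random alignment
  set.seed(3)
  rows <- replicate(6, paste0(sample(c(AA[1:4], "-"), 8L, TRUE), collapse = ""))
  msa3 <- xt_msa(sprintf("r%d", 1:6), rows)
  ps3 <- build_pssm(msa3, 1:8, alpha = 1)
  chars <- do.call(rbind, strsplit(rows, ""))
  for (j in 1:8) {
    cnt <- sum(chars[, j] == "A")
    n <- sum(chars[, j] %in% AA)
    expect_equal(unname(ps3$probs["A", j]), (cnt + 1) / (n + 20))
  }
})

test_that("PSSM construction is row-order invariant", {
  set.seed(19)
  rows <- replicate(5, paste0(sample(c(AA, "-"), 10L, TRUE), collapse = ""))
  m1 <- xt_msa(sprintf("r%d", 1:5), rows)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  m2 <- xt_msa(sprintf("r%d", perm), rows[perm])
  expect_equal(build_pssm(m1, 1:10)$probs, build_pssm(m2, 1:10)$probs)
  expect_equal(build_profile_hmm(m1, 1:10)$emissions,
               build_profile_hmm(m2, 1:10)$emissions)
  expect_equal(build_profile_hmm(m1, 1:10)$tM,
               build_profile_hmm(m2, 1:10)$tM)
})

test_that("PSSM summary features score the query against the consensus", {
  msa <- xt_msa(c("a", "b"), c("ACDY", "ACDY"))
  ps <- build_pssm(msa, 1:4, alpha = 0)
  f <- pssm_features("ACDY", ps)
  expect_length(f, 23L)
  expect_equal(unname(f[["pssm.mean"]]), log2(20), tolerance = 1e-9)
  expect_equal(unname(f[["pssm.coverage"]]), 1.0)
  expect_equal(unname(f[["pssm.mean.A"]]), log2(20), tolerance = 1e-9)
  expect_equal(unname(f[["pssm.mean.W"]]), 0)  # letter absent from query
  expect_error(pssm_features("", ps), "empty")

  # toy profile + query: hand alignment is the identity, scores looked up
  msa2 <- xt_msa(c("a", "b"), c("AAAC", "AAAC"))
  ps2 <- build_pssm(msa2, 1:4, alpha = 1)
  f2 <- pssm_features("AAAC", ps2)
  hand <- c(rep(ps2$log_odds["A", 1L], 3L), ps2$log_odds["C", 4L])
  expect_equal(unname(f2[["pssm.mean"]]), mean(hand), tolerance = 1e-9)
  expect_equal(unname(f2[["pssm.max"]]), max(hand), tolerance = 1e-9)
})

test_that("profile HMM architecture follows occupancy and count rules", {
  msa <- xt_msa(c("a", "b"), c("AC", "AC"))
  h <- build_profile_hmm(msa, 1:2, alpha = 0)
  expect_equal(h$m, 2L)
  expect_equal(unname(h$tM[2L, "M"]), 1.0)      # deterministic M1 -> M2
  expect_equal(unname(h$emissions["A", 1L]), 1.0)

  gapmsa <- xt_msa(c("a", "b"), c("--", "--"))
  expect_error(build_profile_hmm(gapmsa, 1:2), "occupancy")

  # occupancy rule: a column with 1/3 residues feeds an insert state
  msa2 <- xt_msa(c("a", "b", "c"), c("AC-A", "A--A", "A-CA"))
  h2 <- build_profile_hmm(msa2, 1:4, alpha = 1)
  expect_equal(h2$m, 2L)                        # columns 1 and 4 only
  expect_equal(h2$match_columns, c(1L, 4L))

  # transitions and emissions are proper distributions
  expect_equal(rowSums(h2$tM), rep(1, 3L), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(rowSums(h2$tI), rep(1, 3L), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(rowSums(h2$tD)[2L], 1, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(colSums(h2$emissions), rep(1, 2L), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("hand-counted transitions appear in a 3-row gapped alignment", {
  # rows: "AC", "A-", "-C" on two match columns, alpha = 0
  msa <- xt_msa(c("a", "b", "c"), c("AC", "A-", "-C"))
  h <- build_profile_hmm(msa, 1:2, alpha = 0, flank_loop = NULL)
  # from M1: a goes M1->M2, b goes M1->D2  => 1/2 each
  expect_equal(unname(h$tM[2L, c("M", "D")]), c(0.5, 0.5))
  # from B: a,b start in M1, c starts in D1 => 2/3, 1/3
  expect_equal(unname(h$tM[1L, c("M", "D")]), c(2 / 3, 1 / 3))
})

test_that("forward scores match the single forced path and enumeration", {
  msa1 <- xt_msa("only", "AC")
  h1 <- build_profile_hmm(msa1, 1:2, alpha = 0)
  expect_equal(hmm_score(h1, "AC"), 2 * log2(20), tolerance = 1e-9)

  set.seed(42)
  msa2 <- xt_msa(c("a", "b", "c"), c("AC-A", "A-CA", "GCTA"))
  h2 <- build_profile_hmm(msa2, 1:4, alpha = 1)
  for (s in c("AC", "ACA", "GGTAA", "A", "WYYW")) {
    expect_equal(forward_prob(h2, s), enum_forward(h2, s),
                 tolerance = 1e-9, info = s)
  }
  # also with alpha = 0 (sparser transition structure)
  h3 <- build_profile_hmm(msa2, 1:4, alpha = 0)
  for (s in c("ACA", "AA", "GCTA")) {
    expect_equal(forward_prob(h3, s), enum_forward(h3, s),
                 tolerance = 1e-9, info = s)
  }
})

test_that("forward probabilities over all short sequences stay within 1", {
  alpha3 <- c("A", "B", "C")
  q3 <- setNames(rep(1 / 3, 3L), alpha3)
  msa <- xt_msa(c("a", "b"), c("AB", "AC"))
  h <- build_profile_hmm(msa, 1:2, alpha = 1, q = q3, alphabet = alpha3,
                         flank_loop = NULL)
  seqs_of_len <- function(L) {
    apply(do.call(expand.grid, rep(list(alpha3), L)), 1L, paste0,
          collapse = "")
  }
  totals <- cumsum(vapply(1:5, function(L)
    sum(vapply(seqs_of_len(L), function(s) forward_prob(h, s), numeric(1))),
    numeric(1)))
  expect_true(all(diff(totals) > 0))
  expect_lt(totals[[5L]], 1)
  expect_gt(totals[[5L]], 0.8)   # mass concentrates on short sequences
})

test_that("profile serialisation round-trips scores exactly", {
  set.seed(2)
  msa <- xt_msa(c("a", "b", "c"), c("ACDA", "AC-A", "AWDA"))
  h <- build_profile_hmm(msa, 1:4, alpha = 1)
  ps <- build_pssm(msa, 1:4, alpha = 1)
  fp <- tempfile(fileext = ".json")
  write_profile(h, fp)
  h2 <- read_profile(fp)
  s <- rand_seq(30)
  expect_identical(hmm_score(h, s), hmm_score(h2, s))
  write_profile(ps, fp)
  ps2 <- read_profile(fp)
  expect_equal(ps2$log_odds, ps$log_odds, tolerance = 1e-12)
  expect_identical(ps2$consensus, ps$consensus)
  file.remove(fp)
})

test_that("ASCII PSSM files parse and summarise", {
  f <- tempfile(fileext = ".pssm")
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed",
    paste0("     ", paste(AA, collapse = "  ")),
    paste("1 M ", paste(seq(-10, 9), collapse = " ")),
    paste("2 K ", paste(rep(2, 20), collapse = " "))), f)
  ps <- read_pssm_ascii(f)
  expect_equal(ps$residues, c("M", "K"))
  expect_equal(dim(ps$log_odds), c(2L, 20L))
  feats <- pssm_ascii_features(ps)
  expect_length(feats, 23L)
  expect_equal(unname(feats[["pssm.coverage"]]), 1.0)
  file.remove(f)
})

test_that("the HMM score separates motif carriers on synthetic data", {
  syn <- suppressMessages(synth_generate(synth_config(n_pos = 30L, n_neg = 30L,
                                     length_range = c(120L, 160L),
                                     motif_region = c(21L, 60L),
                                     mutation_rate = 0.1, seed = 7L)))
  cols <- map_regions_to_columns(syn$msa, syn$regions)
  h <- build_profile_hmm(syn$msa, cols, alpha = 1)
  scores <- vapply(syn$dataset$records$residues,
                   function(s) hmm_score(h, s), numeric(1))
  y <- as.integer(syn$dataset$labels)
  pv <- stats::wilcox.test(scores[y == 1L], scores[y == 0L],
                           alternative = "greater", exact = FALSE)$p.value
  expect_lt(pv, 0.01)
})
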