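test_that("GVOG reward: ratio normalization and clamping", {
  expect_equal(score_gvog(100, 0.5, 0.0), 100)    # phage-free keeps full B
  expect_equal(score_gvog(100, 0.2, 0.2), 50)     # evenly shared halves it
  expect_equal(score_gvog(-3, 0.5, 0.1), 0)       # negative bits clamp to 0
  expect_equal(score_gvog(100, 0.0, 0.0), 0)      # absent from both surveys
  expect_error(score_gvog(10, 1.5, 0), "\\[0, 1\\]")
})

test_that("literal GVOG variant reproduces the additive form", {
  p <- score_params(eq1_variant = "literal")
  expect_equal(score_gvog(100, 0.5, 0.25, p), 100 * (0.5 + 0.25 / 0.5))
  # the floor guards phage-only families from dividing by zero
  expect_equal(score_gvog(10, 0.0, 0.5, p), 10 * (0 + 0.5 / 0.01))
})

test_that("Pfam penalty: normalization, eligibility and clamping", {
  expect_equal(score_pfam(50, 1.0, 0.0, TRUE), 0)   # NCLDV-universal: free
  expect_equal(score_pfam(50, 0.5, 0.5, TRUE), 26)  # 50*0.5 + 0.5/0.5
  expect_equal(score_pfam(50, 0.0, 0.0, FALSE), 50) # ineligible: raw B
  expect_equal(score_pfam(-7, 0.2, 0.2, TRUE), score_pfam(0, 0.2, 0.2, TRUE))
})

test_that("score components combine as sqrt(gvog) - sqrt(pfam)", {
  expect_equal(combine_scores(16, 9), 1)
  expect_equal(combine_scores(0, 0), 0)
  expect_equal(combine_scores(0, 25), -5)
  expect_equal(combine_scores(100, 0), 10)
  # homogeneity of degree 1/2
  expect_equal(combine_scores(2 * 16, 2 * 9), sqrt(2) * combine_scores(16, 9))
})

test_that("scores agree with straight-line recomputation on random triples", {
  set.seed(101)
  n <- 1000
  B <- runif(n, -20, 300)
  pn <- runif(n)
  pc <- runif(n)
  # independent straight-line oracle, written without the package's helpers
  oracle_gvog <- numeric(n)
  oracle_pfam <- numeric(n)
  for (i in seq_len(n)) {
    b <- if (B[i] > 0) B[i] else 0
    oracle_gvog[i] <- if (pn[i] + pc[i] > 0) b * pn[i] / (pn[i] + pc[i]) else 0
    elig <- pn[i] >= 0.01 || pc[i] >= 0.01
    s <- if (elig) b * (1 - pn[i]) + pc[i] / max(pn[i], 0.01) else b
    oracle_pfam[i] <- max(s, 0)
  }
  expect_equal(score_gvog(B, pn, pc), oracle_gvog, tolerance = 1e-9)
  elig <- pn >= 0.01 | pc >= 0.01
  expect_equal(score_pfam(B, pn, pc, elig), oracle_pfam, tolerance = 1e-9)
  expect_equal(combine_scores(oracle_gvog, oracle_pfam),
               sqrt(oracle_gvog) - sqrt(oracle_pfam), tolerance = 1e-9)
})

test_that("monotonicity: phage-shared families never raise the reward", {
  grid <- seq(0, 1, length.out = 101)
  B <- 80
  for (pn in c(0.05, 0.3, 0.7, 1.0)) {
    s <- score_gvog(B, rep(pn, 101), grid)
    expect_true(all(diff(s) <= 1e-12))         # non-increasing in p_caudo
    expect_true(all(s >= 0 & s <= B))
  }
  for (pc in c(0, 0.25, 0.9)) {
    s <- score_gvog(B, grid, rep(pc, 101))
    expect_true(all(diff(s) >= -1e-12))        # non-decreasing in p_ncldv
  }
})

test_that("monotonicity: NCLDV-common domains never raise the penalty", {
  grid <- seq(0, 1, length.out = 101)
  for (pc in c(0, 0.4, 1)) {
    s <- score_pfam(60, grid, rep(pc, 101), eligible = TRUE)
    expect_true(all(diff(s) <= 1e-9))          # non-increasing in p_ncldv
  }
  for (pn in c(0, 0.3, 1)) {
    s <- score_pfam(60, rep(pn, 101), grid, eligible = TRUE)
    expect_true(all(diff(s) >= -1e-9))         # non-decreasing in p_caudo
  }
})

test_that("score_all_orfs emits one row per ORF in ordinal order", {
  db <- tiny_db()
  orfs <- tiny_orfs(5)
  hits <- rbind(hit("c1_2", "GVOG_SPEC", "GVOG", 100),
                hit("c1_4", "PF_CELL", "PFAM", 25))
  sc <- score_all_orfs(orfs, best_hit_per_orf(hits), db)
  expect_equal(nrow(sc), 5L)
  expect_equal(sc$ordinal, 1:5)
  expect_equal(sum(sc$s_final == 0), 3L)
  expect_equal(sc$s_final[2], 10)              # sqrt(100 * 0.8/0.8)
  expect_equal(sc$s_final[4], -5)              # ineligible Pfam, raw B = 25
  expect_equal(sc$s_gvog >= 0, rep(TRUE, 5))
  expect_equal(sc$s_final, sqrt(sc$s_gvog) - sqrt(sc$s_pfam),
               tolerance = 1e-9)
})

test_that("hits referencing unknown ORFs or profiles are errors", {
  db <- tiny_db()
  orfs <- tiny_orfs(3)
  expect_error(
    score_all_orfs(orfs, hit("cX_9", "GVOG_SPEC", "GVOG", 10), db),
    "unknown ORF")
  expect_error(
    score_all_orfs(orfs, hit("c1_1", "NOPE", "GVOG", 10), db),
    "absent from metadata")
})
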