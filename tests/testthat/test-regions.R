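test_that("rolling average: identity, invariance, truncation, linearity", {
  x <- c(2, -1, 4, 0, 3)
  expect_equal(rolling_average(x, 1), x)                 # window 1 identity
  expect_equal(rolling_average(rep(3.5, 20), 15), rep(3.5, 20))
  expect_equal(rolling_average(c(0, 0, 3, 0, 0), 3), c(0, 1, 1, 1, 0))
  expect_equal(rolling_average(numeric(0), 5), numeric(0))
  expect_error(rolling_average(x, 0), ">= 1")
  # linearity under scaling
  set.seed(5)
  s <- rnorm(50)
  expect_equal(rolling_average(7 * s, 9), 7 * rolling_average(s, 9))
  # even windows widen to the next odd size
  expect_message(r <- rolling_average(x, 4), "even")
  expect_equal(r, rolling_average(x, 5))
})

test_that("contig classification is strict at the cutoff", {
  expect_equal(classify_contig(9.7, 0), "NCLDV")
  expect_equal(classify_contig(0.0, 0), "NON_NCLDV")
  expect_equal(classify_contig(-2.4, 0), "NON_NCLDV")
  expect_equal(classify_contig(c(0.01, -0.01), 0), c("NCLDV", "NON_NCLDV"))
})

# Build a score table whose rolling track is directly the planted values
# (window 1 used in most region tests to decouple calling from smoothing).
score_table <- function(s_final, gvog = rep(TRUE, length(s_final))) {
  sc <- tiny_orfs(length(s_final))
  sc$gvog_profile <- ifelse(gvog, "GVOG_SPEC", NA_character_)
  sc$s_gvog <- ifelse(s_final > 0, s_final^2, 0)
  sc$pfam_profile <- NA_character_
  sc$s_pfam <- ifelse(s_final < 0, s_final^2, 0)
  sc$s_final <- s_final
  sc
}

test_that("region calling finds maximal positive runs with filters", {
  p1 <- region_params(window = 1, min_region_orfs = 4)
  # all non-positive: nothing
  expect_equal(nrow(call_viral_regions(score_table(rep(-1, 30)), p1)), 0L)
  # all positive: one whole-contig region
  whole <- call_viral_regions(score_table(rep(2, 30)), p1, tiny_db())
  expect_equal(nrow(whole), 1L)
  expect_equal(c(whole$first_ordinal, whole$last_ordinal), c(1L, 30L))
  expect_equal(whole$length_bp, whole$end - whole$start + 1L)
  # short runs are dropped
  s <- rep(-1, 20); s[5:7] <- 2
  expect_equal(nrow(call_viral_regions(score_table(s), p1)), 0L)
  # runs without a GVOG hit are dropped unless the flag is off
  s <- rep(-1, 20); s[5:10] <- 2
  no_gvog <- score_table(s, gvog = rep(FALSE, 20))
  expect_equal(nrow(call_viral_regions(no_gvog, p1)), 0L)
  p_nofilter <- region_params(window = 1, min_region_orfs = 4,
                              require_gvog_hit = FALSE)
  expect_equal(nrow(call_viral_regions(no_gvog, p_nofilter)), 1L)
})

test_that("region calling matches a brute-force run finder on random tracks", {
  brute_runs <- function(roll, cutoff, min_len) {
    pos <- which(roll > cutoff)
    if (length(pos) == 0) return(NULL)
    runs <- split(pos, cumsum(c(1, diff(pos) != 1)))
    runs <- Filter(function(r) length(r) >= min_len, runs)
    if (length(runs) == 0) return(NULL)
    cbind(first = vapply(runs, min, numeric(1)),
          last = vapply(runs, max, numeric(1)))
  }
  set.seed(77)
  p <- region_params(window = 5, min_region_orfs = 3,
                     require_gvog_hit = FALSE)
  for (rep in 1:25) {
    s <- rnorm(60, sd = 2)
    tab <- score_table(s)
    got <- call_viral_regions(tab, p)
    roll <- rolling_average(s, 5)
    want <- brute_runs(roll, 0, 3)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$first_ordinal, unname(want[, "first"]))
      expect_equal(got$last_ordinal, unname(want[, "last"]))
      # maximality: every run is bounded by a non-positive window or an edge
      for (k in seq_len(nrow(got))) {
        if (got$first_ordinal[k] > 1) {
          expect_lte(roll[got$first_ordinal[k] - 1], 0)
        }
        if (got$last_ordinal[k] < 60) {
          expect_lte(roll[got$last_ordinal[k] + 1], 0)
        }
      }
    }
  }
})

test_that("region calling is symmetric under score reversal", {
  set.seed(9)
  s <- rnorm(40)
  p <- region_params(window = 3, min_region_orfs = 2,
                     require_gvog_hit = FALSE)
  fwd <- call_viral_regions(score_table(s), p)
  rev_ <- call_viral_regions(score_table(rev(s)), p)
  expect_equal(nrow(fwd), nrow(rev_))
  if (nrow(fwd) > 0) {
    expect_equal(sort(41L - fwd$last_ordinal), sort(rev_$first_ordinal))
    expect_equal(sort(41L - fwd$first_ordinal), sort(rev_$last_ordinal))
  }
})

test_that("marker reporting counts best-hit marker ORFs per contig", {
  db <- tiny_db()
  orfs <- tiny_orfs(4)
  hits <- rbind(hit("c1_1", "GVOG_MARK", "GVOG", 120),
                hit("c1_3", "GVOG_SPEC", "GVOG", 90))
  sc <- score_all_orfs(orfs, best_hit_per_orf(hits), db)
  mk <- report_markers(sc, db)
  expect_equal(mk$MCP, 1L)
  expect_equal(sum(unlist(mk[GV_MARKERS])), 1L)
  # no marker hits anywhere: all-zero map
  sc0 <- score_all_orfs(orfs, best_hit_per_orf(hit("c1_2", "GVOG_SPEC",
                                                   "GVOG", 50)), db)
  expect_equal(sum(unlist(report_markers(sc0, db)[GV_MARKERS])), 0L)
})

test_that("contig summary uses raw means, not the rolling track", {
  db <- tiny_db()
  s <- c(5, -1, -1, -1, 5)          # rolling(3) mean != raw mean at edges
  tab <- score_table(s)
  sm <- contig_summary(tab, db, region_params(window = 3,
                                              require_gvog_hit = FALSE))
  expect_equal(sm$mean_score, mean(s))
  expect_equal(sm$n_orfs, 5L)
  expect_equal(sm$call, classify_contig(mean(s), 0))
})

test_that("BED export converts to 0-based half-open coordinates", {
  p1 <- region_params(window = 1, min_region_orfs = 2)
  reg <- call_viral_regions(score_table(rep(1, 5)), p1, tiny_db())
  path <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(reg, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, reg$start - 1L)
  expect_equal(bed$V3, reg$end)
  expect_equal(bed$V3 - bed$V2, reg$length_bp)
})
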