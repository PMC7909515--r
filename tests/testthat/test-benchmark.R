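test_that("shredding gives non-overlapping in-range deterministic fragments", {
  # degenerate uniform: exact tiling
  fr <- shred("p", 50000, min_len = 10000, max_len = 10000, seed = 1)
  expect_equal(nrow(fr), 5L)
  expect_equal(fr$offset, seq(0L, 40000L, by = 10000L))
  expect_equal(fr$id[1], "p|0|10000")
  # too-short parent: empty with a notice
  expect_message(fr0 <- shred("tiny", 4999, min_len = 5000, seed = 1),
                 "shorter")
  expect_equal(nrow(fr0), 0L)
  # determinism and invariants on a large parent
  a <- shred("big", 1e6, 5000, 100000, seed = 42)
  b <- shred("big", 1e6, 5000, 100000, seed = 42)
  expect_identical(a, b)
  expect_true(all(a$length >= 5000 & a$length <= 100000))
  expect_true(all(a$offset + a$length <= 1e6))
  # fragments tile a prefix of the parent with no gaps or overlap
  expect_equal(a$offset, c(0, cumsum(a$length))[seq_len(nrow(a))])
})

test_that("shredding across random parents keeps fragments contiguous", {
  set.seed(33)
  for (rep in 1:10) {
    len <- sample(20000:400000, 1)
    fr <- shred("x", len, 5000, 50000, seed = rep)
    if (nrow(fr) == 0) next
    expect_equal(fr$offset[1], 0L)
    expect_equal(diff(fr$offset), fr$length[-nrow(fr)])
    expect_lte(sum(fr$length), len)
    expect_lt(len - sum(fr$length), 5000)   # only a sub-minimum tail is lost
  }
})

test_that("specificity and sensitivity reproduce benchmark arithmetic", {
  expect_equal(specificity(879, 7), 99.2)
  expect_equal(specificity(2973, 142), 95.2)
  expect_equal(false_positive_rate(2973, 142), 4.8)
  expect_equal(sensitivity(38896, 657), 98.3)
  expect_equal(specificity(10, 0), 100.0)
  expect_equal(sensitivity(100, 100), 0.0)
  expect_error(specificity(0, 0), "undefined")
  expect_error(sensitivity(0, 0), "undefined")
  # complement identity holds exactly, including rounding
  for (n in c(879, 2973, 17)) {
    for (fp in c(0, 1, n %/% 3, n)) {
      expect_identical(specificity(n, fp) + false_positive_rate(n, fp), 100)
    }
  }
})

test_that("N50 matches a brute-force oracle on random length lists", {
  brute_n50 <- function(lens) {
    half <- sum(lens) / 2
    cand <- sort(unique(lens), decreasing = TRUE)
    for (L in cand) if (sum(lens[lens >= L]) >= half) return(L)
  }
  expect_equal(compute_n50(c(10, 8, 5, 3)), 8)
  expect_equal(compute_n50(42), 42)
  expect_equal(compute_n50(rep(5, 4)), 5)
  expect_error(compute_n50(numeric(0)), "empty")
  set.seed(17)
  for (rep in 1:200) {
    lens <- sample(1:5000, sample(1:60, 1), replace = TRUE)
    expect_equal(compute_n50(lens), brute_n50(lens))
  }
})

test_that("single-linkage clusters equal transitive-closure components", {
  # chaining below the threshold
  d <- data.frame(id1 = c("a", "b"), id2 = c("b", "c"),
                  distance = c(0.02, 0.04))
  cl <- single_linkage_clusters(d, c("a", "b", "c", "d"))
  expect_equal(length(unique(cl$cluster_id)), 2L)
  expect_equal(cl$cluster_id[cl$genome_id == "a"],
               cl$cluster_id[cl$genome_id == "c"])
  # the threshold is strict
  d2 <- data.frame(id1 = "a", id2 = "b", distance = 0.05)
  cl2 <- single_linkage_clusters(d2, c("a", "b"))
  expect_equal(length(unique(cl2$cluster_id)), 2L)
  expect_error(single_linkage_clusters(
    data.frame(id1 = "zz", id2 = "a", distance = 0.01), c("a", "b")),
    "unknown")

  # random graphs vs an independent reachability oracle
  set.seed(23)
  for (rep in 1:15) {
    ids <- paste0("g", 1:20)
    n_edges <- sample(5:40, 1)
    d <- data.frame(id1 = sample(ids, n_edges, replace = TRUE),
                    id2 = sample(ids, n_edges, replace = TRUE),
                    distance = runif(n_edges, 0, 0.1))
    d <- d[d$id1 != d$id2, ]
    cl <- single_linkage_clusters(d, ids, 0.05)
    # oracle: boolean transitive closure of the adjacency matrix
    adj <- diag(TRUE, 20)
    dimnames(adj) <- list(ids, ids)
    link <- d[d$distance < 0.05, ]
    for (k in seq_len(nrow(link))) {
      adj[link$id1[k], link$id2[k]] <- TRUE
      adj[link$id2[k], link$id1[k]] <- TRUE
    }
    repeat {
      nxt <- (adj %*% adj) > 0
      if (identical(nxt, adj > 0)) break
      adj <- nxt
    }
    same_oracle <- outer(seq(20), seq(20),
                         Vectorize(function(i, j) adj[i, j]))
    same_pkg <- outer(cl$cluster_id, cl$cluster_id, "==")
    expect_equal(unname(same_pkg), unname(same_oracle))
    # edge-order invariance
    perm <- d[sample(nrow(d)), ]
    cl_perm <- single_linkage_clusters(perm, ids, 0.05)
    expect_equal(cl_perm$cluster_id, cl$cluster_id)
  }
})

test_that("representatives maximize N50 with lexicographic ties", {
  expect_equal(select_representative(c("g1", "g2"), c(g1 = 8, g2 = 12)), "g2")
  expect_equal(select_representative(c("g2", "g1"), c(g1 = 8, g2 = 8)), "g1")
  expect_equal(select_representative("g1", c(g1 = 1)), "g1")
  expect_error(select_representative(character(0), c(g1 = 1)), "empty")
  der <- dereplicate_genomes(
    data.frame(id1 = "a", id2 = "b", distance = 0.01),
    c("a", "b", "c"), c(a = 5, b = 9, c = 2))
  expect_equal(der$genome_id[der$is_representative], c("b", "c"))
})

test_that("genome quality filter enumerates its failed criteria", {
  ok <- quality_filter(rep(1e5, 12),
                       c(A32 = 1, PolB = 1, VLTF3 = 1, SFII = 1))
  expect_true(ok$pass)
  expect_equal(length(ok$failed), 0L)
  miss <- quality_filter(rep(1e5, 12),
                         c(A32 = 1, PolB = 0, VLTF3 = 1, SFII = 1))
  expect_false(miss$pass)
  expect_equal(miss$failed, "missing_single_copy_marker")
  dup <- quality_filter(rep(1e5, 12),
                        c(A32 = 1, PolB = 2, VLTF3 = 1, SFII = 1),
                        duplicate_marker_min_identity = 0.85)
  expect_equal(dup$failed, "divergent_duplicate_marker")
  # 90% identity duplicates are tolerated (strict "<")
  dup90 <- quality_filter(rep(1e5, 12),
                          c(A32 = 1, PolB = 2, VLTF3 = 1, SFII = 1),
                          duplicate_marker_min_identity = 0.90)
  expect_true(dup90$pass)
  frag <- quality_filter(rep(1e4, 30),
                         c(A32 = 1, PolB = 1, VLTF3 = 1, SFII = 1),
                         flagged_low_quality = TRUE)
  expect_equal(frag$failed, c("too_many_contigs", "flagged_low_quality"))
})
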