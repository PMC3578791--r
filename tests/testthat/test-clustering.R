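dm3 <- function(ab, ac, bc) {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- ab
  d["A", "C"] <- d["C", "A"] <- ac
  d["B", "C"] <- d["C", "B"] <- bc
  as_dm(d)
}

test_that("furthest-neighbor merges at complete-linkage heights", {
  dend <- cluster_furthest_neighbor(dm3(0.01, 0.10, 0.10))
  expect_equal(dend$merges[[1]], list(height = 0.01, members = c("A", "B")))
  expect_equal(dend$merges[[2]],
               list(height = 0.10, members = c("A", "B", "C")))

  # all-zero distances: every merge at height 0
  z <- cluster_furthest_neighbor(as_dm(matrix(0, 3, 3,
    dimnames = list(c("x", "y", "z"), c("x", "y", "z")))))
  expect_true(all(vapply(z$merges, `[[`, numeric(1), "height") == 0))

  # final merge height is the complete-linkage maximum regardless of ties
  tied <- cluster_furthest_neighbor(dm3(0.04, 0.12, 0.04))
  expect_equal(tied$merges[[2]]$height, 0.12)
})

test_that("distances are rounded to the precision grid before merging", {
  d <- dm3(0.00004, 0.00006, 0.2)
  dend <- cluster_furthest_neighbor(d, precision = 10000L)
  # 0.00004 rounds down to 0, 0.00006 rounds up to 0.0001
  expect_equal(dend$merges[[1]]$height, 0)
  coarse <- cluster_furthest_neighbor(d, precision = 100L)
  expect_equal(vapply(coarse$merges, `[[`, numeric(1), "height"),
               c(0, 0.2))
})

test_that("tie-breaking follows the lexicographically smallest members", {
  d <- matrix(0.05, 4, 4,
              dimnames = list(c("d", "c", "b", "a"), c("d", "c", "b", "a")))
  diag(d) <- 0
  dend <- cluster_furthest_neighbor(as_dm(d))
  expect_equal(dend$merges[[1]]$members, c("a", "b"))
})

test_that("agglomeration matches the brute-force oracle on random matrices", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(3:12, 1)
    m <- random_dm(n)
    got <- cluster_furthest_neighbor(m)$merges
    want <- oracle_complete_linkage(m)
    expect_equal(got, want)
  }
})

test_that("agglomeration heights agree with stats::hclust complete linkage", {
  set.seed(32)
  m <- random_dm(8)
  dend <- cluster_furthest_neighbor(m, precision = 1e7)
  hc <- stats::hclust(stats::as.dist(m$d), method = "complete")
  expect_equal(sort(vapply(dend$merges, `[[`, numeric(1), "height")),
               sort(hc$height), tolerance = 1e-6)
})

test_that("partitions honor the closed cutoff and refine monotonically", {
  dend <- cluster_furthest_neighbor(dm3(0.01, 0.10, 0.10))
  p <- partition_at(dend, 0.05)
  expect_equal(p$otus, list(c("A", "B"), list("C")[[1]]))
  expect_equal(length(partition_at(dend, 0)$otus), 3L)
  expect_equal(length(partition_at(dend, 0.10)$otus), 1L)  # closed cutoff
  expect_equal(length(partition_at(dend, 1)$otus), 1L)
  expect_error(partition_at(dend, -0.1), ">= 0")

  set.seed(33)
  for (rep in 1:10) {
    m <- random_dm(sample(4:10, 1))
    dd <- cluster_furthest_neighbor(m)
    cuts <- c(0, 0.01, 0.05, 0.1, 0.3, 1)
    counts <- vapply(cuts, function(cc) n_otus(dd, cc), integer(1))
    expect_true(all(diff(counts) <= 0))
    # complete-linkage guarantee on the rounded grid
    for (cc in cuts) {
      for (otu in partition_at(dd, cc)$otus) {
        if (length(otu) > 1L) {
          sub <- round(m$d[otu, otu] * 10000) / 10000
          expect_true(max(sub) <= cc + 1e-9)
        }
      }
    }
  }
})

test_that("maximum corrected distance follows the 90% single-OTU rule", {
  # 9 identical sequences + 1 outlier: satisfied already at cutoff 0
  n <- 10
  d <- matrix(0, n, n)
  d[n, -n] <- d[-n, n] <- 0.30
  nms <- sprintf("s%02d", 1:n)
  dimnames(d) <- list(nms, nms)
  dend <- cluster_furthest_neighbor(as_dm(d))
  expect_equal(max_corrected_distance(dend, 0.9), 0)

  # 4 sequences all mutually at 0.10: need all four (0.9*4 = 3.6)
  d4 <- matrix(0.10, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d4) <- 0
  dend4 <- cluster_furthest_neighbor(as_dm(d4))
  expect_equal(max_corrected_distance(dend4, 0.9), 0.10)

  expect_error(max_corrected_distance(dend4, 0), "in \\(0, 1\\]")

  # never exceeds the maximum pairwise distance; equals the last merge
  # height when fraction = 1 forces it
  set.seed(34)
  for (rep in 1:10) {
    m <- random_dm(sample(4:12, 1))
    dd <- cluster_furthest_neighbor(m)
    mc <- max_corrected_distance(dd, 0.9)
    expect_lte(mc, max(round(m$d * 10000) / 10000))
    last_h <- dd$merges[[length(dd$merges)]]$height
    expect_lte(max_corrected_distance(dd, 1), last_h)
  }
})

test_that("clustering pattern reports OTU percentages relative to 0 distance", {
  laby <- diversity_stats("Labyrinthulida", 29L, 0.17, 0.35, 0.34,
                          c("0.00" = 26L, "0.01" = 19L, "0.05" = 17L))
  pct <- clustering_pattern(laby)
  expect_equal(unname(pct["0.00"]), 100)
  expect_equal(unname(pct["0.05"]), 100 * 17 / 26)
  expect_equal(round(unname(pct["0.05"])), 65)

  mast4 <- diversity_stats("MAST-4", 92L, 0.03, 0.07, 0.06,
                           c("0.00" = 60L, "0.01" = 24L, "0.05" = 3L))
  expect_equal(unname(clustering_pattern(mast4)["0.05"]), 5)

  expect_error(clustering_pattern(laby, cutoffs = c(0, 0.1)),
               "no OTU count at cutoff")
  no_zero <- diversity_stats("x", 5L, 0.1, 0.2, 0.2,
                             c("0.01" = 4L, "0.05" = 2L))
  expect_error(clustering_pattern(no_zero), "cutoff 0")
})

test_that("diversity statistics enforce their invariants", {
  expect_error(
    diversity_stats("x", 5L, 0.1, 0.2, 0.3,
                    c("0.00" = 5L, "0.01" = 3L)),
    "max_corrected")
  expect_error(
    diversity_stats("x", 5L, 0.1, 0.2, 0.2,
                    c("0.00" = 3L, "0.01" = 4L)),
    "non-increasing")
  expect_error(
    diversity_stats("x", 2L, 0.1, 0.2, 0.2, c("0.00" = 5L, "0.01" = 3L)),
    "exceeds n_seq")
})

test_that("group diversity computed end to end on a known alignment", {
  # two identical pairs at distance 0.304 between pairs
  aln <- group_alignment(c("ACGTACGT", "ACGTACGT", "ACGAACGA", "ACGAACGA"),
                         c("a", "b", "c", "d"))
  stats <- group_diversity(distance_matrix(aln), group_id = "demo")
  expect_equal(stats$n_seq, 4L)
  expect_equal(stats$max, jukes_cantor(0.25))
  expect_equal(unname(stats$otu_counts),
               c(2L, 2L, 2L, 2L))  # pairs merge at 0, unite only at 0.29
  expect_equal(stats$max_corrected,
               round(jukes_cantor(0.25) * 10000) / 10000)
})

test_that("the group report carries per-group rows plus a totals row", {
  g1 <- diversity_stats("one", 2L, 0, 0, 0,
                        c("0.00" = 1L, "0.01" = 1L, "0.05" = 1L))
  g2 <- diversity_stats("two", 6L, 0.1, 0.2, 0.15,
                        c("0.00" = 6L, "0.01" = 3L, "0.05" = 2L))
  rep <- group_report(list(g1, g2))
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$Group, c("one", "two", "Total"))
  expect_equal(rep$OTU_0.01, c(1L, 3L, 4L))
  expect_equal(rep$Seq[3], 8L)
  expect_true(is.na(rep$Avg[3]))
  g3 <- diversity_stats("three", 3L, 0, 0, 0, c("0.00" = 1L))
  expect_error(group_report(list(g1, g3)), "same cutoffs")
})

test_that("mothur-style list files carry one line per cutoff", {
  dend <- cluster_furthest_neighbor(dm3(0.01, 0.10, 0.10))
  f <- withr::local_tempfile(fileext = ".list")
  write_list_file(dend, c(0, 0.01, 0.05, 0.10), f)
  lines <- strsplit(readLines(f), "\t")
  expect_length(lines, 4L)
  expect_equal(lines[[1]], c("0.00", "3", "A", "B", "C"))
  expect_equal(lines[[2]], c("0.01", "2", "A,B", "C"))
  expect_equal(lines[[4]], c("0.10", "1", "A,B,C"))
})
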