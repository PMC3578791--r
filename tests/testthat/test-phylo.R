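tree3 <- function() {
  structured_tree(ape::read.tree(text = "((a:1,b:1):1,c:2);"))
}

test_that("newick reading validates branch lengths and round-trips", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:1):1,c:2);", f)
  st <- read_newick(f)
  expect_equal(ape::Ntip(st$tree), 3L)
  expect_length(st$tree$edge.length, 4L)

  writeLines("((a,b),c);", f)
  expect_error(read_newick(f), "branch lengths")

  # round trip preserves topology and lengths
  st2 <- simulate_yule_tree(12, seed = 9)
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(st2, f2)
  back <- read_newick(f2)
  expect_true(ape::all.equal.phylo(st2$tree, back$tree,
                                   use.edge.length = TRUE))
})

test_that("tip-group maps attach from TSV and reject unknown tips", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:1):1,c:2);", f)
  map <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tip_name\tgroup_id", "a\tG1", "b\tG1", "c\tG2"), map)
  st <- read_newick(f, map)
  expect_equal(unname(st$groups[c("a", "c")]), c("G1", "G2"))
  writeLines(c("tip_name\tgroup_id", "a\tG1", "zzz\tG2"), map)
  expect_error(read_newick(f, map), "zzz")
})

test_that("mean-path-length smoothing produces ultrametric trees", {
  skew <- structured_tree(ape::read.tree(text = "((a:1,b:3):1,c:4);"))
  u <- make_ultrametric(skew)
  depths <- ape::node.depth.edgelength(u$tree)[1:3]
  expect_equal(max(depths) - min(depths), 0, tolerance = 1e-9)
  expect_true(ape::all.equal.phylo(u$tree, skew$tree,
                                   use.edge.length = FALSE))
  expect_true(all(u$tree$edge.length >= 0))

  # already-ultrametric trees are fixed points
  st <- tree3()
  same <- make_ultrametric(st)
  expect_equal(same$tree$edge.length, st$tree$edge.length,
               tolerance = 1e-9)

  star <- structured_tree(ape::read.tree(text = "(a:2,b:2,c:2);"))
  expect_equal(make_ultrametric(star)$tree$edge.length,
               star$tree$edge.length, tolerance = 1e-9)

  # smoothing perturbed ultrametric trees keeps total length in bounds
  set.seed(51)
  for (rep in 1:10) {
    st0 <- simulate_yule_tree(sample(5:15, 1))
    pert <- st0
    pert$tree$edge.length <- pert$tree$edge.length *
      stats::runif(length(pert$tree$edge.length), 0.9, 1.1)
    u2 <- make_ultrametric(pert)
    expect_true(ape::is.ultrametric(u2$tree, tol = 1e-8))
    expect_equal(sum(u2$tree$edge.length), sum(pert$tree$edge.length),
                 tolerance = 0.2)
  }
})

test_that("branching times list internal-node depths in decreasing order", {
  expect_equal(branching_times(tree3()), c(2, 1))
  st <- simulate_yule_tree(10, seed = 52)
  bt <- branching_times(st)
  expect_length(bt, 9L)
  expect_true(all(diff(bt) <= 0))
  skew <- structured_tree(ape::read.tree(text = "((a:1,b:3):1,c:4);"))
  expect_error(branching_times(skew), "not ultrametric")
  # zero-length internal branches give duplicated times
  z <- structured_tree(
    ape::read.tree(text = "(((a:1,b:1):0,c:1):1,d:2);"))
  expect_equal(branching_times(z), c(2, 1, 1))
})

test_that("LTT curves are standardized to relative time and percent", {
  curve <- ltt_curve(tree3())
  expect_equal(curve$points$relative_time, c(-1, -0.5, 0))
  expect_equal(curve$points$lineage_percent, c(200 / 3, 100, 100))
  expect_equal(curve$n_tips, 3L)

  # 2-tip tree: flat at 100%
  two <- structured_tree(ape::read.tree(text = "(a:1,b:1);"))
  expect_equal(ltt_curve(two)$points$lineage_percent, c(100, 100))

  # comb with equal intervals: evenly spaced steps, non-decreasing
  comb <- structured_tree(
    ape::read.tree(text = "(((a:1,b:1):1,c:2):1,d:3);"))
  pts <- ltt_curve(comb)$points
  expect_equal(pts$relative_time, c(-1, -2 / 3, -1 / 3, 0))
  expect_equal(pts$lineage_percent, c(50, 75, 100, 100))
  set.seed(53)
  st <- simulate_yule_tree(20)
  pts2 <- ltt_curve(st)$points
  expect_true(all(diff(pts2$lineage_percent) >= 0))
  expect_equal(nrow(pts2), 20L)  # n-1 steps + the present endpoint
  expect_equal(pts2$lineage_percent[nrow(pts2)], 100)
})

test_that("gamma matches the hand-computed example and ape's gammaStat", {
  g <- gamma_statistic(tree3())       # g2 = g3 = 1, T = 5
  expect_equal(g$T, 5)
  expect_equal(unname(g$g), c(1, 1))
  expect_equal(g$gamma, (2 - 2.5) / (5 * sqrt(1 / 12)))
  expect_equal(g$gamma, -0.3464, tolerance = 1e-4)
  expect_equal(g$p_one_tailed, stats::pnorm(g$gamma))

  set.seed(54)
  for (rep in 1:10) {
    st <- simulate_yule_tree(sample(5:40, 1))
    expect_equal(gamma_statistic(st)$gamma, ape::gammaStat(st$tree),
                 tolerance = 1e-10)
  }

  two <- structured_tree(ape::read.tree(text = "(a:1,b:1);"))
  expect_error(gamma_statistic(two), "at least 3")
  zero <- structured_tree(ape::read.tree(text = "((a:0,b:0):0,c:0);"))
  expect_error(gamma_statistic(zero), "zero depth|degenerate")
})

test_that("gamma handles polytomies by zero-length resolution", {
  poly <- structured_tree(ape::read.tree(text = "(a:2,b:2,c:2,d:2);"))
  expect_message(g <- gamma_statistic(poly), "polytomies")
  # all branching at the root: maximally early cladogenesis for n = 4
  manual <- structured_tree(
    ape::read.tree(text = "(((a:2,b:2):0,c:2):0,d:2);"))
  expect_equal(g$gamma, gamma_statistic(manual)$gamma)
})

test_that("classification is one-tailed in the direction of the sign", {
  g <- list(gamma = -3.64, p_one_tailed = stats::pnorm(-3.64))
  expect_equal(classify_gamma(g), "negative")
  g2 <- list(gamma = 16.72, p_one_tailed = stats::pnorm(-16.72))
  expect_equal(classify_gamma(g2), "positive")
  g3 <- list(gamma = -0.35, p_one_tailed = stats::pnorm(-0.35))
  expect_equal(classify_gamma(g3), "zero")
})

test_that("MPD and intergroup distances match the path oracle", {
  st <- structured_tree(ape::read.tree(text = "((a:1,b:1):1,c:2);"),
                        groups = c(a = "G", b = "G", c = "G"))
  expect_equal(mpd(st, "G"), (2 + 4 + 4) / 3)

  two <- structured_tree(ape::read.tree(text = "((a:1,b:1):3,c:4);"),
                         groups = c(a = "X", b = "X", c = "Y"))
  expect_equal(mpd(two, "X"), 2)
  expect_error(mpd(two, "Y"), "fewer than 2")
  ig <- intergroup_distances(two)
  expect_equal(ig$d["X", "Y"], (8 + 8) / 2)
  expect_equal(unname(ig$min_intergroup["X"]), 8)

  set.seed(55)
  for (rep in 1:5) {
    n <- sample(6:20, 1)
    st2 <- simulate_yule_tree(n)
    gids <- sample(c("A", "B"), n, replace = TRUE)
    while (length(unique(gids)) < 2 || min(table(gids)) < 2)
      gids <- sample(c("A", "B"), n, replace = TRUE)
    st2 <- structured_tree(st2$tree,
                           stats::setNames(gids, st2$tree$tip.label))
    tipsA <- names(st2$groups)[st2$groups == "A"]
    oracle <- mean(apply(
      utils::combn(tipsA, 2), 2,
      function(pr) oracle_patristic(st2$tree, pr[1], pr[2])))
    expect_equal(mpd(st2, "A"), oracle, tolerance = 1e-10)
    tipsB <- names(st2$groups)[st2$groups == "B"]
    cross <- mean(outer(tipsA, tipsB, Vectorize(function(x, y)
      oracle_patristic(st2$tree, x, y))))
    expect_equal(intergroup_distances(st2)$d["A", "B"], cross,
                 tolerance = 1e-10)
  }
})

test_that("trunk length reads the stem branch and demands monophyly", {
  st <- structured_tree(ape::read.tree(text = "((a:1,b:1):3,c:4);"),
                        groups = c(a = "G1", b = "G1", c = "G2"))
  expect_equal(trunk_length(st, "G1"), 3)
  expect_message(expect_equal(trunk_length(st, "G2"), 4), "single tip")

  bad <- structured_tree(ape::read.tree(text = "((a:1,b:1):3,c:4);"),
                         groups = c(a = "M", c = "M", b = "O"))
  expect_error(trunk_length(bad, "M"), "not monophyletic")

  whole <- structured_tree(ape::read.tree(text = "((a:1,b:1):3,c:4);"),
                           groups = c(a = "W", b = "W", c = "W"))
  expect_error(trunk_length(whole, "W"), "no stem|whole tree")
})

test_that("group subtree extraction spans the group's clade", {
  st <- structured_tree(
    ape::read.tree(text = "(((a:1,b:1):1,c:2):2,(d:1,e:1):3);"),
    groups = c(a = "P", b = "P", c = "P", d = "Q", e = "Q"))
  sub <- extract_group_tree(st, "P")
  expect_setequal(sub$tree$tip.label, c("a", "b", "c"))
  expect_equal(unname(sub$groups), rep("P", 3))
})
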