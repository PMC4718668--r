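test_that("modularity of hand-computable partitions is exact", {
  w <- two_triangles()
  # two communities matching the triangles: Q = 2 * (3/6 - (6/12)^2) = 0.5
  part <- c(1, 1, 1, 2, 2, 2)
  expect_equal(modularity_score(w, part), 0.5)
  # whole-graph single community has Q = 0 for positive weights
  expect_equal(modularity_score(w, rep(1, 6)), 0)
  # named assignment is aligned by region id
  named <- setNames(part[c(4, 5, 6, 1, 2, 3)], colnames(w)[c(4:6, 1:3)])
  expect_equal(modularity_score(w, named), 0.5)
})

test_that("sign flip swaps the roles of the positive/negative parts", {
  w <- random_signed_matrix(7, seed = 5)
  part <- c(1, 1, 2, 2, 3, 3, 3)
  s <- function(m) list(p = pmax(m, 0), n = pmax(-m, 0))
  q_orig <- modularity_score(w, part)
  q_flip <- modularity_score(-w, part)
  # recompute both from the definition Q* = Q+ - (m-/(m+ + m-)) Q-
  qpart <- function(m, memb) {
    tw <- sum(m)
    if (tw == 0) return(0)
    same <- outer(memb, memb, "==")
    k <- rowSums(m)
    sum(m[same]) / tw - sum(tapply(k, memb, sum)^2) / tw^2
  }
  sp <- s(w)
  mp <- sum(sp$p) / 2; mn <- sum(sp$n) / 2
  expect_equal(q_orig,
               qpart(sp$p, part) - (mn / (mp + mn)) * qpart(sp$n, part))
  expect_equal(q_flip,
               qpart(sp$n, part) - (mp / (mp + mn)) * qpart(sp$p, part))
})

test_that("brute force resolves 2-node graphs per the signed objective", {
  pos <- matrix(c(0, 0.8, 0.8, 0), 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(max(brute_force_partition(pos)$assignment), 1L)
  neg <- -pos
  expect_equal(max(brute_force_partition(neg)$assignment), 2L)
  big <- random_signed_matrix(11, seed = 1)
  expect_error(brute_force_partition(big), "TooLarge")
})

test_that("two disjoint triangles are recovered with Q = 0.5", {
  w <- two_triangles()
  bf <- brute_force_partition(w)
  dl <- detect_communities(w, seed = 1, restarts = 10)
  expect_equal(bf$Q, 0.5)
  expect_equal(dl$Q, 0.5)
  expect_equal(unname(dl$assignment), c(1, 1, 1, 2, 2, 2))
  expect_equal(unname(bf$assignment), unname(dl$assignment))
})

test_that("detection matches the brute-force optimum on random graphs", {
  matched <- 0L
  n_graphs <- 30L
  for (i in seq_len(n_graphs)) {
    w <- random_signed_matrix(sample(4:8, 1), seed = 100 + i)
    bf <- brute_force_partition(w)
    dl <- detect_communities(w, seed = i, restarts = 20)
    expect_lte(dl$Q, bf$Q + 1e-9)   # never exceeds the true optimum
    if (abs(dl$Q - bf$Q) <= 1e-9) matched <- matched + 1L
  }
  expect_gte(matched / n_graphs, 0.95)
})

test_that("empty and edgeless networks give singletons with Q = 0", {
  reg <- mini_registry(27)
  w <- matrix(0, 27, 27, dimnames = list(reg$region_id, reg$region_id))
  part <- detect_communities(as_thresholded(w), seed = 1)
  expect_equal(part$Q, 0)
  expect_equal(max(part$assignment), 27L)
  expect_equal(length(part$assignment), 27L)
})

test_that("isolated nodes stay singleton communities", {
  w <- two_triangles()
  w2 <- rbind(cbind(w, 0, 0), 0, 0)
  dimnames(w2) <- list(c(colnames(w), "x", "y"),
                       c(colnames(w), "x", "y"))
  part <- detect_communities(w2, seed = 2, restarts = 10)
  expect_equal(max(part$assignment), 4L)
  expect_false(part$assignment["x"] == part$assignment["y"])
})

test_that("Q is invariant under community relabeling and node permutation", {
  w <- random_signed_matrix(8, seed = 9)
  part <- c(1, 2, 1, 3, 2, 3, 1, 2)
  q0 <- modularity_score(w, part)
  relabeled <- c(3, 1, 3, 2, 1, 2, 3, 1)   # same grouping, new labels
  expect_equal(modularity_score(w, relabeled), q0)
  perm <- sample(8)
  expect_equal(modularity_score(w[perm, perm], part[perm]), q0)
})

test_that("detection is deterministic and its Q is self-consistent", {
  w <- random_signed_matrix(10, seed = 77)
  p1 <- detect_communities(w, gamma = 1, seed = 42, restarts = 15)
  p2 <- detect_communities(w, gamma = 1, seed = 42, restarts = 15)
  expect_identical(p1, p2)
  expect_equal(p1$Q, modularity_score(w, p1$assignment, gamma = 1))
})

test_that("positive-only mode agrees with igraph modularity", {
  w <- abs(random_signed_matrix(10, seed = 31))
  part <- detect_communities(w, seed = 3, restarts = 20,
                             positive_only = TRUE)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  q_ig <- igraph::modularity(g, membership = part$assignment,
                             weights = igraph::E(g)$weight)
  expect_equal(part$Q, q_ig, tolerance = 1e-12)
})

test_that("a strongly planted 3-block structure is recovered exactly", {
  reg <- mini_registry(9, blocks = 3)
  blocks <- split(reg$region_id, reg$area_group)
  spec <- covariance_spec(blocks, within_r = 0.8, between_r = 0)
  groups <- data.frame(gene = "cfos", age = "adult", treatment = "saline",
                       n_subjects = 200L, stringsAsFactors = FALSE)
  groups$spec <- list(spec)
  tab <- simulate_expression(simulation_design(groups, seed = 8L), reg)
  net <- pearson_network(tab, "cfos", "adult", "saline", reg)
  thr <- threshold_network(net, 0.05)
  part <- detect_communities(thr, seed = 1, restarts = 20)
  planted <- match(reg$area_group, unique(reg$area_group))
  found <- part$assignment[reg$region_id]
  # identical partitions up to labeling
  expect_equal(length(unique(paste(planted, found))), 3L)
  expect_equal(max(found), 3L)
})

test_that("partition export writes the documented columns", {
  w <- two_triangles()
  part <- detect_communities(w, seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_partition(part, f)
  back <- utils::read.delim(f)
  expect_equal(names(back), c("region_id", "community", "Q", "method",
                              "seed"))
  expect_equal(back$community, unname(part$assignment))
})
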