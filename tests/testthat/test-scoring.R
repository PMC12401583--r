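test_that("amspl: basic values, identity, and source-set orientation", {
  P5 <- path_graph(5)
  D <- all_pairs_shortest_path(P5)
  expect_equal(amspl(node_set("v0", "A"), node_set("v4", "B"), D), 4)

  A <- node_set(c("v0", "v2"), "A")
  expect_equal(amspl(A, A, D), 0)  # min includes self, diagonal is 0

  st <- star_graph(3)
  Ds <- all_pairs_shortest_path(st)
  expect_equal(amspl(node_set(c("l1", "l2"), "A"), node_set("c", "B"), Ds), 1)

  # asymmetry is real: P(A,B) != P(B,A)
  A2 <- node_set(c("v0", "v1"), "A")
  B2 <- node_set("v4", "B")
  expect_equal(amspl(A2, B2, D), 3.5)
  expect_equal(amspl(B2, A2, D), 3)
  expect_false(amspl(A2, B2, D) == amspl(B2, A2, D))
})

test_that("amspl equals the brute-force oracle on random triples", {
  set.seed(77)
  for (i in 1:20) {
    g <- random_er(30, 0.1, i, weighted = i %% 2 == 0)
    D <- all_pairs_shortest_path(g)
    ids <- igraph::V(g)$name
    A <- node_set(sample(ids, sample(2:6, 1)), "A")
    B <- node_set(sample(ids, sample(2:6, 1)), "B")
    expect_identical(suppressWarnings(amspl(A, B, D)),
                     suppressWarnings(amspl_oracle(A, B, D)))
  }
})

test_that("symmetric amspl: swap invariance and hand-computed value", {
  P5 <- path_graph(5)
  D <- all_pairs_shortest_path(P5)
  expect_equal(symmetric_amspl(node_set("v0", "A"), node_set("v4", "B"), D), 4)
  A <- node_set(c("v0", "v1"), "A")
  B <- node_set("v4", "B")
  expect_equal(symmetric_amspl(A, B, D), 10 / 3)  # (3 + 4 + 3) / 3
  expect_equal(symmetric_amspl(A, B, D), symmetric_amspl(B, A, D))
})

test_that("internal distance: pairs, singletons, cliques", {
  P5 <- path_graph(5)
  D <- all_pairs_shortest_path(P5)
  expect_equal(internal_distance(node_set(c("v0", "v2"), "A"), D), 2)
  expect_equal(internal_distance(node_set("v3", "A"), D), 0)
  k4 <- make_interactome(t(combn(c("a", "b", "c", "d"), 2)))
  Dk <- all_pairs_shortest_path(k4)
  expect_equal(internal_distance(node_set(c("a", "b", "c"), "A"), Dk), 1)
})

test_that("separation identities hold exactly", {
  P5 <- path_graph(5)
  D <- all_pairs_shortest_path(P5)
  A <- node_set(c("v0", "v2"), "A")
  s_aa <- separation(A, A, D)
  expect_equal(s_aa$s_ab, -2)            # 0 - (2+2)/2
  expect_equal(s_aa$s_ab, -s_aa$d_aa)

  # singletons at distance d
  sv <- separation(node_set("v0", "A"), node_set("v3", "B"), D)
  expect_equal(sv$s_ab, 3)

  # invariant on random calls, exact
  set.seed(5)
  for (i in 1:20) {
    g <- random_er(40, 0.1, i)
    Dg <- all_pairs_shortest_path(g)
    ids <- igraph::V(g)$name
    sep <- suppressWarnings(
      separation(node_set(sample(ids, 5), "A"), node_set(sample(ids, 5), "B"), Dg))
    expect_equal(sep$s_ab, sep$d_ab - (sep$d_aa + sep$d_bb) / 2,
                 tolerance = 1e-12)
  }
})

test_that("z_and_p: tails, add-one convention, degeneracy", {
  zp <- z_and_p(2, c(1, 2, 3), "lower")
  expect_equal(zp$z, 0)
  expect_equal(zp$p_empirical, 0.75)

  zp2 <- z_and_p(-5, rnorm(99) , "lower")
  expect_equal(zp2$p_empirical, 1 / 100)

  zp3 <- z_and_p(1, rep(1, 10), "lower")
  expect_true(zp3$degenerate)
  expect_true(is.na(zp3$z))
  expect_equal(zp3$p_empirical, 1.0)

  zp4 <- z_and_p(0, c(-1, 1, -2, 2), "two_sided")
  expect_equal(zp4$p_empirical, 1.0)
  # population sd, not sample sd
  expect_equal(z_and_p(4, c(0, 2), "upper")$z, 3)
})

test_that("proximity: identity sets score zero and are never anti-close", {
  g <- random_er(80, 0.08, 10)
  D <- all_pairs_shortest_path(g)
  set.seed(4)
  A <- node_set(sample(igraph::V(g)$name, 6), "A")
  pr <- proximity(g, A, A, D, null_model_spec("uniform"), n_iter = 50, seed = 1)
  expect_equal(pr$raw, 0)
  expect_true(is.na(pr$z) || pr$z <= 0)
  expect_length(pr$null_samples, 50)
  expect_equal(pr$p_empirical, (1 + sum(pr$null_samples <= 0)) / 51)
})

test_that("proximity and separation runs are reproducible from the seed", {
  g <- random_er(60, 0.1, 2)
  D <- all_pairs_shortest_path(g)
  set.seed(8)
  A <- node_set(sample(igraph::V(g)$name, 5), "A")
  B <- node_set(sample(igraph::V(g)$name, 5), "B")
  spec <- null_model_spec("degree_match")
  p1 <- proximity(g, A, B, D, spec, n_iter = 30, seed = 99)
  p2 <- proximity(g, A, B, D, spec, n_iter = 30, seed = 99)
  expect_identical(p1$null_samples, p2$null_samples)
  s1 <- separation_significance(g, A, B, D, spec, n_iter = 30, seed = 99)
  s2 <- separation_significance(g, A, B, D, spec, n_iter = 30, seed = 99)
  expect_identical(s1$null_samples, s2$null_samples)
  expect_equal(s1$raw, separation(A, B, D)$s_ab)
})

test_that("separation significance: sign properties", {
  P5 <- path_graph(5)
  D <- all_pairs_shortest_path(P5)
  A <- node_set(c("v0", "v2"), "A")
  sr <- separation_significance(P5, A, A, D, null_model_spec("uniform"),
                                n_iter = 20, seed = 3)
  expect_equal(sr$raw, -2)  # s(A,A) = -d_AA < 0 for a non-clique set

  # disjoint far-apart modules separate positively
  g <- make_interactome(data.frame(
    a = c("a1", "a2", "a1", "m", "b1", "b2", "b1"),
    b = c("a2", "a3", "a3", "a1", "b2", "b3", "b3")))
  g <- make_interactome(rbind(igraph::as_data_frame(g)[, 1:2],
                              data.frame(from = c("m", "x", "y"),
                                         to = c("x", "y", "b1"))))
  Dg <- all_pairs_shortest_path(g)
  sep <- separation(node_set(c("a1", "a2", "a3"), "A"),
                    node_set(c("b1", "b2", "b3"), "B"), Dg)
  expect_gt(sep$s_ab, 0)
})

test_that("lcc significance: raw sizes and side", {
  g <- random_er(200, 0.01, 31)
  mod <- plant_connected_module(g, 10, seed = 1)
  spec <- null_model_spec("uniform")
  sr <- lcc_significance(g, mod, spec, n_iter = 50, seed = 2)
  expect_equal(sr$raw, 10)
  expect_equal(sr$side, "upper")

  st <- star_graph(5)
  leaves <- node_set(paste0("l", 1:4), "ind")
  sr2 <- lcc_significance(st, leaves, spec, n_iter = 20, seed = 3)
  expect_equal(sr2$raw, 1)
})

test_that("unreachable members are excluded with a warning", {
  two <- make_interactome(data.frame(a = c("a", "b", "x"),
                                     b = c("b", "c", "y")))
  D <- all_pairs_shortest_path(two)
  A <- node_set(c("a", "x"), "A")
  B <- node_set("c", "B")
  expect_warning(v <- amspl(A, B, D), "unreachable")
  expect_equal(v, 2)  # only a contributes
  # fully unreachable: error
  expect_error(suppressWarnings(amspl(node_set(c("x", "y"), "X"), B, D)),
               "no source")
})

test_that("amspl is finite under all four metrics on a connected fixture", {
  g <- random_er(40, 0.15, 12)
  g <- largest_connected_component(g)
  ids <- igraph::V(g)$name
  A <- node_set(ids[1:4], "A")
  B <- node_set(ids[5:8], "B")
  for (m in c("shortest_path", "random_walk", "biased_random_walk",
              "communicability")) {
    D <- compute_distance_matrix(g, m)
    expect_true(is.finite(amspl(A, B, D)), info = m)
  }
})
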