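# Classical baselines: degree, closeness (+ harmonic fallback),
# betweenness, eigenvector.

test_that("degree centrality counts distinct merged edges by direction", {
  star <- make_net(rep("hub", 3), c("x", "y", "z"))
  expect_equal(unname(degree_centrality(star, "out")$scores["hub"]), 3)
  sv_in <- degree_centrality(star, "in")
  expect_equal(unname(sv_in$scores[c("hub", "x", "y", "z")]), c(0, 1, 1, 1))

  K4 <- expand.grid(s = letters[1:4], t = letters[1:4])
  K4 <- K4[K4$s != K4$t, ]
  complete <- make_net(as.character(K4$s), as.character(K4$t))
  expect_true(all(degree_centrality(complete, "in")$scores == 3))
  expect_true(all(degree_centrality(complete, "out")$scores == 3))

  # duplicate rows merge before counting
  dup <- make_net(c("a", "a"), c("b", "b"))
  expect_equal(unname(degree_centrality(dup, "out")$scores["a"]), 1)
  expect_error(degree_centrality(interaction_network()), "empty")
})

test_that("standard closeness matches closed forms on reachable graphs", {
  # undirected path a-b-c as reciprocal directed edges
  path3 <- make_net(c("a", "b", "b", "c"), c("b", "a", "c", "b"))
  cc <- closeness_centrality(path3, formulation = "standard")
  expect_equal(unname(cc$scores["b"]), 0.5)
  expect_equal(unname(cc$scores["a"]), 1 / 3)
  expect_equal(cc$params$formulation_used, "standard")
})

test_that("harmonic closeness zeroes unreachable contributions and auto falls back", {
  star <- make_net(rep("centre", 3), c("x", "y", "z"))
  h <- closeness_centrality(star, formulation = "harmonic",
                            direction = "outgoing")
  expect_equal(unname(h$scores["centre"]), 3)
  expect_equal(unname(h$scores["x"]), 0)

  pairs <- make_net(c("a", "b", "c", "d"), c("b", "a", "d", "c"))
  auto <- closeness_centrality(pairs, formulation = "auto")
  expect_equal(auto$params$formulation_used, "harmonic")
  expect_equal(unname(auto$scores["a"]), 1)

  expect_error(closeness_centrality(pairs, formulation = "standard"),
               "harmonic")
})

test_that("harmonic closeness is monotone under edge addition for the source", {
  set.seed(11)
  for (i in 1:10) {
    net <- random_digraph(10, p = 0.15)
    before <- closeness_centrality(net, "harmonic")$scores
    absent <- expand.grid(s = net$nodes, t = net$nodes,
                          stringsAsFactors = FALSE)
    absent <- absent[absent$s != absent$t, ]
    key <- paste(net$edges$source, net$edges$target)
    absent <- absent[!(paste(absent$s, absent$t) %in% key), ]
    pick <- absent[sample(nrow(absent), 1L), ]
    grown <- interaction_network(rbind(net$edges,
                                       data.frame(source = pick$s, target = pick$t,
                                                  weight = 1)),
                                 nodes = net$nodes)
    after <- closeness_centrality(grown, "harmonic")$scores
    expect_gte(after[[pick$s]], before[[pick$s]] - 1e-12)
  }
})

test_that("betweenness matches hand values on path and cycle fixtures", {
  p <- make_net(c("a", "b"), c("b", "c"))
  bc <- betweenness_centrality(p)$scores
  expect_equal(unname(bc[c("a", "b", "c")]), c(0, 1, 0))

  cyc <- make_net(c("a", "b", "c"), c("b", "c", "a"))
  expect_true(all(betweenness_centrality(cyc)$scores == 1))
})

test_that("betweenness equals the exhaustive path-enumeration oracle", {
  set.seed(21)
  for (i in 1:15) {
    n <- sample(4:8, 1L)
    net <- random_digraph(n, p = 0.3)
    got <- betweenness_centrality(net)$scores
    want <- oracle_betweenness_enum(net)
    expect_equal(got, want[names(got)], tolerance = 1e-10)
  }
})

test_that("weighted betweenness treats strong ties as short paths", {
  # a->c direct (weight 1, length 1) vs a->b->c (weights 4: length 0.5)
  net <- make_net(c("a", "a", "b"), c("c", "b", "c"), w = c(1, 4, 4))
  bc <- betweenness_centrality(net, weighted = TRUE)$scores
  expect_equal(unname(bc["b"]), 1) # the strong two-hop route wins
  expect_equal(unname(betweenness_centrality(net)$scores["b"]), 0)
})

test_that("eigenvector centrality is uniform on symmetric graphs and positive", {
  K3 <- expand.grid(s = letters[1:3], t = letters[1:3])
  K3 <- K3[K3$s != K3$t, ]
  complete <- make_net(as.character(K3$s), as.character(K3$t))
  res <- eigenvector_centrality(complete)
  expect_equal(unname(res$scores$scores), rep(1 / sqrt(3), 3), tolerance = 1e-6)
  expect_gt(res$summary$dominant_eigenvalue, 0)

  frag <- interaction_network(data.frame(s = c("a", "b"), t = c("b", "a")),
                              nodes = c("a", "b", "c"))
  sc <- eigenvector_centrality(frag, epsilon_teleport = 1e-6)$scores$scores
  expect_equal(sc[["a"]], sc[["b"]], tolerance = 1e-8)
  expect_gt(sc[["a"]], sc[["c"]])
  expect_true(all(sc > 0))
})

test_that("power iteration matches the dense full-spectrum solve", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(5:20, 1L)
    net <- random_digraph(n, p = 0.25)
    got <- eigenvector_centrality(net, tol = 1e-12, max_iter = 20000)$scores$scores
    want <- oracle_eigen_dense(net)
    expect_equal(got, want[names(got)], tolerance = 1e-6)
  }
})

test_that("eigenvector scores are invariant to node relabelling", {
  set.seed(5)
  net <- random_digraph(12, p = 0.3)
  perm <- sample(net$nodes)
  relabel <- stats::setNames(sprintf("w%03d", seq_along(perm)), perm)
  renamed <- interaction_network(data.frame(
    source = unname(relabel[net$edges$source]),
    target = unname(relabel[net$edges$target]),
    weight = net$edges$weight), nodes = unname(relabel))
  a <- eigenvector_centrality(net, tol = 1e-12, max_iter = 20000)$scores$scores
  b <- eigenvector_centrality(renamed, tol = 1e-12, max_iter = 20000)$scores$scores
  expect_equal(unname(b[relabel[names(a)]]), unname(a), tolerance = 1e-8)
})
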