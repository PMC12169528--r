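# The three propagation-aware metrics: PC, MVC, DIC.

test_that("PC reproduces closed-form fixed points on tiny fixtures", {
  edgeless <- interaction_network(nodes = c("a", "b", "c", "d"))
  pc <- propagation_centrality(edgeless)$scores$scores
  expect_equal(unname(pc), rep((1 - 0.85) / 4, 4)) # empty in-sums

  pair <- make_net(c("a", "b"), c("b", "a"))
  pc2 <- propagation_centrality(pair, pc_params(tol = 1e-13, max_iter = 500))
  expect_equal(unname(pc2$scores$scores), c(0.5, 0.5), tolerance = 1e-10)
  expect_true(pc2$summary$converged)

  tri <- make_net(c("a", "a", "b"), c("b", "c", "c"))
  pc3 <- propagation_centrality(tri, pc_params(tol = 1e-13, max_iter = 500))
  expect_equal(unname(pc3$scores$scores[c("a", "b", "c")]),
               c(0.05, 0.07125, 0.1318125), tolerance = 1e-10)
})

test_that("PC equals the direct linear solve on random digraphs", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(5:50, 1L)
    net <- random_digraph(n, p = 0.15)
    got <- propagation_centrality(net, pc_params(tol = 1e-13,
                                                 max_iter = 500))$scores$scores
    want <- oracle_pc_solve(net)
    expect_equal(got, want[names(got)], tolerance = 1e-9)
  }
})

test_that("PC mass sums to one on dangling-free graphs and stays in [0, 1]", {
  set.seed(55)
  for (i in 1:10) {
    net <- random_digraph(15, p = 0.3)
    # make dangling-free: every node points somewhere
    outd <- degree_of(net, mode = "out")
    fix <- names(outd)[outd == 0]
    if (length(fix)) {
      extra <- data.frame(source = fix,
                          target = net$nodes[(match(fix, net$nodes)) %% 15 + 1L],
                          weight = 1)
      net <- interaction_network(rbind(net$edges, extra), nodes = net$nodes)
    }
    x <- propagation_centrality(net, pc_params(tol = 1e-12,
                                               max_iter = 500))$scores$scores
    expect_equal(sum(x), 1, tolerance = 1e-8)
    expect_true(all(x >= 0 & x <= 1))
  }
})

test_that("PC redistribute mode restores total mass on graphs with dangling nodes", {
  net <- make_net(c("a", "a"), c("b", "c")) # b, c dangling
  lit <- propagation_centrality(net, pc_params(tol = 1e-13, max_iter = 500))
  red <- propagation_centrality(net, pc_params(tol = 1e-13, max_iter = 500,
                                               dangling_mode = "redistribute"))
  expect_lt(sum(lit$scores$scores), 1)
  expect_equal(sum(red$scores$scores), 1, tolerance = 1e-8)
})

test_that("PC flags but does not fail when the iteration cap is reached", {
  net <- random_digraph(20, p = 0.2)
  expect_warning(
    res <- propagation_centrality(net, pc_params(max_iter = 2L, tol = 1e-15)),
    "max_iter")
  expect_false(res$summary$converged)
})

test_that("vulnerability initialisation honours its source hierarchy", {
  net <- make_net(c("a", "b"), c("c", "c"))
  # explicit vul0
  attrs <- node_attribute_table(data.frame(node_id = c("a", "b", "c"),
                                           vul0 = c(0.5, 0.5, 0.5)))
  init <- initialise_vulnerability(net, attrs)
  expect_equal(unname(init$vul), rep(0.5, 3))
  # single feature column: min-max of the feature
  attrs2 <- node_attribute_table(data.frame(node_id = c("a", "b", "c"),
                                            retweet_count = c(0L, 10L, 20L)))
  init2 <- initialise_vulnerability(net, attrs2)
  expect_equal(unname(init2$vul[c("a", "b", "c")]), c(0, 0.5, 1))
  # seeded fallback is reproducible
  i1 <- initialise_vulnerability(net, seed = 42)
  i2 <- initialise_vulnerability(net, seed = 42)
  expect_identical(i1$vul, i2$vul)
  expect_true(all(i1$vul >= 0 & i1$vul <= 1))
  # partial coverage is an error, not silent mixing
  part <- node_attribute_table(data.frame(node_id = c("a", "b"),
                                          vul0 = c(0.1, 0.2)))
  expect_error(initialise_vulnerability(net, part), "cover")
  expect_error(initialise_vulnerability(net), "source")
})

test_that("MVC follows the degree-amplification closed form and normalises", {
  net <- make_net(c("a", "b"), c("c", "c")) # in-deg: a=0, b=0, c=2
  init <- initialise_vulnerability(
    net, node_attribute_table(data.frame(node_id = c("a", "b", "c"),
                                         vul0 = c(0.3, 0.7, 0.5))))
  res <- misinformation_vulnerability_centrality(net, init, steps = 3)
  expect_equal(unname(res$trajectory$trajectory["c", ]), c(0.5, 1, 2, 4))
  expect_equal(unname(res$trajectory$vul["c"]), 2^3 * 0.5) # raw closed form
  expect_equal(unname(res$trajectory$vul["a"]), 0) # zero in-degree
  expect_equal(unname(res$scores$scores[c("a", "b", "c")]), c(0, 0, 1))
  expect_error(misinformation_vulnerability_centrality(net, init, steps = 0),
               ">= 1")
  expect_error(misinformation_vulnerability_centrality(net, init, steps = 11),
               "ceiling")
})

test_that("MVC min-max handles the stated normalisation examples", {
  # raw vector (0, 4, 8) -> (0, 0.5, 1)
  expect_equal(misinfluence:::minmax_scale(c(0, 4, 8)), c(0, 0.5, 1))
  # degenerate: all equal raw scores map to the 0.5 midpoint
  net <- make_net(c("a", "b"), c("b", "a"))
  init <- initialise_vulnerability(
    net, node_attribute_table(data.frame(node_id = c("a", "b"),
                                         vul0 = c(0.4, 0.4))))
  res <- misinformation_vulnerability_centrality(net, init, steps = 2)
  expect_equal(unname(res$scores$scores), c(0.5, 0.5))
})

test_that("MVC matches the literal recurrence and respects dominance order", {
  set.seed(202)
  for (i in 1:20) {
    n <- sample(4:30, 1L)
    net <- random_digraph(n, p = 0.2)
    vul0 <- stats::setNames(sample(0:256, n, replace = TRUE) / 256, net$nodes)
    attrs <- node_attribute_table(data.frame(node_id = net$nodes, vul0 = vul0))
    init <- initialise_vulnerability(net, attrs)
    steps <- sample(1:6, 1L)
    res <- misinformation_vulnerability_centrality(net, init, steps = steps)
    deg <- as.numeric(degree_of(net, mode = "in"))
    want <- oracle_mvc_recurrence(deg, as.numeric(vul0), steps)
    expect_identical(unname(res$trajectory$vul), want) # exact, dyadic vul0
    expect_true(all(res$scores$scores >= 0 & res$scores$scores <= 1))
  }
  # dominance order holds at every step count: a node with at least the
  # degree and at least the vulnerability of another never ranks below it
  set.seed(203)
  net <- random_digraph(20, p = 0.25)
  vul0 <- stats::setNames(stats::runif(20, 0.05, 1), net$nodes)
  init <- initialise_vulnerability(
    net, node_attribute_table(data.frame(node_id = net$nodes, vul0 = vul0)))
  deg <- degree_of(net, mode = "in")
  for (steps in c(1L, 4L, 9L)) {
    sc <- misinformation_vulnerability_centrality(net, init, steps = steps,
                                                  max_steps = 10L)$scores$scores
    for (u in net$nodes) for (v in net$nodes) {
      if (deg[[u]] >= deg[[v]] && vul0[[u]] >= vul0[[v]]) {
        expect_gte(sc[[u]], sc[[v]] - 1e-12)
      }
    }
  }
})

test_that("DIC reproduces hand-iterated trajectories", {
  lone <- interaction_network(nodes = c("a", "b"))
  res <- dynamic_influence_centrality(lone, steps = 4)
  expect_true(all(res$trajectory$values == 1))
  expect_true(all(res$scores$scores == 1)) # everyone is the max on edgeless

  path3 <- make_net(c("a", "b"), c("b", "c"))
  r <- dynamic_influence_centrality(path3, steps = 2)
  expect_equal(unname(r$trajectory$values[, 3L]), c(1, 3, 4))
  expect_equal(unname(r$scores$scores[c("a", "b", "c")]), c(0.25, 0.75, 1))

  pair <- make_net(c("a", "b"), c("b", "a"))
  rp <- dynamic_influence_centrality(pair, steps = 6)
  expect_equal(unname(rp$trajectory$values["a", ]), 2^(0:6))
})

test_that("DIC recurrence equals the matrix-power formulation entrywise", {
  set.seed(301)
  for (i in 1:15) {
    n <- sample(5:30, 1L)
    net <- random_digraph(n, p = 0.2)
    steps <- sample(1:10, 1L)
    got <- dynamic_influence_centrality(net, steps = steps)$trajectory$values
    want <- oracle_dic_power(net, steps)
    expect_identical(unname(got[, steps + 1L]), unname(want))
    # entrywise non-decreasing in t
    expect_true(all(diff(t(got)) >= 0))
  }
})

test_that("DIC guards against overflow with actionable advice", {
  K12 <- expand.grid(s = sprintf("n%02d", 1:12), t = sprintf("n%02d", 1:12),
                     stringsAsFactors = FALSE)
  K12 <- K12[K12$s != K12$t, ]
  dense <- make_net(K12$s, K12$t)
  expect_error(dynamic_influence_centrality(dense, steps = 300),
               "reduce 'steps'")
})

test_that("persistence profile ranks planted persistent spreaders first", {
  # t0 is degenerate (credits all); t1 ties b/c -> "b" by id; c leads t2-t4
  path3 <- make_net(c("a", "b"), c("b", "c"))
  r <- dynamic_influence_centrality(path3, steps = 4)
  pp <- persistence_profile(r$trajectory, k = 1)
  expect_equal(pp[1L], "c")
  expect_equal(unname(attr(pp, "persistence")[c("a", "b", "c")]),
               c(1L, 2L, 4L))
  # a node that is top-k at every step scores steps + 1
  star <- make_net(c("a", "b", "c"), c("hub", "hub", "hub"))
  rs <- dynamic_influence_centrality(star, steps = 3)
  ps <- persistence_profile(rs$trajectory, k = 4)
  expect_equal(unname(attr(ps, "persistence")["hub"]), 4L)

  lone <- interaction_network(nodes = c("b", "a", "c"))
  r2 <- dynamic_influence_centrality(lone, steps = 3)
  expect_equal(as.character(persistence_profile(r2$trajectory, k = 3)),
               c("a", "b", "c")) # all tie; ascending id
  expect_error(persistence_profile(r2$trajectory, k = 9), "exceeds")

  g <- generate_network(synthetic_spec(n = 200, planted_persistent = 1,
                                       seed = 6))
  traj <- dynamic_influence_centrality(g$network, steps = 10)$trajectory
  prof <- persistence_profile(traj, k = 5)
  expect_equal(prof[1L], g$manifest$planted_persistent)
})

test_that("all three metrics are deterministic given network and parameters", {
  g <- generate_network(synthetic_spec(n = 100, planted_hubs = 2, seed = 9))
  net <- g$network
  expect_identical(propagation_centrality(net)$scores$scores,
                   propagation_centrality(net)$scores$scores)
  i1 <- initialise_vulnerability(net, seed = 5)
  expect_identical(
    misinformation_vulnerability_centrality(net, i1)$scores$scores,
    misinformation_vulnerability_centrality(net,
      initialise_vulnerability(net, seed = 5))$scores$scores)
  expect_identical(dynamic_influence_centrality(net)$scores$scores,
                   dynamic_influence_centrality(net)$scores$scores)
})
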