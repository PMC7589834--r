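# Residue interaction networks, betweenness/shortest-path profiles and
# delta profiles.

test_that("contact graphs follow the 6.7 A rule on constructed geometries", {
  line <- ca_traj(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)))
  g <- build_rin(line)
  expect_equal(igraph::ecount(g), 2)
  expect_true(igraph::are_adjacent(g, 1, 2))
  expect_true(igraph::are_adjacent(g, 2, 3))
  expect_false(igraph::are_adjacent(g, 1, 3))

  sparse <- ca_traj(rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0)))
  expect_equal(igraph::ecount(build_rin(sparse)), 0)

  # glycine helix: the C-alpha trace is the network node set, and the
  # helical geometry connects each residue to its 3 successors
  helix <- build_ideal_helix(12)
  keep <- helix$atoms$name != "CB"
  gly <- trajectory(transform(helix$atoms[keep, ], resname = "GLY"),
                    helix$xyz[, rep(keep, each = 3), drop = FALSE])
  gh <- build_rin(gly)
  for (i in 1:9) for (off in 1:3)
    expect_true(igraph::are_adjacent(gh, i, i + off))

  # larger cutoff never removes contacts
  d_small <- igraph::degree(build_rin(gly, cutoff = 5.0))
  d_large <- igraph::degree(build_rin(gly, cutoff = 6.7))
  expect_true(all(d_large >= d_small))
})

test_that("BC and L match closed forms on path, star and complete graphs", {
  line <- ca_traj(rbind(c(0, 0, 0), c(5, 0, 0), c(10, 0, 0)))
  expect_equal(as.numeric(betweenness_profile(line)), c(0, 1, 0))
  expect_equal(as.numeric(shortest_path_profile(line)), c(1.5, 1, 1.5))

  # 5-clique: all residues pairwise within cutoff
  tight <- ca_traj(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0),
                         c(0, 0, 3), c(2, 2, 2)))
  expect_equal(as.numeric(betweenness_profile(tight)), rep(0, 5))
  expect_equal(as.numeric(shortest_path_profile(tight)), rep(1, 5))

  # star: center within 5 A of each leaf, leaves mutually distant
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  star <- ca_traj(rbind(c(0, 0, 0), 5 * dirs / sqrt(3)))
  bc <- as.numeric(betweenness_profile(star))
  expect_equal(bc, c(1, 0, 0, 0, 0))
})

test_that("profiles equal exhaustive-enumeration oracles on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(3:8, 1)
    adj <- random_adjacency(n, p = runif(1, 0.2, 0.8))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(vardyn:::rin_betweenness(g)$value, enum_betweenness(adj),
                 tolerance = 1e-10)
    expect_equal(vardyn:::rin_avg_path(g)$value, enum_avg_path(adj),
                 tolerance = 1e-10)
  }
})

test_that("BC is invariant under relabeling (graph isomorphism)", {
  set.seed(32)
  adj <- random_adjacency(7, 0.5)
  perm <- sample(7)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  gp <- igraph::graph_from_adjacency_matrix(adj[perm, perm],
                                            mode = "undirected")
  expect_equal(vardyn:::rin_betweenness(g)$value[perm],
               vardyn:::rin_betweenness(gp)$value, tolerance = 1e-12)
})

test_that("disconnected components exclude unreachable pairs and flag them", {
  dimers <- ca_traj(rbind(c(0, 0, 0), c(4, 0, 0),
                          c(50, 0, 0), c(54, 0, 0)))
  L <- shortest_path_profile(dimers)
  expect_equal(as.numeric(L), rep(1, 4))
  expect_equal(sort(attr(L, "flagged")), 1:4)
})

test_that("delta profiles subtract shared residues and usage is
           antisymmetric", {
  helix <- build_ideal_helix(10)
  tr <- sample_harmonic_ensemble(helix, diag(0.3, 10), n_frames = 20,
                                 seed = 33)
  bc <- betweenness_profile(tr)
  zero <- delta_profile(bc, bc)
  expect_equal(as.numeric(zero), rep(0, 10))

  # same generator, disjoint seeds: deltas are sampling noise only
  trb <- sample_harmonic_ensemble(helix, diag(0.3, 10), n_frames = 20,
                                  seed = 34)
  d <- delta_profile(betweenness_profile(tr), betweenness_profile(trb),
                     "vs_other_system")
  expect_lt(max(abs(as.numeric(d))), 0.25)

  u1 <- residue_usage(bc, betweenness_profile(trb))
  u2 <- residue_usage(betweenness_profile(trb), bc)
  expect_equal(as.numeric(u1), -as.numeric(u2))

  b2 <- bc[as.character(3:8)]
  class(b2) <- "residue_profile"; attr(b2, "label") <- "BC"
  expect_length(delta_profile(bc, b2), 6)
  b3 <- bc; names(b3) <- as.character(101:110)
  expect_error(delta_profile(bc, b3), "no residues")
})

test_that("a planted contact loss redistributes BC around the lost edge", {
  # hexagonal ring, side 5 A: only ring edges fall under the cutoff
  theta <- seq(0, 2 * pi, length.out = 7)[1:6]
  ring <- ca_traj(cbind(5 * cos(theta) / (2 * sin(pi / 6)),
                        5 * sin(theta) / (2 * sin(pi / 6)), 0))
  # variant: the same chain opened into a line (edge 1-6 lost)
  open <- ca_traj(cbind(5 * (0:5), 0, 0))
  expect_equal(igraph::ecount(build_rin(ring)), 6)
  expect_equal(igraph::ecount(build_rin(open)), 5)
  d <- delta_profile(betweenness_profile(ring), betweenness_profile(open),
                     "vs_other_system")
  # the lost edge's endpoints lose centrality; interior residues gain it
  expect_gt(d["1"], 0); expect_gt(d["6"], 0)
  expect_lt(d["3"], 0); expect_lt(d["4"], 0)
})
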