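test_that("unfolding splits reversible reactions with a sign flip", {
  m <- metabolic_model(c("X1", "X2"), "R1", matrix(c(-1, 2), 2, 1),
                       TRUE, -10, 10)
  sys <- unfold(m)
  expect_equal(unname(sys$S2m[, 1]), c(-1, 2))   # fwd: consumes X1, makes 2 X2
  expect_equal(unname(sys$S2m[, 2]), c(1, -2))   # rev: mirror image
  expect_equal(unname(sys$Splus[, 2]), c(1, 0))
  expect_equal(unname(sys$Sminus[, 2]), c(0, 2))
  # invariants of the split
  expect_identical(sys$Splus - sys$Sminus, sys$S2m)
  expect_true(all(sys$Splus * sys$Sminus == 0))
  expect_equal(unname(sys$wplus), unname(rowSums(sys$Splus)))
})

test_that("irreversible models unfold to all-zero reverse columns", {
  m <- random_model(5, 7, fraction_reversible = 0, seed = 3)
  sys <- unfold(m)
  expect_true(all(sys$S2m[, 8:14] == 0))
  expect_identical(length(sys$active), 7L)
  expect_identical(nrow(build_nfg(m)$W), 7L)
})

test_that("RAG counts shared metabolites with participation self-loops", {
  m <- metabolic_model(c("X1", "X2", "X3", "X4"), c("R1", "R2"),
                       matrix(c(-1, 1, 1, 0,
                                 0, -1, -2, 1), 4, 2),
                       c(FALSE, FALSE), c(0, 0), c(10, 10))
  rag <- build_rag(m)
  expect_false(rag$directed)
  expect_identical(rag$W, t(rag$W))
  expect_equal(unname(diag(rag$W)), c(3, 3))  # metabolites per reaction
  expect_equal(rag$W["R1", "R2"], 2)          # shares X2 and X3
  expect_true(all(rag$W == round(rag$W)))
})

test_that("chain NFG is a single certain edge", {
  m <- chain_model()
  nfg <- build_nfg(m)
  expect_identical(nrow(nfg$W), 2L)
  expect_equal(nfg$W["R1", "R2"], 1)
  expect_equal(sum(nfg$W), 1)
})

test_that("NFG weights sum to the produced-and-consumed fraction", {
  # full normalisation when every metabolite is produced and consumed
  for (seed in 1:25) {
    m <- random_model(sample(3:10, 1), sample(4:12, 1),
                      density = stats::runif(1, 0.2, 0.5),
                      fraction_reversible = stats::runif(1),
                      seed = seed, ensure_flow = TRUE)
    expect_equal(sum(build_nfg(m)$W), 1, tolerance = 1e-12)
  }
  # a metabolite never consumed contributes 0 through the pseudoinverse
  m <- metabolic_model(c("X1", "X2"), c("R1", "R2"),
                       matrix(c(1, 0, -1, 1), 2, 2),
                       c(FALSE, FALSE), c(0, 0), c(10, 10))
  expect_equal(sum(build_nfg(m)$W), 1 / 2)  # only X1 is both
})

test_that("matrix-form NFG equals the brute-force triple loop", {
  for (seed in 1:10) {
    n <- sample(3:12, 1); mm <- sample(3:12, 1)
    m <- random_model(n, mm, density = 0.4,
                      fraction_reversible = stats::runif(1), seed = seed,
                      ensure_flow = (seed %% 2 == 0))
    D_oracle <- nfg_bruteforce(m)
    sys <- unfold(m)
    D_pkg <- matrix(0, 2 * mm, 2 * mm)
    D_pkg[sys$active, sys$active] <- build_nfg(m, threshold = 0)$W
    expect_lt(max(abs(D_pkg - D_oracle)), 1e-12)
  }
})

test_that("pairwise flow follows the proportional-allocation rule", {
  # producers 1.5 + 8.5, consumers 3.0 + 7.0 of a single metabolite
  m <- metabolic_model("X", c("P1", "P2", "C1", "C2"),
                       matrix(c(1, 1, -1, -1), 1, 4),
                       rep(FALSE, 4), rep(0, 4), rep(20, 4))
  v <- c(1.5, 8.5, 3, 7)
  sys <- unfold(m)
  v2m <- unfold_fluxes(v, m)$v2m
  expect_identical(pairwise_flow(1, 1, 3, sys, v2m), 0.45)
  # sole producer to sole consumer carries the full flux
  mc <- chain_model()
  sysc <- unfold(mc)
  expect_equal(pairwise_flow(1, 1, 2, sysc, c(7, 7, 0, 0)), 7)
  # consumer with zero flux receives nothing
  expect_equal(pairwise_flow(1, 1, 4, sys, unfold_fluxes(c(10, 0, 10, 0), m)$v2m), 0)
})

test_that("chain MFG carries the flux as a single edge", {
  m <- chain_model()
  mfg <- build_mfg(m, c(2, 2))
  expect_identical(nrow(mfg$W), 2L)
  expect_equal(mfg$W["R1", "R2"], 2)
  expect_identical(mfg$weight_semantics, "flux_mmol_gDW_h")
})

test_that("MFG rejects unbalanced fluxes naming the worst metabolite", {
  expect_error(build_mfg(chain_model(), c(10, 3)), "X1")
})

test_that("zero-flux reactions are pruned from the MFG node set", {
  m <- toy_network()
  sol <- solve_fba(m)
  mfg <- build_mfg(m, sol)
  zero <- names(sol$v)[abs(sol$v) < 1e-9]
  expect_true(length(zero) > 0)
  expect_false(any(zero %in% mfg$nodes$node_id))
})

test_that("matrix-form MFG equals the brute-force triple loop", {
  for (seed in 1:10) {
    n <- sample(3:8, 1)
    m <- random_model(n, n + sample(2:4, 1), density = 0.4,
                      fraction_reversible = 1, seed = seed)
    v <- random_balanced_flux(m, seed = seed + 100)
    M_oracle <- mfg_bruteforce(m, v)
    sys <- unfold(m)
    mm2 <- ncol(sys$S2m)
    g <- build_mfg(m, v, zero_tol = 0, threshold = 0)
    M_pkg <- matrix(0, mm2, mm2)
    idx <- match(g$nodes$node_id, colnames(sys$S2m))
    M_pkg[idx, idx] <- g$W
    expect_lt(max(abs(M_pkg - M_oracle)), 1e-12)
  }
})

test_that("MFG conserves metabolite mass flows", {
  for (seed in 1:5) {
    m <- random_model(5, 9, density = 0.4, fraction_reversible = 1,
                      seed = seed)
    v <- random_balanced_flux(m, seed = seed)
    sys <- unfold(m)
    uf <- unfold_fluxes(v, m)
    g <- build_mfg(m, v, zero_tol = 0, threshold = 0)
    consumed <- as.vector(sys$Sminus %*% uf$v2m) > 1e-12
    # total edge mass = total metabolite flux over consumed metabolites
    expect_equal(sum(g$W), sum(uf$j[consumed]), tolerance = 1e-9)
    # row sums equal each node's production into consumed metabolites
    idx <- match(g$nodes$node_id, colnames(sys$S2m))
    expected_rows <- colSums(sys$Splus[consumed, idx, drop = FALSE] *
                               rep(uf$v2m[idx], each = sum(consumed)))
    expect_equal(unname(rowSums(g$W)), unname(expected_rows), tolerance = 1e-9)
  }
})

test_that("competition and synergy graphs are symmetric probabilities", {
  # two consumers sharing the single molecule of X1: off-diagonal 1/4
  m <- metabolic_model("X1", c("P", "C1", "C2"),
                       matrix(c(2, -1, -1), 1, 3),
                       rep(FALSE, 3), rep(0, 3), rep(10, 3))
  dc <- build_competition_graph(m)
  expect_equal(dc$W["C1", "C2"], 1 / 4)
  expect_identical(dc$W, t(dc$W))
  ds <- build_synergy_graph(m)
  expect_equal(ds$W["P", "P"], 1)  # sole producer
  # no shared substrates: competition off-diagonal all zero
  m2 <- metabolic_model(c("X1", "X2"), c("R1", "R2"),
                        matrix(c(-1, 1, 1, -1), 2, 2),
                        c(FALSE, FALSE), c(0, 0), c(10, 10))
  W <- build_competition_graph(m2)$W
  expect_true(all(W[upper.tri(W)] == 0))
})

test_that("graph averaging unions node sets and means weights", {
  m <- toy_network()
  g <- build_mfg(m, solve_fba(m))
  avg <- average_graphs(list(g, g, g))
  expect_equal(avg$W, g$W)

  # an edge present in one of two graphs halves its weight
  g2 <- build_mfg(m, solve_fba(m, scenario("alt", list(R7 = c(1, 1000)))))
  avg2 <- average_graphs(list(g, g2))
  only_g <- setdiff(g$nodes$node_id, g2$nodes$node_id)
  extra <- setdiff(g2$nodes$node_id, g$nodes$node_id)
  expect_true(all(c(g$nodes$node_id, g2$nodes$node_id) %in% avg2$nodes$node_id))
  if (length(extra) > 0) {
    e1 <- extra[1]
    expect_equal(avg2$W[e1, ], g2$W[e1, avg2$nodes$node_id] / 2,
                 ignore_attr = TRUE)
  }
  expect_error(average_graphs(list(g, build_nfg(m))), "semantics")
})

test_that("graph writers round trip through text formats", {
  m <- toy_network()
  g <- build_nfg(m)
  tsv <- file.path(withr::local_tempdir(), "g.tsv")
  write_edge_tsv(g, tsv)
  df <- utils::read.delim(tsv)
  expect_identical(nrow(df), n_edges(g))
  W2 <- matrix(0, nrow(g$W), ncol(g$W), dimnames = dimnames(g$W))
  W2[cbind(df$from, df$to)] <- df$weight
  expect_identical(W2, g$W)  # 17 significant digits: bit-exact

  gml <- file.path(withr::local_tempdir(), "g.graphml")
  write_graphml(g, gml)
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(ig), nrow(g$W))
  expect_equal(igraph::gsize(ig), n_edges(g))
  expect_setequal(igraph::vertex_attr(ig, "subsystem"),
                  unique(g$nodes$subsystem))
})
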