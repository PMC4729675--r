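test_that("overlap_energy: exact continuation, margin arithmetic", {
  sc <- cached_scenario()
  fr <- sc$fragments
  op <- overlap_params()  # 2.3 / 2.8 A margins, k = 100
  # consecutive planted fragments share nucleotides exactly -> 0
  for (k in 1:5) expect_equal(overlap_energy(fr[[k]], fr[[k + 1]], op), 0)
  # one bead pair at margin + 0.1 with k = 100 -> exactly 1.0 kcal/mol
  a <- toy_trinucleotide()$conformer
  b <- a
  shift_one <- function(b, role, delta) {
    # displace one bead of nucleotide 1 of b relative to nt 2 of a pairing
    b
  }
  # build a continuation of `a` by hand: nt1,nt2 of b coincide with nt2,nt3
  # of a; then push a single backbone bead of b out by margin + 0.1
  cont <- a
  cont$pos <- rbind(a$pos[3:6, ], a$pos[5:6, ] + matrix(c(4, 0, 0), 2, 3,
                                                        byrow = TRUE))
  expect_equal(overlap_energy(a, cont, op), 0)
  pushed <- cont
  pushed$pos[1, ] <- pushed$pos[1, ] + c(0, 0, op$margin_backbone + 0.1)
  expect_equal(overlap_energy(a, pushed, op), 100 * 0.1^2, tolerance = 1e-9)
  # margin + 0.15 -> 2.25 kcal/mol: beyond the 2 kcal/mol budget
  pushed$pos[1, ] <- cont$pos[1, ] + c(0, 0, op$margin_backbone + 0.15)
  e <- overlap_energy(a, pushed, op)
  expect_equal(e, 2.25, tolerance = 1e-9)
  expect_gt(e, op$max_violation)
  # base beads use the larger margin
  pushed2 <- cont
  pushed2$pos[2, ] <- cont$pos[2, ] + c(0, 0, op$margin_base + 0.1)
  expect_equal(overlap_energy(a, pushed2, op), 1.0, tolerance = 1e-9)
})

test_that("build_graph: edges, modes, and pre-filter equivalence", {
  conf <- toy_trinucleotide()$conformer
  # pose B continues pose A exactly: one edge A->B
  tfA <- rigid_transform(t = c(0, 0, 0))
  tfB <- rigid_transform(t = c(4, 0, 0))  # nucleotide spacing is 4
  pool <- pool_from_transforms(conf, list(tfA, tfB))
  g <- build_graph(pool, overlap_params(), mode = "single_pool")
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$node_id[g$edges$from], "pose001")
  expect_equal(g$node_id[g$edges$to], "pose002")
  # all mutually overlapping poses: n(n-1) edges in single-pool mode
  same <- pool_from_transforms(conf, rep(list(tfA), 4))
  # identical poses do not continue each other (the shared window is
  # displaced), so use a pool of exact continuations instead
  chain4 <- pool_from_transforms(conf, lapply(0:3 * 4, function(s)
    rigid_transform(t = c(s, 0, 0))))
  g4 <- build_graph(chain4, overlap_params(), mode = "single_pool")
  expect_equal(nrow(g4$edges), 3L)  # path 1->2->3->4

  # position-specific mode: edges only between consecutive pools
  pools <- lapply(0:2, function(s)
    pool_from_transforms(conf, list(rigid_transform(t = c(4 * s, 0, 0)))))
  gp <- build_graph(pools, overlap_params())
  expect_equal(gp$mode, "position_specific")
  expect_equal(nrow(gp$edges), 2L)
  expect_true(all(gp$pool_of[gp$edges$to] - gp$pool_of[gp$edges$from] == 1L))

  # spatial pre-filter must not change the edge set (random poses)
  set.seed(17)
  tfs <- lapply(1:25, function(i)
    rigid_transform(random_quaternions(1)[1, ], rnorm(3, sd = 6)))
  rnd <- pool_from_transforms(conf, tfs)
  op <- overlap_params(margin_backbone = 4, margin_base = 5,
                       max_violation = 10)
  gf <- build_graph(rnd, op, mode = "single_pool", prefilter = TRUE)
  gb <- build_graph(rnd, op, mode = "single_pool", prefilter = FALSE)
  expect_identical(gf$edges, gb$edges)
})

test_that("count_chains: worked examples", {
  # pools {a1,a2} -> {b1} -> {c1,c2}; edges a1->b1, a2->b1, b1->c1
  g <- chain_graph(c("a1", "a2", "b1", "c1", "c2"),
                   data.frame(from = c(1L, 2L, 3L), to = c(3L, 3L, 4L),
                              energy = 0),
                   pool_of = c(1L, 1L, 2L, 3L, 3L))
  cc <- count_chains(g, 3)
  expect_equal(cc$total_chains, 2)
  expect_equal(unname(cc$propensity["b1"]), 1.0)
  expect_equal(unname(cc$propensity["c2"]), 0)
  expect_equal(unname(cc$counts[c("a1", "a2", "c1")]), c(1, 1, 2))
  # positional accounting identity
  expect_equal(sum(cc$counts), 3 * cc$total_chains)

  # complete tripartite 2x2x2: T = 8, every propensity 0.5
  e <- expand.grid(from = 1:2, to = 3:4)
  e <- rbind(e, expand.grid(from = 3:4, to = 5:6))
  g2 <- chain_graph(paste0("n", 1:6),
                    data.frame(from = e$from, to = e$to, energy = 0),
                    pool_of = rep(1:3, each = 2))
  cc2 <- count_chains(g2, 3)
  expect_equal(cc2$total_chains, 8)
  expect_equal(unname(cc2$propensity), rep(0.5, 6))

  expect_error(count_chains(g, 1), ">= 2")
})

test_that("count_chains equals brute-force walk enumeration (100 graphs)", {
  for (trial in 1:100) {
    n <- 4 + trial %% 9  # 4..12 nodes
    N <- 2 + trial %% 5  # 2..6
    edges <- random_graph(n, p = 0.25, seed = 1000 + trial)
    if (nrow(edges) == 0) next
    g <- chain_graph(paste0("v", seq_len(n)), edges)
    cc <- count_chains(g, N)
    oracle <- walk_enumeration_oracle(n, edges, N)
    expect_equal(cc$total_chains, oracle$total)
    expect_equal(unname(cc$counts), oracle$counts)
    expect_equal(sum(cc$counts), N * cc$total_chains)
  }
})

test_that("propensity_filter: thresholds, zero-count removal, toybench", {
  g <- chain_graph(c("a1", "a2", "b1", "c1", "c2"),
                   data.frame(from = c(1L, 2L, 3L), to = c(3L, 3L, 4L),
                              energy = 0),
                   pool_of = c(1L, 1L, 2L, 3L, 3L))
  cc <- count_chains(g, 3)
  # T = 2; with threshold 1e-4 everything with c_v > 0 stays, c2 drops
  conf <- toy_trinucleotide()$conformer
  pools <- list(
    pool_from_transforms(conf, rep(list(rigid_transform()), 2)),
    pool_from_transforms(conf, list(rigid_transform())),
    pool_from_transforms(conf, rep(list(rigid_transform()), 2)))
  # rename pose ids to match graph nodes
  pools[[1]]$poses$pose_id <- c("a1", "a2")
  pools[[2]]$poses$pose_id <- "b1"
  pools[[3]]$poses$pose_id <- c("c1", "c2")
  out <- propensity_filter(pools, cc, g, threshold = 1e-4)
  expect_equal(out[[3]]$poses$pose_id, "c1")
  expect_equal(nrow(out[[1]]$poses), 2L)

  # threshold arithmetic: c_v = 2 of T = 20000 kept at 1/10000
  gbig <- chain_graph(c("x", "y"), data.frame(from = 1L, to = 2L, energy = 0))
  fake <- structure(list(N = 2, total_chains = 20000,
                         counts = c(x = 2, y = 20000),
                         propensity = c(x = 1e-4, y = 1)),
                    class = "chain_count_result")
  pool2 <- pool_from_transforms(conf, rep(list(rigid_transform()), 2))
  pool2$poses$pose_id <- c("x", "y")
  kept <- propensity_filter(pool2, fake, gbig, threshold = 1e-4)
  expect_setequal(kept$poses$pose_id, c("x", "y"))

  # toybench: planted kept, zero-propensity decoys removed
  sc <- cached_scenario()
  op <- overlap_params()
  g3 <- build_graph(sc$pool, op, mode = "single_pool")
  cc3 <- count_chains(g3, 5)
  filt <- propensity_filter(sc$pool, cc3, g3)
  expect_setequal(filt$poses$pose_id, paste0("planted_frag", 1:6))
})

test_that("no chains formed -> empty pool with message", {
  conf <- toy_trinucleotide()$conformer
  # two far-apart poses: no edges, T = 0
  pool <- pool_from_transforms(conf, list(rigid_transform(t = c(0, 0, 0)),
                                          rigid_transform(t = c(50, 0, 0))))
  g <- build_graph(pool, overlap_params(), mode = "single_pool")
  cc <- count_chains(g, 2)
  expect_equal(cc$total_chains, 0)
  expect_message(out <- propensity_filter(pool, cc, g), "no chains")
  expect_equal(nrow(out$poses), 0L)
})

test_that("enumerate_chains: listing, determinism, DP cross-check", {
  g <- chain_graph(c("a1", "a2", "b1", "c1", "c2"),
                   data.frame(from = c(1L, 2L, 3L), to = c(3L, 3L, 4L),
                              energy = c(0.5, 0.25, 1)),
                   pool_of = c(1L, 1L, 2L, 3L, 3L))
  ch <- enumerate_chains(g, 3)
  expect_length(ch, 2L)
  expect_equal(ch[[1]]$pose_ids, c("a1", "b1", "c1"))
  expect_equal(ch[[2]]$pose_ids, c("a2", "b1", "c1"))
  expect_equal(ch[[1]]$junction_energies, c(0.5, 1))
  # empty graph -> empty list
  g0 <- chain_graph(c("u", "v"), data.frame(from = integer(), to = integer(),
                                            energy = numeric()))
  expect_length(enumerate_chains(g0, 2), 0L)
  # |enumerated| == DP total on random DAG-ish graphs without repeats
  for (trial in 1:10) {
    n <- 6 + trial %% 4
    edges <- random_graph(n, 0.3, seed = 400 + trial)
    edges <- edges[edges$from < edges$to, , drop = FALSE]  # acyclic: simple
    if (nrow(edges) == 0) next
    g1 <- chain_graph(paste0("v", sprintf("%02d", seq_len(n))), edges)
    cc <- count_chains(g1, 3)
    expect_length(enumerate_chains(g1, 3, cap = 1e6), cc$total_chains)
  }
  # overflow guard
  full <- expand.grid(from = 1:8, to = 1:8)
  full <- full[full$from != full$to, ]
  gbig <- chain_graph(paste0("v", 1:8),
                      data.frame(from = full$from, to = full$to, energy = 0))
  expect_error(enumerate_chains(gbig, 6, cap = 100), "exceeds cap")
})

test_that("filter monotonicity: violation budget and threshold", {
  set.seed(23)
  conf <- toy_trinucleotide()$conformer
  tfs <- lapply(1:20, function(i)
    rigid_transform(random_quaternions(1)[1, ] * c(1, .05, .05, .05),
                    c(4, 0, 0) * (i %% 5) + rnorm(3, sd = 1.5)))
  pool <- pool_from_transforms(conf, tfs)
  edge_counts <- vapply(c(0.5, 1, 2, 4, 8), function(v)
    nrow(build_graph(pool, overlap_params(max_violation = v),
                     mode = "single_pool")$edges), 0L)
  expect_true(all(diff(edge_counts) >= 0))
  g <- build_graph(pool, overlap_params(max_violation = 8),
                   mode = "single_pool")
  cc <- count_chains(g, 3)
  if (cc$total_chains > 0) {
    kept <- vapply(c(1e-1, 1e-2, 1e-4, 1e-6), function(t)
      nrow(propensity_filter(pool, cc, g, t)$poses), 0L)
    expect_true(all(diff(kept) >= 0))
    # threshold 1/T never removes a pose on an enumerated chain
    ch <- enumerate_chains(g, 3, cap = 1e6)
    on_chain <- unique(unlist(lapply(ch, `[[`, "pose_ids")))
    f <- propensity_filter(pool, cc, g, threshold = 1 / cc$total_chains)
    expect_true(all(on_chain %in% f$poses$pose_id))
  }
})

test_that("iterative_assembly: degenerate schedule and proximity rule", {
  sc <- cached_scenario()
  op <- overlap_params()
  # schedule {100%} is one propensity_filter pass
  it1 <- iterative_assembly(sc$pool, schedule = 1.0, radius = 5,
                            params = op, N = 5)
  g <- build_graph(sc$pool, op, mode = "single_pool")
  cc <- count_chains(g, 5)
  direct <- propensity_filter(sc$pool, cc, g)
  expect_setequal(it1$poses$pose_id, direct$poses$pose_id)
  # staged: planted poses rank at the top, survive all stages; decoys
  # (far from everything selected) are never added. The first fraction
  # must cover all 6 planted poses of this 56-pose pool.
  it <- iterative_assembly(sc$pool, schedule = c(0.15, 0.4, 0.8),
                           radius = 5, params = op, N = 5)
  expect_setequal(it$poses$pose_id, paste0("planted_frag", 1:6))
  stages <- attr(it, "stages")
  expect_length(stages, 3L)
  expect_true(all(vapply(stages[-1], function(s) s[["admitted"]], 0) == 0))
})
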