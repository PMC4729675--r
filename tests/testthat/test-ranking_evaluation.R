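test_that("ligand_rmsd: exact values, rigid-motion invariance, oracle", {
  s <- random_cg(7, seed = 3)
  expect_equal(ligand_rmsd(s, s), 0)
  shifted <- s
  shifted$pos <- s$pos + matrix(rep(c(3, 0, 0), each = 7), 7, 3)
  expect_equal(ligand_rmsd(shifted, s), 3.0, tolerance = 1e-12)
  # random rigid motion: equals the direct per-bead formula to 1e-9
  tr <- random_rigid_transform(13)
  moved <- apply_transform(s, tr)
  direct <- sqrt(mean(rowSums((moved$pos - s$pos)^2)))
  expect_equal(ligand_rmsd(moved, s), direct, tolerance = 1e-9)
  # invariant under a joint rigid motion of pose and reference
  joint <- random_rigid_transform(14)
  expect_equal(ligand_rmsd(apply_transform(moved, joint),
                           apply_transform(s, joint)),
               ligand_rmsd(moved, s), tolerance = 1e-9)
  expect_error(ligand_rmsd(s, random_cg(6)), "mismatch")
})

test_that("classify_hits: strict thresholds and planted counts", {
  sc <- cached_scenario()
  conf <- sc$conformers[[1]]
  ref <- sc$fragments[[1]]
  # plant poses at known RMSDs 0.5, 3, 10 from the reference
  base <- sc$planted_transforms[[1]]
  tfs <- lapply(c(0.5, 3, 10), function(d)
    rigid_transform(base$q, base$t + c(0, 0, d)))
  pool <- pool_from_transforms(conf, tfs)
  cls <- classify_hits(pool, list(ref))
  expect_equal(cls$hits, 1L)       # only 0.5 < 2
  expect_equal(cls$near_hits, 2L)  # 0.5 and 3 < 5
  expect_equal(cls$close_hits, 2L) # 10 is not < 6
  expect_equal(cls$min_rmsd, 0.5, tolerance = 1e-9)
  # strictness at the boundary: a pose at exactly 5.0 A is not a near-hit
  at5 <- pool_from_transforms(conf, list(
    rigid_transform(base$q, base$t + c(0, 0, 5))))
  cls5 <- classify_hits(at5, list(ref))
  expect_equal(cls5$near_hits, 0L)
  expect_equal(cls5$close_hits, 1L)
  at19 <- pool_from_transforms(conf, list(
    rigid_transform(base$q, base$t + c(0, 0, 1.9))))
  expect_equal(classify_hits(at19, list(ref))$hits, 1L)
})

test_that("chain_rmsd: geometric-mean identities", {
  expect_equal(chain_rmsd(c(1, 1, 1, 1, 1)), 1.0)
  expect_equal(chain_rmsd(c(0.5, 2.0)), 1.0)
  expect_equal(chain_rmsd(c(1, 2, 4, 8, 16)), 4.0)
  expect_equal(chain_rmsd(c(0, 3, 5)), 0)
  r <- runif(1, 0.1, 9)
  expect_equal(chain_rmsd(rep(r, 6)), r, tolerance = 1e-12)
})

test_that("score_poses: Eq-1 style log-over-rank", {
  conf <- toy_trinucleotide()$conformer
  pool <- pool_from_transforms(conf, lapply(1:3, function(i)
    rigid_transform(t = c(10 * i, 0, 0))))
  counts <- structure(list(N = 5, total_chains = 100,
                           counts = c(pose001 = 100, pose002 = 100 * exp(-2),
                                      pose003 = 0),
                           propensity = c(pose001 = 1,
                                          pose002 = exp(-2), pose003 = 0)),
                      class = "chain_count_result")
  sp <- score_poses(pool, counts)
  # propensity 1, rank 1 -> 0; propensity e^-2, rank 2 -> -1
  expect_equal(sp$s_poses[sp$pose_id == "pose001"], 0)
  expect_equal(sp$s_poses[sp$pose_id == "pose002"], -1)
  # zero-propensity poses are excluded
  expect_false("pose003" %in% sp$pose_id)
  # at fixed rank, the score increases with propensity
  expect_gt(log(0.5) / 2, log(0.1) / 2)
})

test_that("score_chains: both readings, linearity in overlap", {
  conf <- toy_trinucleotide()$conformer
  pool <- pool_from_transforms(conf, lapply(1:10, function(i)
    rigid_transform(t = c(10 * i, 0, 0))))
  mk <- function(ids, junc) list(pose_ids = ids, junction_energies = junc)
  perfect <- mk(pool$poses$pose_id[6:10], rep(0, 4))
  good_ranks <- mk(pool$poses$pose_id[1:5], rep(0.5, 4))
  bad_ranks <- mk(pool$poses$pose_id[6:10], rep(0.5, 4))
  scd <- score_chains(list(perfect, good_ranks, bad_ranks), pool)
  # all-zero overlaps score 0: the best possible regardless of ranks
  expect_equal(scd$s_chains[scd$chain_id == 1], 0)
  expect_true(all(scd$s_chains >= 0))
  # equal overlaps: better member ranks win under the product reading
  expect_lt(scd$s_chains[scd$chain_id == 2], scd$s_chains[scd$chain_id == 3])
  # doubling every junction overlap doubles the score
  doubled <- mk(pool$poses$pose_id[1:5], rep(1.0, 4))
  s2 <- score_chains(list(good_ranks, doubled), pool)
  expect_equal(s2$s_chains[s2$chain_id == 2],
               2 * s2$s_chains[s2$chain_id == 1])
  # ratio reading also linear in overlap, recorded in the attribute
  sr <- score_chains(list(good_ranks, doubled), pool, mode = "ratio")
  expect_equal(attr(sr, "mode"), "ratio")
  expect_equal(sr$s_chains[sr$chain_id == 2], 2 * sr$s_chains[sr$chain_id == 1])
})

test_that("binding_site_stats: fractions under cutoffs", {
  sc <- cached_scenario()
  conf <- sc$conformers[[1]]
  base <- sc$planted_transforms[[1]]
  # synthetic distances 5, 12, 20 from the nearest reference
  far_ref <- sc$fragments[[1]]
  pool <- pool_from_transforms(conf, lapply(c(5, 12, 20), function(d)
    rigid_transform(base$q, base$t + c(0, 0, -d))))
  st <- binding_site_stats(pool, list(far_ref), cutoffs = c(10, 15))
  expect_equal(unname(st$fractions), c(1 / 3, 2 / 3), tolerance = 1e-9)
  expect_equal(st$max, 20, tolerance = 1e-9)
  # all poses on the reference chain: fractions 1, max below hit threshold
  on_site <- pool_from_transforms(conf, rep(list(base), 3))
  st2 <- binding_site_stats(on_site, list(far_ref))
  expect_equal(unname(st2$fractions), c(1, 1))
  expect_lt(st2$max, 2)
})

test_that("fit_vs_dock_correlation: exact cases and textbook oracle", {
  # collinear pairs -> r = 1
  col <- cbind(1:5, 2 * (1:5) + 3)
  expect_equal(fit_vs_dock_correlation(col)$r, 1.0)
  # random pairs vs the two-pass textbook formula
  set.seed(8)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  res <- fit_vs_dock_correlation(cbind(x, y))
  num <- sum((x - mean(x)) * (y - mean(y)))
  den <- sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, num / den, tolerance = 1e-12)
  expect_error(fit_vs_dock_correlation(cbind(rep(1, 5), 1:5)), "variance")
  expect_error(fit_vs_dock_correlation(cbind(1:2, 2:3)), "3 pairs")
})

test_that("enrichment: exact hypergeometric tails", {
  expect_equal(enrichment(3, 10, 0, 4), 1.0)
  expect_equal(enrichment(5, 10, 2, 10), 1.0)  # all poses are hits
  # N=10, K=5, n=5, x=5 -> C(5,5)C(5,0)/C(10,5) = 1/252
  expect_equal(enrichment(5, 10, 5, 5), 1 / 252, tolerance = 1e-12)
  # monotone decreasing in hits_in_top
  vals <- vapply(0:5, function(x) enrichment(5, 20, x, 8), 0)
  expect_true(all(diff(vals) < 0))
  expect_error(enrichment(5, 10, 6, 5), "inconsistent")
})
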