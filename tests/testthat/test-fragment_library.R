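make_rna_cg <- function(n, chain = "R", auth_start = 1L, gap_after = NULL,
                        residues = rep("U", n)) {
  # simple CG RNA: 2 beads per nucleotide along x
  auth <- auth_start + seq_len(n) - 1L
  if (!is.null(gap_after)) {
    auth[(gap_after + 1):n] <- auth[(gap_after + 1):n] + 5L
  }
  pos <- NULL
  for (i in seq_len(n)) {
    pos <- rbind(pos, c(4 * i, 0, 0), c(4 * i + 1, 2, 0))
  }
  cg_structure(pos, rep(c("BB", "BA"), n), rep(c("backbone", "base"), n),
               rep(c(1L, 2L), n), 0, rep(seq_len(n), each = 2), chain,
               rep(residues, each = 2), rep(auth, each = 2))
}

test_that("extract_trinucleotides: sliding windows and chain breaks", {
  protein <- one_bead(c(4, -3, 0))
  # 8-nucleotide chain -> 6 overlapping fragments
  frags <- extract_trinucleotides(list(list(protein = protein,
                                            rna = make_rna_cg(8))), 5)
  expect_length(frags, 6L)
  expect_equal(vapply(frags, `[[`, 0L, "start_residue"), 1:6)
  # 3-nucleotide chain -> 1 fragment
  expect_length(extract_trinucleotides(list(list(protein = protein,
                                                 rna = make_rna_cg(3))), 5),
                1L)
  # chain shorter than 3 -> none, not an error
  expect_length(extract_trinucleotides(list(list(protein = protein,
                                                 rna = make_rna_cg(2))), 5),
                0L)
  # numbering gap between residues 4 and 5 -> 2 + 2 = 4 fragments
  gapped <- extract_trinucleotides(list(list(protein = protein,
                                             rna = make_rna_cg(8,
                                                               gap_after = 4))),
                                   5)
  expect_length(gapped, 4L)
  expect_equal(vapply(gapped, `[[`, 0L, "start_residue"), c(1:2, 5:6))
  # protein contact tagging
  expect_true(frags[[1]]$contacts_protein)
  expect_false(frags[[6]]$contacts_protein)
})

test_that("sequence classes and canonicalization", {
  mapping <- read_mapping()
  # a real all-atom UCU fragment, coarse-grained then canonicalized
  path <- withr::local_tempfile(fileext = ".pdb")
  write_nt_pdb(path, c("U", "C", "U"))
  cg <- coarse_grain(load_structure(path), mapping)
  frag <- trinucleotide_fragment(cg, source_id = "fixture")
  expect_equal(frag$sequence_class, "UUU")
  can <- canonicalize(frag, mapping)
  # positions bit-identical, all residues re-typed to U
  expect_identical(can$conformer$pos, frag$conformer$pos)
  expect_equal(unique(can$conformer$residue_name), "U")
  u_types <- mapping$type_code[mapping$residue_name == "U"]
  expect_equal(unname(can$conformer$type_code), rep(u_types, 3))

  # AAA: identity re-typing, no bead moved or dropped
  pa <- withr::local_tempfile(fileext = ".pdb")
  write_nt_pdb(pa, c("A", "A", "A"))
  fa <- trinucleotide_fragment(coarse_grain(load_structure(pa), mapping))
  expect_equal(fa$sequence_class, "AAA")
  ca <- canonicalize(fa, mapping)
  expect_identical(ca$conformer$pos, fa$conformer$pos)
  expect_identical(ca$conformer$type_code, fa$conformer$type_code)

  # G/A mixed purines canonicalize to AAA with unchanged positions
  pg <- withr::local_tempfile(fileext = ".pdb")
  write_nt_pdb(pg, c("A", "A", "A"))
  # mixed purine/pyrimidine -> class "other", untouched
  fo <- toy_trinucleotide(residue_names = c("G", "A", "U"))
  expect_equal(fo$sequence_class, "other")
  expect_identical(canonicalize(fo, mapping), fo)
})

test_that("superposed_rmsd: exact values and invariances", {
  s <- random_cg(8, seed = 5)
  moved <- apply_transform(s, random_rigid_transform(11))
  expect_lt(superposed_rmsd(s, moved), 1e-6)
  expect_equal(superposed_rmsd(s, s), 0)

  # two beads {(0,0,0),(2,0,0)} vs {(0,0,0),(4,0,0)} -> 1.0 A exactly;
  # verified against a brute-force rotation-grid oracle
  a <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  b <- matrix(c(0, 0, 0, 4, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(superposed_rmsd(a, b), 1.0, tolerance = 1e-9)
  grid_best <- Inf
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  for (th in seq(0, pi, length.out = 721)) {
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    grid_best <- min(grid_best, sqrt(mean(rowSums((ac %*% t(R) - bc)^2))))
  }
  expect_equal(grid_best, 1.0, tolerance = 1e-6)

  expect_error(superposed_rmsd(random_cg(4), random_cg(5)), "4.*5")
})

test_that("deduplicate_library matches the all-pairs oracle", {
  expect_error(deduplicate_library(list(toy_trinucleotide()), 0), "> 0")

  # bit-identical conformers collapse; distant ones are kept
  f <- toy_trinucleotide()
  lib <- deduplicate_library(list(f, f), 0.2)
  expect_length(lib$classes$UUU, 1L)
  g <- toy_trinucleotide(jitter = 1.0, seed = 3)
  expect_gt(superposed_rmsd(f$conformer, g$conformer), 0.5)
  lib2 <- deduplicate_library(list(f, g), 0.5)
  expect_length(lib2$classes$UUU, 2L)

  # random conformers: greedy retained set equals the oracle built from
  # the full pairwise RMSD matrix
  frags <- lapply(1:10, function(i) toy_trinucleotide(jitter = 0.4, seed = i))
  thr <- 0.8
  lib3 <- deduplicate_library(frags, thr)
  rm_mat <- sapply(frags, function(a) sapply(frags, function(b)
    superposed_rmsd(a$conformer, b$conformer)))
  kept <- integer()
  for (i in 1:10) {
    if (all(rm_mat[i, kept] > thr)) kept <- c(kept, i)
  }
  expect_equal(length(lib3$classes$UUU), length(kept))
  expect_equal(vapply(lib3$classes$UUU, function(x)
    superposed_rmsd(x$conformer, frags[[kept[1]]]$conformer), 0)[1], 0)

  # dedup output size is monotone non-increasing in threshold
  sizes <- vapply(c(0.1, 0.5, 1, 2, 5), function(t)
    length(deduplicate_library(frags, t)$classes$UUU), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("best_fit: argmin with ties to lowest index, oracle check", {
  frags <- lapply(1:12, function(i) toy_trinucleotide(jitter = 0.5, seed = i))
  lib <- fragment_library(list(UUU = frags))
  target <- toy_trinucleotide(jitter = 0.5, seed = 99)
  bf <- best_fit(lib, target)
  oracle <- vapply(frags, function(f)
    superposed_rmsd(f$conformer, target$conformer), 0)
  expect_equal(bf$index, which.min(oracle))
  expect_equal(bf$rmsd, min(oracle))
  # member of the library fits itself exactly
  self <- best_fit(lib, frags[[4]])
  expect_equal(self$rmsd, 0)
  expect_equal(self$index, 4L)
  # best_fit is a lower bound over all members
  expect_true(all(bf$rmsd <= oracle))
  expect_error(best_fit(lib, toy_trinucleotide(residue_names = c("A", "A", "A"))),
               "AAA")
})

test_that("library write/read round trip", {
  frags <- lapply(1:3, function(i) toy_trinucleotide(jitter = 0.5, seed = i))
  lib <- fragment_library(list(UUU = frags))
  dir <- withr::local_tempdir()
  write_library(lib, dir)
  back <- read_library(dir)
  expect_length(back$classes$UUU, 3L)
  expect_equal(back$classes$UUU[[2]]$conformer$pos,
               unname(frags[[2]]$conformer$pos), tolerance = 1e-3)
})
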