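# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

# --- tiny PDB text fixtures -------------------------------------------------

pdb_line <- function(serial, name, resname, chain, resseq, x, y, z,
                     record = "ATOM", altloc = " ", element = "") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, name, altloc, resname, chain, resseq, x, y, z,
          element)
}

# full heavy-atom uridine (PDB v3 names) at arbitrary but fixed coordinates
uridine_atoms <- function() {
  data.frame(
    name = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "C2'", "C1'",
             "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6"),
    x = c(0, 0.8, -0.9, 1.2, 2.1, 3.2, 4.1, 4.8, 5.5,
          6.4, 7.2, 7.1, 8.2, 9.0, 9.9, 8.8, 7.6),
    y = c(0, 1.2, 0.4, -0.8, -1.5, -0.9, -1.8, -0.7, -1.4,
          -0.6, -1.2, -2.4, -0.5, 0.8, 1.3, 1.5, 0.9),
    z = seq(0, 1.6, length.out = 17))
}

# full heavy-atom adenosine
adenosine_atoms <- function() {
  data.frame(
    name = c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "C2'", "C1'",
             "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
    x = c(0, 0.8, -0.9, 1.2, 2.1, 3.2, 4.1, 4.8, 5.5,
          6.4, 7.3, 8.3, 8.1, 9.0, 10.2, 8.5, 7.3, 6.5, 6.9),
    y = c(0, 1.2, 0.4, -0.8, -1.5, -0.9, -1.8, -0.7, -1.4,
          -0.6, -1.3, -0.8, 0.5, 1.5, 1.6, 2.6, 2.7, 1.8, 0.7),
    z = seq(0, 1.8, length.out = 19))
}

write_nt_pdb <- function(path, residues, chain = "R", start_seq = 1L,
                         extra_lines = character()) {
  # residues: character vector over c("U","A"); consecutive numbering
  lines <- character()
  serial <- 1L
  for (k in seq_along(residues)) {
    at <- if (residues[k] == "U") uridine_atoms() else adenosine_atoms()
    sh <- (k - 1) * 6  # displace residues along x so beads do not overlap
    for (a in seq_len(nrow(at))) {
      lines <- c(lines, pdb_line(serial, at$name[a], residues[k], chain,
                                 start_seq + k - 1L,
                                 at$x[a] + sh, at$y[a], at$z[a]))
      serial <- serial + 1L
    }
  }
  writeLines(c(lines, extra_lines, "END"), path)
  path
}

# --- tiny CG structures -----------------------------------------------------

# minimal single-bead structure at a position
one_bead <- function(pos = c(0, 0, 0), type = 1L, charge = 0) {
  cg_structure(matrix(pos, 1, 3), "B", "sidechain", type, charge, 1L, "A", "X")
}

# n-bead random structure (one residue)
random_cg <- function(n = 5, seed = 1, spread = 3) {
  set.seed(seed)
  cg_structure(matrix(stats::rnorm(3 * n, sd = spread), n, 3),
               paste0("B", seq_len(n)), rep("sidechain", n),
               seq_len(n), rep(0, n), 1L, "A", "X")
}

# toy trinucleotide fragment: 2 beads per nucleotide (backbone + base)
toy_trinucleotide <- function(shift = c(0, 0, 0), jitter = 0, seed = NULL,
                              residue_names = c("U", "U", "U")) {
  if (!is.null(seed)) set.seed(seed)
  base <- NULL
  for (i in 1:3) {
    p <- c(4 * (i - 1), 0, 0)
    base <- rbind(base, p, p + c(1.5, 2, 0.5))
  }
  pos <- base + matrix(jitter * stats::rnorm(length(base)), ncol = 3)
  pos <- sweep(pos, 2, -shift)
  conf <- cg_structure(pos, rep(c("BB", "BA"), 3),
                       rep(c("backbone", "base"), 3),
                       rep(c(1L, 2L), 3), 0,
                       rep(1:3, each = 2), "R",
                       rep(residue_names, each = 2))
  trinucleotide_fragment(conf)
}

random_rigid_transform <- function(seed = 1) {
  set.seed(seed)
  rigid_transform(random_quaternions(1)[1, ], stats::rnorm(3, sd = 10))
}

# --- graph oracles ----------------------------------------------------------

# brute-force enumeration of all N-node walks in a directed graph given as
# an adjacency list; returns total count and per-node participation counts
# (one increment per occupied position), the independent oracle for the
# forward-backward DP.
walk_enumeration_oracle <- function(n, edges, N, starts = seq_len(n),
                                    ends = seq_len(n)) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    adj[[edges$from[r]]] <- c(adj[[edges$from[r]]], edges$to[r])
  }
  counts <- numeric(n)
  total <- 0
  walk <- integer(N)
  recurse <- function(v, depth) {
    walk[depth] <<- v
    if (depth == N) {
      if (walk[N] %in% ends) {
        total <<- total + 1
        for (w in walk) counts[w] <<- counts[w] + 1
      }
      return()
    }
    for (u in adj[[v]]) recurse(u, depth + 1L)
  }
  for (s in starts) recurse(s, 1L)
  list(total = total, counts = counts)
}

random_graph <- function(n, p, seed) {
  set.seed(seed)
  idx <- which(matrix(stats::runif(n * n) < p, n, n) & !diag(n), arr.ind = TRUE)
  data.frame(from = idx[, 1], to = idx[, 2],
             energy = rep(0, nrow(idx)))
}

# --- small docking pool built directly from coordinates ---------------------

# a pool of poses of one shared conformer, each pose given by a transform;
# energies are made up but sorted, ranks 1..n
pool_from_transforms <- function(conformer, transforms,
                                 energies = seq_along(transforms)) {
  conf <- conformer
  conf$pos <- sweep(conf$pos, 2, colMeans(conf$pos))
  rows <- lapply(seq_along(transforms), function(i) {
    tf <- transforms[[i]]
    data.frame(pose_id = sprintf("pose%03d", i), conformer_id = "c1",
               rank = NA_integer_, energy = energies[i],
               qw = tf$q[1], qx = tf$q[2], qy = tf$q[3], qz = tf$q[4],
               tx = tf$t[1], ty = tf$t[2], tz = tf$t[3],
               stringsAsFactors = FALSE)
  })
  poses <- do.call(rbind, rows)
  poses <- poses[order(poses$energy), , drop = FALSE]
  poses$rank <- seq_len(nrow(poses))
  rownames(poses) <- NULL
  docking_pool(poses, list(c1 = conf))
}

# cached small scenario shared across test files (cheap, deterministic)
scenario_cache <- new.env()
cached_scenario <- function(seed = 1, n_decoy_poses = 50) {
  key <- paste0("s", seed, "_", n_decoy_poses)
  if (is.null(scenario_cache[[key]])) {
    scenario_cache[[key]] <- make_scenario(seed = seed,
                                           n_decoy_poses = n_decoy_poses)
  }
  scenario_cache[[key]]
}
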