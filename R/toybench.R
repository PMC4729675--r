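#' Deterministic synthetic docking scenario
#'
#' Builds a self-contained toy world for end-to-end testing: an 8-nucleotide
#' coarse-grained ssRNA chain laid along a jittered planar path, the 6
#' overlapping trinucleotide fragments cut from it (the planted chain), a
#' receptor bed whose groove beads are type-matched attractive partners
#' placed at the 8-6 potential minimum distance straight below every chain
#' bead (backed by a deeper repulsive core wall), a conformer library of
#' the 6 planted conformers plus perturbed decoys, and a pose pool of the
#' exact planted poses plus far-away decoy poses that can never form
#' chains. Deterministic per-nucleotide jitter makes the six planted
#' conformers mutually distinct (pairwise superposed RMSD >= 1 A) so each
#' conformer fits its own site best.
#'
#' @param seed integer; governs decoy conformer noise and decoy pose
#'   placement. Same seed, same scenario, bit for bit.
#' @param n_decoy_conformers perturbed library decoys (default 10).
#' @param n_decoy_poses random far poses injected into the pool
#'   (default 200).
#' @param groove_depth distance from chain beads to their receptor partner
#'   beads, Angstrom; defaults to the pair-potential minimum r* = R sqrt(4/3).
#' @return object of class \code{toy_scenario}; see Details.
#' @details Fields: \code{receptor}, \code{chain} (full 8-nt RNA),
#'   \code{fragments} (6 placed fragment \code{cg_structure}s = ground
#'   truth), \code{conformers} (the same 6, as the library conformers),
#'   \code{planted_transforms} (identity rotation + COM translation, valid
#'   for COM-centered conformers), \code{library} (a
#'   \code{fragment_library} with planted + decoy conformers),
#'   \code{pool} (planted + decoy poses, energies re-scored, ranked),
#'   \code{ff} (toy force field), \code{seed}.
#' @export
make_scenario <- function(seed = 1L, n_decoy_conformers = 10L,
                          n_decoy_poses = 200L, groove_depth = NULL) {
  stopifnot(n_decoy_conformers >= 0, n_decoy_poses >= 0)
  ff <- read_forcefield()
  rstar <- 3.4641016 * sqrt(4 / 3)  # minimum of the matched 8-6 pair
  if (is.null(groove_depth)) groove_depth <- rstar

  nnt <- 8L
  beads_per_nt <- 6L
  # planar chain (all beads at z = 0) along a jittered path; the jitter
  # makes the six fragment windows mutually distinct shapes
  i_nt <- seq_len(nnt)
  jx <- c(1.722, 0.798, -0.919, 1.893, -1.787, 0.395, 0.625, 1.091)
  jy <- c(1.728, 2.391, 2.292, -0.218, -2.296, 3.381, -0.686, 1.863)
  path <- cbind(5.9 * (i_nt - 1) + jx, jy, 0)
  tang <- rbind(path[2, ] - path[1, ],
                (path[3:nnt, ] - path[1:(nnt - 2), ]) / 2,
                path[nnt, ] - path[nnt - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  norm2d <- cbind(-tang[, 2], tang[, 1], 0)  # in-plane normal

  # flat toy nucleotide in the chain plane; every groove partner sits
  # exactly groove_depth below its bead, so a mismatched bead-partner
  # distance is always >= groove_depth by construction
  offsets <- list(  # (along tangent, along in-plane normal)
    c(0.0, 0.0),     # GP   phosphate
    c(1.3, 1.0),     # GS1  sugar
    c(2.5, -0.6),    # GS2  sugar
    c(0.9, 2.4),     # UB1  base
    c(1.4, 3.7),     # UB2  base
    c(2.4, 2.9))     # UB3  base
  bead_names <- c("GP", "GS1", "GS2", "UB1", "UB2", "UB3")
  roles <- c("phosphate", "sugar", "sugar", "base", "base", "base")

  pos <- matrix(NA_real_, nnt * beads_per_nt, 3)
  for (i in seq_len(nnt)) {
    for (b in seq_len(beads_per_nt)) {
      o <- offsets[[b]]
      pos[(i - 1) * beads_per_nt + b, ] <-
        path[i, ] + o[1] * tang[i, ] + o[2] * norm2d[i, ]
    }
  }
  # bead types cycle with period 3 nucleotides (18 types): no two
  # nucleotides closer than ~18 A share a type, so a pose cannot gain
  # energy by bridging same-type groove partners or sliding one step
  type_of_nt <- function(i) 6L * ((i - 1L) %% 3L) + 1:6
  chain <- cg_structure(
    pos, rep(bead_names, nnt), rep(roles, nnt),
    as.integer(unlist(lapply(i_nt, type_of_nt))),
    rep(0, nnt * beads_per_nt),
    rep(seq_len(nnt), each = beads_per_nt), "R",
    rep("U", nnt * beads_per_nt))

  # receptor: one matched attractive partner per chain bead at the pair
  # minimum distance straight below it, plus a repulsive core wall deeper
  down <- matrix(rep(c(0, 0, -1), each = nnt * beads_per_nt), ncol = 3)
  partner_pos <- chain$pos + down * groove_depth
  core_pos <- chain$pos + down * (groove_depth + 4.5)
  receptor <- cg_structure(
    rbind(partner_pos, core_pos),
    c(paste0("W", chain$type_code), rep("CORE", nnt * beads_per_nt)),
    rep("sidechain", 2 * nnt * beads_per_nt),
    c(chain$type_code + 20L, rep(40L, nnt * beads_per_nt)),
    rep(0, 2 * nnt * beads_per_nt),
    c(seq_len(nnt * beads_per_nt), seq_len(nnt * beads_per_nt)),
    "P", rep("TOY", 2 * nnt * beads_per_nt))

  nfrag <- nnt - 2L
  fragments <- lapply(seq_len(nfrag), function(k)
    cg_subset(chain, chain$residue_index %in% k:(k + 2)))
  names(fragments) <- paste0("frag", seq_len(nfrag))
  planted_transforms <- lapply(fragments, function(f)
    rigid_transform(c(1, 0, 0, 0), cg_com(f)))

  lib_frags <- lapply(seq_len(nfrag), function(k) {
    conf <- fragments[[k]]
    conf$residue_index <- conf$residue_index - min(conf$residue_index) + 1L
    conf$auth_seq <- conf$residue_index
    conf$residues <- unique(data.frame(
      chain_id = conf$chain_id[1], residue_index = unique(conf$residue_index),
      residue_name = "U", auth_seq = unique(conf$residue_index),
      stringsAsFactors = FALSE))
    trinucleotide_fragment(conf, source_id = "planted",
                           start_residue = k, contacts_protein = TRUE)
  })
  decoy_confs <- with_seed(seed + 1L, {
    lapply(seq_len(n_decoy_conformers), function(d) {
      base <- lib_frags[[1 + (d - 1) %% nfrag]]
      conf <- base$conformer
      conf$pos <- conf$pos + matrix(stats::rnorm(length(conf$pos), sd = 0.8),
                                    ncol = 3)
      trinucleotide_fragment(conf, source_id = "decoy",
                             start_residue = base$start_residue,
                             contacts_protein = FALSE)
    })
  })
  library <- fragment_library(list(UUU = c(lib_frags, decoy_confs)),
                              dedup_threshold = 0.2,
                              provenance = sprintf(
                                "toybench seed %d: %d planted + %d decoys",
                                seed, nfrag, length(decoy_confs)))

  # pose pool: exact planted poses + far decoys on Fibonacci directions at
  # staggered radii, with random orientations. A repair pass pushes any
  # decoy that could continue (or be continued by) another pose radially
  # outward until the whole decoy set is provably non-continuable.
  com_rec <- cg_com(receptor)
  conformers <- lapply(fragments, center_conformer)
  decoy_tf <- list()
  if (n_decoy_poses > 0) {
    dirs <- fibonacci_sphere(n_decoy_poses, 1)
    radii <- 36 + 8 * (seq_len(n_decoy_poses) %% 3)
    qs <- with_seed(seed + 2L, random_quaternions(n_decoy_poses))
    pts <- sweep(dirs * radii, 2, -com_rec)
    dconf <- lapply(seq_len(n_decoy_poses), function(i)
      conformers[[1 + (i - 1) %% nfrag]])
    dstr <- lapply(seq_len(n_decoy_poses), function(i)
      apply_transform(dconf[[i]], rigid_transform(qs[i, ], pts[i, ])))
    op <- overlap_params()
    reach <- max(vapply(dstr, function(s)
      max(sqrt(rowSums(sweep(s$pos, 2, cg_com(s))^2))), numeric(1))) * 4 +
      op$margin_base + sqrt(op$max_violation / op$k)
    others <- c(fragments, dstr)
    for (pass in 1:6) {
      moved <- FALSE
      ocom <- t(vapply(others, cg_com, numeric(3)))
      for (i in seq_len(n_decoy_poses)) {
        me <- nfrag + i
        close_by <- which(sqrt(rowSums(sweep(ocom, 2,
                                             cg_com(others[[me]]))^2)) <=
                            reach)
        bad <- FALSE
        for (j in setdiff(close_by, me)) {
          if (overlap_energy(others[[me]], others[[j]], op) <=
                op$max_violation ||
              overlap_energy(others[[j]], others[[me]], op) <=
                op$max_violation) {
            bad <- TRUE
            break
          }
        }
        if (bad) {
          pts[i, ] <- com_rec + dirs[i, ] * (sqrt(sum((pts[i, ] -
                                                         com_rec)^2)) + 12)
          others[[me]] <- apply_transform(dconf[[i]],
                                          rigid_transform(qs[i, ], pts[i, ]))
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    decoy_tf <- lapply(seq_len(n_decoy_poses), function(i)
      rigid_transform(qs[i, ], pts[i, ]))
  }
  rows <- list()
  for (k in seq_len(nfrag)) {
    tf <- planted_transforms[[k]]
    rows[[length(rows) + 1L]] <- data.frame(
      pose_id = paste0("planted_frag", k), conformer_id = names(fragments)[k],
      rank = NA_integer_, energy = NA_real_,
      qw = tf$q[1], qx = tf$q[2], qy = tf$q[3], qz = tf$q[4],
      tx = tf$t[1], ty = tf$t[2], tz = tf$t[3], stringsAsFactors = FALSE)
  }
  for (d in seq_len(n_decoy_poses)) {
    tf <- decoy_tf[[d]]
    ci <- names(fragments)[1 + (d - 1) %% nfrag]
    rows[[length(rows) + 1L]] <- data.frame(
      pose_id = paste0("decoy_", d), conformer_id = ci,
      rank = NA_integer_, energy = NA_real_,
      qw = tf$q[1], qx = tf$q[2], qy = tf$q[3], qz = tf$q[4],
      tx = tf$t[1], ty = tf$t[2], tz = tf$t[3], stringsAsFactors = FALSE)
  }
  pool <- structure(list(poses = do.call(rbind, rows),
                         conformers = conformers,
                         provenance = sprintf("toybench pool seed %d", seed)),
                    class = "docking_pool")
  pool <- rescore(pool, receptor, ff)

  structure(list(seed = seed, receptor = receptor, chain = chain,
                 fragments = fragments, conformers = conformers,
                 planted_transforms = planted_transforms,
                 library = library, pool = pool, ff = ff,
                 n_decoy_poses = n_decoy_poses),
            class = "toy_scenario")
}

#' @export
print.toy_scenario <- function(x, ...) {
  cat(sprintf(paste0("toy_scenario (seed %d): receptor %d beads, ",
                     "%d planted fragments, %d decoy poses\n"),
              x$seed, n_beads(x$receptor), length(x$fragments),
              x$n_decoy_poses))
  invisible(x)
}
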