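#' Docking pool
#'
#' A set of rigid-body poses of conformers from one library class on one
#' receptor. \code{poses} is a data.frame sorted by energy with columns
#' \code{pose_id}, \code{conformer_id}, \code{rank}, \code{energy},
#' \code{qw..qz} (rotation quaternion), \code{tx..tz} (translation).
#' Conformers are stored centered on their center of mass; pose bead
#' coordinates are \code{R X + t}.
#'
#' @param poses pose data.frame (see above).
#' @param conformers named list of COM-centered \code{cg_structure}.
#' @param provenance character log.
#' @return object of class \code{docking_pool}.
#' @export
docking_pool <- function(poses, conformers, provenance = character()) {
  if (nrow(poses) > 0) {
    stopifnot(!is.unsorted(poses$energy), !anyDuplicated(poses$pose_id))
  }
  structure(list(poses = poses, conformers = conformers,
                 provenance = provenance),
            class = "docking_pool")
}

#' @export
print.docking_pool <- function(x, ...) {
  cat(sprintf("docking_pool: %d poses, %d conformer(s)\n",
              nrow(x$poses), length(x$conformers)))
  invisible(x)
}

empty_pose_frame <- function() {
  data.frame(pose_id = character(), conformer_id = character(),
             rank = integer(), energy = numeric(),
             qw = numeric(), qx = numeric(), qy = numeric(), qz = numeric(),
             tx = numeric(), ty = numeric(), tz = numeric(),
             stringsAsFactors = FALSE)
}

center_conformer <- function(s) {
  out <- s
  out$pos <- sweep(s$pos, 2, cg_com(s))
  out
}

#' Bead coordinates of poses
#'
#' Expands each pose row into its placed bead coordinates.
#'
#' @param pool a \code{docking_pool}.
#' @param rows integer row selector (default all).
#' @return matrix with one pose per row, flattened x1 y1 z1 x2 ... columns.
#'   All conformers in the pool must have equal bead counts.
#' @export
pose_coord_matrix <- function(pool, rows = seq_len(nrow(pool$poses))) {
  p <- pool$poses[rows, , drop = FALSE]
  nb <- unique(vapply(pool$conformers, n_beads, 0L))
  if (length(nb) != 1) stop("conformers with unequal bead counts in pool")
  out <- matrix(NA_real_, nrow(p), 3L * nb)
  for (i in seq_len(nrow(p))) {
    conf <- pool$conformers[[p$conformer_id[i]]]
    R <- quat_to_matrix(c(p$qw[i], p$qx[i], p$qy[i], p$qz[i]))
    xyz <- conf$pos %*% t(R)
    xyz <- sweep(xyz, 2, -c(p$tx[i], p$ty[i], p$tz[i]))
    out[i, ] <- as.numeric(t(xyz))
  }
  out
}

#' Placed cg_structure of one pose
#'
#' @param pool a \code{docking_pool}.
#' @param row pose row index (or pose_id string).
#' @return the placed \code{cg_structure}.
#' @export
pose_structure <- function(pool, row) {
  if (is.character(row)) row <- match(row, pool$poses$pose_id)
  p <- pool$poses[row, ]
  conf <- pool$conformers[[p$conformer_id]]
  apply_transform(conf, rigid_transform(c(p$qw, p$qx, p$qy, p$qz),
                                        c(p$tx, p$ty, p$tz)))
}

#' Generate docking starts on a sphere around the receptor
#'
#' Center-of-mass start positions are placed deterministically on a
#' Fibonacci lattice over a sphere of the given radius centered on
#' \code{receptor_com}; orientations are drawn uniformly from SO(3) using
#' the seeded generator. Transforms are meant to be applied to COM-centered
#' conformers, so the translation is the start COM itself.
#'
#' @param n number of starts (>= 1). The published library-docking protocol
#'   uses 30,000; the bound benchmark mode 200,000.
#' @param radius sphere radius, Angstrom (75 in the published protocol).
#' @param seed integer RNG seed (orientation draw).
#' @param receptor_com numeric(3).
#' @return list of \code{rigid_transform}.
#' @export
generate_starts <- function(n, radius = 75, seed = 1L,
                            receptor_com = c(0, 0, 0)) {
  stopifnot(n >= 1, radius > 0)
  pts <- fibonacci_sphere(n, radius, receptor_com)
  qs <- with_seed(seed, random_quaternions(n))
  lapply(seq_len(n), function(i) rigid_transform(qs[i, ], pts[i, ]))
}

# evaluate expr with a private RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Precompute receptor grids
#'
#' For every probe bead type, tabulates the receptor interaction potential
#' and its analytic gradient on a regular lattice covering the receptor
#' bounding box plus padding, along with a per-unit-charge electrostatic
#' grid. Pose energies during minimization are trilinear interpolations of
#' these grids (exact at lattice nodes). Points outside the grid evaluate
#' to zero; the COM restraint steers distant poses back.
#'
#' @param protein receptor \code{cg_structure}.
#' @param ff a \code{forcefield_params}.
#' @param probe_codes fragment bead type codes to tabulate.
#' @param spacing lattice spacing, Angstrom.
#' @param padding box padding beyond the receptor bounding box, Angstrom.
#' @return object of class \code{receptor_grid}.
#' @export
build_grid <- function(protein, ff, probe_codes, spacing = 1.0,
                       padding = 10) {
  stopifnot(spacing > 0)
  probe_codes <- sort(unique(probe_codes))
  if (n_beads(protein) == 0) {
    dims <- c(2L, 2L, 2L)
    np <- length(probe_codes)
    z <- numeric(prod(dims) * (np + 1))
    return(structure(list(origin = c(0, 0, 0), spacing = spacing,
                          dims = dims, probe_codes = probe_codes,
                          grids = list(V = z, Gx = z, Gy = z, Gz = z),
                          compiled = NULL, receptor_com = c(0, 0, 0)),
                     class = "receptor_grid"))
  }
  cf <- compile_ff(ff, probe_codes, protein$type_code)
  lo <- apply(protein$pos, 2, min) - padding
  hi <- apply(protein$pos, 2, max) + padding
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  grids <- build_grid_cpp(protein$pos, code_slots(protein$type_code, cf),
                          protein$charge,
                          code_slots(probe_codes, cf),
                          cf$EPS, cf$RB, cf$ATTR,
                          lo, spacing, dims, cf$dd, cf$coulomb_scale)
  structure(list(origin = lo, spacing = spacing, dims = dims,
                 probe_codes = probe_codes, grids = grids,
                 compiled = cf, receptor_com = cg_com(protein)),
            class = "receptor_grid")
}

#' Grid-interpolated energy of a placed fragment
#'
#' @param grid a \code{receptor_grid}.
#' @param fragment placed \code{cg_structure} whose type codes are all in
#'   the grid's probe set.
#' @return energy in kcal/mol.
#' @export
grid_energy <- function(grid, fragment) {
  slot <- match(fragment$type_code, grid$probe_codes) - 1L
  if (any(is.na(slot))) {
    stop("fragment type codes not tabulated in grid: ",
         paste(setdiff(fragment$type_code, grid$probe_codes), collapse = ", "))
  }
  res <- grid_energy_cpp(fragment$pos, slot, fragment$charge, grid$grids,
                         grid$origin, grid$spacing, grid$dims,
                         length(grid$probe_codes))
  res$energy
}

#' Rigid-body minimization of one pose
#'
#' Local minimization over the 6 rigid degrees of freedom (3 translation +
#' 3 rotation) by adaptive-step gradient descent with a monotone
#' backtracking acceptance rule, so the energy trajectory never increases.
#' The center-of-mass restraint toward the receptor COM is active
#' throughout. Early exit when the (scaled) gradient norm drops below
#' \code{gtol}.
#'
#' @param conformer COM-centered \code{cg_structure}.
#' @param transform starting \code{rigid_transform}.
#' @param grid a \code{receptor_grid} (or NULL for direct summation).
#' @param ff a \code{forcefield_params}.
#' @param protein receptor (required when \code{grid} is NULL; also used
#'   for the restraint center when the grid is absent).
#' @param steps maximum minimization steps (published protocol: 1000).
#' @param gtol gradient-norm early-exit threshold, kcal/mol/A.
#' @return list with \code{transform}, \code{energy} (kcal/mol, includes
#'   the restraint), \code{iters}, \code{converged}, \code{ok} (FALSE when
#'   the starting energy was non-finite; such poses are to be skipped).
#' @export
minimize_pose <- function(conformer, transform, grid = NULL, ff,
                          protein = NULL, steps = 1000, gtol = 1e-4) {
  stopifnot(steps >= 1)
  use_grid <- !is.null(grid)
  if (use_grid) {
    slot <- match(conformer$type_code, grid$probe_codes) - 1L
    if (any(is.na(slot))) stop("conformer type codes missing from grid")
    cf <- grid$compiled
    com_rec <- grid$receptor_com
    rpos <- matrix(0, 0, 3); rtyp <- integer(); rq <- numeric()
    if (is.null(cf)) {  # empty-receptor grid
      cf <- list(EPS = matrix(0, 1, 1), RB = matrix(1, 1, 1),
                 ATTR = matrix(FALSE, 1, 1), dd = TRUE, coulomb_scale = 1)
    }
  } else {
    if (is.null(protein)) stop("direct minimization needs the receptor")
    cf <- compile_ff(ff, conformer$type_code, protein$type_code)
    slot <- code_slots(conformer$type_code, cf)
    com_rec <- cg_com(protein)
    rpos <- protein$pos
    rtyp <- code_slots(protein$type_code, cf)
    rq <- protein$charge
  }
  R0 <- quat_to_matrix(transform$q)
  res <- minimize_cpp(conformer$pos, as.numeric(t(R0)), transform$t,
                      slot, conformer$charge,
                      if (use_grid) grid$grids else list(V = 0, Gx = 0,
                                                         Gy = 0, Gz = 0),
                      if (use_grid) grid$origin else c(0, 0, 0),
                      if (use_grid) grid$spacing else 1,
                      if (use_grid) grid$dims else c(2L, 2L, 2L),
                      if (use_grid) length(grid$probe_codes) else 0L,
                      use_grid, rpos, rtyp, rq,
                      cf$EPS, cf$RB, cf$ATTR, cf$dd, cf$coulomb_scale,
                      com_rec, ff$com_restraint_k, as.integer(steps), gtol)
  Rm <- matrix(res$R, 3, 3, byrow = TRUE)
  list(transform = rigid_transform(matrix_to_quat(Rm), res$t),
       energy = res$energy, iters = res$iters,
       converged = res$converged, ok = res$ok)
}

#' Dock a set of conformers onto a receptor
#'
#' Full rigid-body ensemble docking: deterministic sphere starts, grid (or
#' direct) minimization with the COM restraint, grid-free re-scoring
#' without the restraint, energy sort and redundancy removal.
#'
#' @param protein receptor \code{cg_structure}.
#' @param conformers named list of \code{cg_structure} conformers (one
#'   library class); centered internally.
#' @param ff a \code{forcefield_params}.
#' @param nstarts starts per conformer.
#' @param seed integer seed for start orientations.
#' @param radius start-sphere radius, Angstrom.
#' @param steps minimization steps.
#' @param grid optional prebuilt \code{receptor_grid}; built on the fly
#'   when NULL and \code{use_grid} is TRUE.
#' @param use_grid minimize on the precomputed grid (default TRUE).
#' @param spacing,padding grid construction parameters.
#' @param dedup_tol redundancy threshold, Angstrom (published: 0.05).
#' @return a \code{docking_pool} sorted by re-scored energy.
#' @export
dock <- function(protein, conformers, ff, nstarts = 1000, seed = 1L,
                 radius = 75, steps = 1000, grid = NULL, use_grid = TRUE,
                 spacing = 1.0, padding = 10, dedup_tol = 0.05) {
  if (is.null(names(conformers))) {
    names(conformers) <- paste0("conf", seq_along(conformers))
  }
  conformers <- lapply(conformers, center_conformer)
  if (use_grid && is.null(grid)) {
    probe <- sort(unique(unlist(lapply(conformers, `[[`, "type_code"))))
    grid <- build_grid(protein, ff, probe, spacing = spacing,
                       padding = padding)
  }
  starts <- generate_starts(nstarts, radius, seed, cg_com(protein))
  rows <- vector("list", length(conformers) * nstarts)
  n <- 0L
  for (ci in names(conformers)) {
    conf <- conformers[[ci]]
    for (si in seq_along(starts)) {
      m <- minimize_pose(conf, starts[[si]],
                         grid = if (use_grid) grid else NULL,
                         ff = ff, protein = protein, steps = steps)
      if (!m$ok) next
      n <- n + 1L
      rows[[n]] <- data.frame(
        pose_id = sprintf("%s_s%d", ci, si), conformer_id = ci,
        rank = NA_integer_, energy = m$energy,
        qw = m$transform$q[1], qx = m$transform$q[2],
        qy = m$transform$q[3], qz = m$transform$q[4],
        tx = m$transform$t[1], ty = m$transform$t[2],
        tz = m$transform$t[3], stringsAsFactors = FALSE)
    }
  }
  poses <- if (n > 0) do.call(rbind, rows[seq_len(n)]) else empty_pose_frame()
  pool <- docking_pool(poses[order(poses$energy), , drop = FALSE][0, ],
                       conformers,
                       sprintf("dock: %d conformers x %d starts, seed %d",
                               length(conformers), nstarts, seed))
  pool$poses <- poses
  pool <- rescore(pool, protein, ff)
  deduplicate_poses(pool, dedup_tol)
}

#' Re-score poses without the grid
#'
#' Recomputes every pose energy by direct pairwise summation with the
#' force-field cutoff applied and the COM restraint excluded, then re-sorts
#' and re-ranks. Idempotent.
#'
#' @param pool a \code{docking_pool}.
#' @param protein receptor \code{cg_structure}.
#' @param ff a \code{forcefield_params}.
#' @return the re-scored \code{docking_pool}.
#' @export
rescore <- function(pool, protein, ff) {
  p <- pool$poses
  if (nrow(p) > 0) {
    for (i in seq_len(nrow(p))) {
      p$energy[i] <- energy(protein, pose_structure(pool, i), ff,
                            com_restraint = FALSE, use_cutoff = TRUE)
    }
    p <- p[order(p$energy), , drop = FALSE]
    p$rank <- seq_len(nrow(p))
    rownames(p) <- NULL
  }
  docking_pool(p, pool$conformers,
               c(pool$provenance, "rescored without grid/restraint"))
}

#' Discard redundant poses
#'
#' Descending the energy sort, a pose is removed iff its ligand-RMSD (no
#' re-superposition) to any better-scored kept pose of the same conformer
#' is strictly below \code{tol}. Ranks are recomputed 1..N.
#'
#' @param pool a \code{docking_pool} sorted by energy.
#' @param tol Angstrom (published protocol: 0.05).
#' @return the deduplicated \code{docking_pool}.
#' @export
deduplicate_poses <- function(pool, tol = 0.05) {
  p <- pool$poses
  if (nrow(p) <= 1) return(pool)
  stopifnot(!is.unsorted(p$energy))
  coords <- pose_coord_matrix(pool)
  keep <- greedy_dedup_cpp(coords,
                           as.integer(factor(p$conformer_id)), tol)
  p <- p[keep, , drop = FALSE]
  p$rank <- seq_len(nrow(p))
  rownames(p) <- NULL
  docking_pool(p, pool$conformers,
               c(pool$provenance,
                 sprintf("dedup at %.3g A: %d kept", tol, nrow(p))))
}

#' Keep the top-ranked fraction of a pool
#'
#' Keeps the \code{ceiling(fraction * N)} best-energy poses. The original
#' ranks are preserved in an \code{orig_rank} column; working ranks are
#' recomputed.
#'
#' @param pool a \code{docking_pool}.
#' @param fraction in (0, 1]. The published protocol keeps 20\% for bound
#'   and biased docking, 5\% for full-library docking.
#' @return the truncated \code{docking_pool}.
#' @export
select_top <- function(pool, fraction = 0.2) {
  stopifnot(fraction > 0, fraction <= 1)
  p <- pool$poses
  if (nrow(p) == 0) return(pool)
  k <- ceiling(fraction * nrow(p))
  p <- p[seq_len(k), , drop = FALSE]
  if (is.null(p$orig_rank)) p$orig_rank <- p$rank
  p$rank <- seq_len(nrow(p))
  rownames(p) <- NULL
  docking_pool(p, pool$conformers,
               c(pool$provenance,
                 sprintf("top %.3g%%: %d poses", 100 * fraction, nrow(p))))
}

#' Merge docking pools into a single pool
#'
#' Concatenates poses (pose ids are prefixed by pool name when duplicated),
#' re-sorts by energy and re-ranks.
#'
#' @param pools list of \code{docking_pool}.
#' @return one \code{docking_pool}.
#' @export
merge_pools <- function(pools) {
  all_poses <- list()
  conformers <- list()
  cols <- Reduce(union, lapply(pools, function(x) names(x$poses)))
  for (k in seq_along(pools)) {
    p <- pools[[k]]$poses
    for (nm in setdiff(cols, names(p))) p[[nm]] <- NA
    p <- p[cols]
    dup <- p$pose_id %in% unlist(lapply(all_poses, `[[`, "pose_id"))
    if (any(dup)) p$pose_id[dup] <- sprintf("p%d_%s", k, p$pose_id[dup])
    all_poses[[k]] <- p
    for (nm in names(pools[[k]]$conformers)) {
      conformers[[nm]] <- pools[[k]]$conformers[[nm]]
    }
  }
  p <- do.call(rbind, all_poses)
  p <- p[order(p$energy), , drop = FALSE]
  p$rank <- seq_len(nrow(p))
  rownames(p) <- NULL
  docking_pool(p, conformers, "merged pool")
}

#' Write a pose table
#'
#' Tab-separated with a \code{#} header naming units: pose_id,
#' conformer_id, rank, energy (kcal/mol), qw..qz, tx..tz (Angstrom).
#'
#' @param pool a \code{docking_pool}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pose_table <- function(pool, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# rnafragdock pose table; energy kcal/mol; ",
                    "quaternion (qw qx qy qz) then translation (tx ty tz, A) ",
                    "applied to the COM-centered conformer"), con)
  utils::write.table(pool$poses, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pose table written by \code{\link{write_pose_table}}
#'
#' @param path pose table file.
#' @param conformers named list of conformers (centered or not; centered
#'   internally).
#' @return a \code{docking_pool}.
#' @export
read_pose_table <- function(path, conformers) {
  p <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  p <- p[order(p$energy), , drop = FALSE]
  rownames(p) <- NULL
  docking_pool(p, lapply(conformers, center_conformer),
               sprintf("read from %s", path))
}
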