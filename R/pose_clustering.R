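#' Greedy leader clustering of poses
#'
#' Walks the poses in rank (energy) order: a pose joins the first existing
#' cluster whose representative lies within \code{radius} (ligand-RMSD, no
#' re-superposition), else it founds a new cluster. Deterministic given the
#' rank order; ranks are unique so there is no tie ambiguity.
#'
#' @param pool a rank-sorted \code{docking_pool}.
#' @param radius cluster radius, Angstrom (> 0).
#' @return list of clusters; each cluster is a list with
#'   \code{representative} (pose_id of the best-ranked member),
#'   \code{members} (pose_ids) and \code{radius}.
#' @export
cluster_poses <- function(pool, radius) {
  if (radius <= 0) stop("cluster radius must be > 0")
  p <- pool$poses
  if (nrow(p) == 0) return(list())
  stopifnot(!is.unsorted(p$energy))
  cl <- leader_cluster_cpp(pose_coord_matrix(pool), radius)
  lapply(seq_len(max(cl)), function(k) {
    members <- p$pose_id[cl == k]
    list(representative = members[1], members = members, radius = radius)
  })
}

#' Multi-radius sequential clustering
#'
#' Clusters the pool at the first radius, then repeatedly clusters the
#' previous level's representatives at the next (larger) radius, recording
#' parent links. Published radii: 2, 3, 4 Angstrom.
#'
#' @param pool a rank-sorted \code{docking_pool}.
#' @param radii strictly increasing radii, Angstrom.
#' @return object of class \code{cluster_hierarchy}: \code{levels} (list of
#'   cluster lists, finest first), \code{radii}, \code{parent} (for each
#'   level l < L, integer vector mapping level-l clusters to their
#'   level-(l+1) parent), and \code{pool}.
#' @export
sequential_cluster <- function(pool, radii = c(2, 3, 4)) {
  stopifnot(length(radii) >= 1, all(diff(radii) > 0))
  levels <- list()
  parent <- list()
  current <- pool
  for (l in seq_along(radii)) {
    cl <- cluster_poses(current, radii[l])
    levels[[l]] <- cl
    reps <- vapply(cl, `[[`, "", "representative")
    idx <- match(reps, current$poses$pose_id)
    q <- current$poses[idx, , drop = FALSE]
    rownames(q) <- NULL
    current <- docking_pool(q[order(q$energy), , drop = FALSE],
                            current$conformers)
  }
  for (l in seq_along(radii)[-length(radii)]) {
    reps <- vapply(levels[[l]], `[[`, "", "representative")
    parent[[l]] <- vapply(reps, function(r) {
      which(vapply(levels[[l + 1]], function(c2) r %in% c2$members,
                   logical(1)))[1]
    }, integer(1))
  }
  structure(list(levels = levels, radii = radii, parent = parent,
                 pool = pool),
            class = "cluster_hierarchy")
}

#' @export
print.cluster_hierarchy <- function(x, ...) {
  cat("cluster_hierarchy:\n")
  for (l in seq_along(x$levels)) {
    cat(sprintf("  %.3g A: %d clusters\n", x$radii[l], length(x$levels[[l]])))
  }
  invisible(x)
}

#' Coarse-to-fine hierarchical overlap assembly
#'
#' Candidate cluster pairs are screened at the coarsest level with the
#' loosest overlap margins (on cluster representatives); every retained
#' pair is refined by testing its children pair-wise at the next level's
#' tighter margins, down to individual poses where the standard overlap
#' energy decides the final edge set. Chains are then enumerated from the
#' surviving pose edges. A one-entry schedule reduces to a direct
#' all-pairs graph build.
#'
#' @param hierarchy a \code{cluster_hierarchy}.
#' @param params_schedule list of \code{overlap_params}: entry 1 for the
#'   pose level, entry l+1 for hierarchy level l (margins should not
#'   increase toward the pose level).
#' @param N chain length.
#' @param cap enumeration cap (see \code{\link{enumerate_chains}}).
#' @return list with \code{chains}, \code{graph} (pose-level
#'   \code{chain_graph}) and \code{counts}.
#' @export
hierarchical_assembly <- function(hierarchy, params_schedule, N,
                                  cap = 1e6) {
  nlev <- length(params_schedule) - 1L
  stopifnot(nlev >= 0, nlev <= length(hierarchy$levels))
  pool <- hierarchy$pool
  ids <- pool$poses$pose_id
  structs <- lapply(seq_along(ids), function(i) pose_structure(pool, i))
  names(structs) <- ids

  # members of a level-l cluster as pose ids (level 0 = a single pose)
  members_of <- function(l, k) {
    if (l == 0) return(ids[k])
    hierarchy$levels[[l]][[k]]$members
  }
  children_of <- function(l, k) {
    # indices at level l-1 whose parent is cluster k of level l
    if (l == 1) return(match(hierarchy$levels[[1]][[k]]$members, ids))
    which(hierarchy$parent[[l - 1]] == k)
  }
  rep_struct <- function(l, k) {
    if (l == 0) return(structs[[k]])
    structs[[hierarchy$levels[[l]][[k]]$representative]]
  }
  test_pair <- function(l, i, j, params) {
    if (l == 0 && i == j) return(FALSE)
    e <- overlap_energy(rep_struct(l, i), rep_struct(l, j), params)
    thr <- if (params$hard_mode) 0 else params$max_violation
    e <= thr
  }

  if (nlev == 0) {
    graph <- build_graph(pool, params_schedule[[1]], mode = "single_pool")
  } else {
    ntop <- length(hierarchy$levels[[nlev]])
    if (ntop == 0) {
      return(list(chains = list(),
                  graph = structure(list(node_id = character(),
                                         pool_of = integer(),
                                         edges = data.frame(),
                                         n_pools = 1L,
                                         mode = "single_pool"),
                                    class = "chain_graph"),
                  counts = NULL))
    }
    pairs <- expand.grid(i = seq_len(ntop), j = seq_len(ntop))
    keep <- mapply(function(i, j)
      test_pair(nlev, i, j, params_schedule[[nlev + 1]]),
      pairs$i, pairs$j)
    pairs <- pairs[keep, , drop = FALSE]
    for (l in seq(nlev, 1)) {
      refined <- list()
      seen <- character()
      for (r in seq_len(nrow(pairs))) {
        ci <- children_of(l, pairs$i[r])
        cj <- children_of(l, pairs$j[r])
        for (a in ci) {
          for (b in cj) {
            key <- paste(a, b)
            if (key %in% seen) next
            seen <- c(seen, key)
            if (test_pair(l - 1, a, b, params_schedule[[l]])) {
              refined[[length(refined) + 1L]] <- c(a, b)
            }
          }
        }
      }
      if (length(refined) == 0) {
        pairs <- data.frame(i = integer(), j = integer())
        break
      }
      m <- do.call(rbind, refined)
      pairs <- data.frame(i = m[, 1], j = m[, 2])
    }
    # pairs are now pose-level edges, already decided by params_schedule[[1]]
    edges <- if (nrow(pairs)) {
      en <- mapply(function(i, j)
        overlap_energy(structs[[i]], structs[[j]], params_schedule[[1]]),
        pairs$i, pairs$j)
      data.frame(from = pairs$i, to = pairs$j, energy = en)
    } else data.frame(from = integer(), to = integer(), energy = numeric())
    graph <- structure(list(node_id = ids,
                            pool_of = rep(1L, length(ids)),
                            edges = edges, n_pools = 1L,
                            mode = "single_pool"),
                       class = "chain_graph")
  }
  counts <- count_chains(graph, N)
  chains <- if (counts$total_chains > 0 && counts$total_chains <= cap) {
    enumerate_chains(graph, N, cap)
  } else list()
  list(chains = chains, graph = graph, counts = counts)
}

#' Cluster-then-assemble with enlarged hard margins
#'
#' The cluster-level assembly used after propensity filtering: cluster the
#' filtered poses (published: 3 A), take the best-ranked representative of
#' each cluster, connect representatives with uniform enlarged margins
#' (published: 5 A) and no violation allowed, propensity-filter the
#' representatives, and enumerate the resulting chains.
#'
#' @param pool a propensity-filtered \code{docking_pool}.
#' @param cluster_radius Angstrom (default 3).
#' @param loose_margin uniform margin for both backbone and base beads,
#'   Angstrom (default 5).
#' @param hard_mode no violation allowed (default TRUE).
#' @param N chain length.
#' @param threshold propensity threshold.
#' @param cap enumeration cap.
#' @return list with \code{pool} (filtered representatives), \code{chains},
#'   \code{graph}, \code{counts}, \code{clusters}.
#' @export
assemble_clustered <- function(pool, cluster_radius = 3, loose_margin = 5,
                               hard_mode = TRUE, N = 5, threshold = 1e-4,
                               cap = 1e6) {
  clusters <- cluster_poses(pool, cluster_radius)
  reps <- vapply(clusters, `[[`, "", "representative")
  idx <- match(reps, pool$poses$pose_id)
  q <- pool$poses[idx, , drop = FALSE]
  rownames(q) <- NULL
  rep_pool <- docking_pool(q[order(q$energy), , drop = FALSE],
                           pool$conformers,
                           c(pool$provenance,
                             sprintf("clustered at %.3g A: %d representatives",
                                     cluster_radius, length(reps))))
  params <- overlap_params(margin_backbone = loose_margin,
                           margin_base = loose_margin, k = 100,
                           max_violation = if (hard_mode) 0 else 2,
                           hard_mode = hard_mode)
  graph <- build_graph(rep_pool, params, mode = "single_pool")
  counts <- count_chains(graph, N)
  filtered <- propensity_filter(rep_pool, counts, graph, threshold)
  chains <- if (counts$total_chains > 0 && counts$total_chains <= cap) {
    enumerate_chains(graph, N, cap)
  } else list()
  list(pool = filtered, chains = chains, graph = graph, counts = counts,
       clusters = clusters)
}

#' Write a cluster table
#'
#' Tab-separated: cluster_id, level_radius, representative_pose_id,
#' member_count, member_ids (comma-joined).
#'
#' @param clusters list of clusters from \code{\link{cluster_poses}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  df <- data.frame(
    cluster_id = seq_along(clusters),
    level_radius = vapply(clusters, `[[`, 0, "radius"),
    representative_pose_id = vapply(clusters, `[[`, "", "representative"),
    member_count = vapply(clusters, function(c) length(c$members), 0L),
    member_ids = vapply(clusters, function(c)
      paste(c$members, collapse = ","), ""))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
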