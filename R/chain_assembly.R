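#' Overlap restraint parameters
#'
#' Flat-bottom harmonic restraints tying the shared nucleotides of two
#' candidate consecutive poses: nucleotides 2-3 of the first fragment must
#' superpose (within a margin) on nucleotides 1-2 of the second. Margins
#' are tighter for backbone/sugar/phosphate beads than for base beads, to
#' leave room for later backbone linking.
#'
#' @param margin_backbone Angstrom (published: 2.3).
#' @param margin_base Angstrom (published: 2.8).
#' @param k harmonic constant, kcal/mol/A^2 (published: 100).
#' @param max_violation total violation budget, kcal/mol (published: 2);
#'   two poses are connectable when the summed violation energy is at or
#'   below this.
#' @param hard_mode when TRUE no violation at all is allowed (used with the
#'   enlarged 5 A margins of cluster-level assembly).
#' @return object of class \code{overlap_params}.
#' @export
overlap_params <- function(margin_backbone = 2.3, margin_base = 2.8,
                           k = 100, max_violation = 2, hard_mode = FALSE) {
  stopifnot(margin_backbone > 0, margin_base > 0, k > 0, max_violation >= 0)
  structure(list(margin_backbone = margin_backbone,
                 margin_base = margin_base, k = k,
                 max_violation = max_violation, hard_mode = hard_mode),
            class = "overlap_params")
}

# beads of the r-th residue (1-based within the fragment), in bead order
residue_beads <- function(s, r) {
  ord <- sort(unique(s$residue_index))
  which(s$residue_index == ord[r])
}

#' Overlap violation energy between two placed fragment poses
#'
#' Sums, over the corresponding bead pairs (nt2 of \code{pose_i} vs nt1 of
#' \code{pose_j}, and nt3 vs nt2), the flat-bottom energy
#' \eqn{k (d - m)^2} for \eqn{d > m} and 0 otherwise, with margin \eqn{m}
#' chosen by bead role.
#'
#' @param pose_i,pose_j placed \code{cg_structure} fragments (3 nucleotides
#'   each) with matching bead roles on the paired nucleotides.
#' @param params an \code{overlap_params}.
#' @return violation energy, kcal/mol.
#' @export
overlap_energy <- function(pose_i, pose_j, params = overlap_params()) {
  e <- 0
  for (pair in list(c(2L, 1L), c(3L, 2L))) {
    bi <- residue_beads(pose_i, pair[1])
    bj <- residue_beads(pose_j, pair[2])
    if (length(bi) != length(bj) ||
        !all(pose_i$role[bi] == pose_j$role[bj])) {
      stop("bead-role mismatch between paired nucleotides")
    }
    d <- sqrt(rowSums((pose_i$pos[bi, , drop = FALSE] -
                         pose_j$pos[bj, , drop = FALSE])^2))
    m <- ifelse(pose_i$role[bi] == "base", params$margin_base,
                params$margin_backbone)
    exc <- pmax(0, d - m)
    e <- e + params$k * sum(exc^2)
  }
  e
}

# overlap restraint beads of a pose, flattened, with margins:
# "tail" = nucleotides 2+3 (restrained when the pose comes first),
# "head" = nucleotides 1+2 (restrained when the pose comes second).
pose_overlap_parts <- function(struct) {
  tail_idx <- c(residue_beads(struct, 2L), residue_beads(struct, 3L))
  head_idx <- c(residue_beads(struct, 1L), residue_beads(struct, 2L))
  list(tail = struct$pos[tail_idx, , drop = FALSE],
       head = struct$pos[head_idx, , drop = FALSE],
       tail_role = struct$role[tail_idx],
       head_role = struct$role[head_idx])
}

#' Construct a pose connectivity graph directly
#'
#' Low-level constructor, mainly for testing and for graphs imported from
#' edge lists; \code{\link{build_graph}} builds one from docking pools.
#'
#' @param node_id character vector of node (pose) ids.
#' @param edges data.frame with integer columns \code{from}, \code{to}
#'   (1-based node indices) and numeric \code{energy}.
#' @param pool_of integer pool index per node (all 1 for single-pool).
#' @return a \code{chain_graph}.
#' @export
chain_graph <- function(node_id, edges, pool_of = rep(1L, length(node_id))) {
  stopifnot(all(edges$from >= 1), all(edges$from <= length(node_id)),
            all(edges$to >= 1), all(edges$to <= length(node_id)),
            length(pool_of) == length(node_id))
  if (is.null(edges$energy)) edges$energy <- rep(0, nrow(edges))
  npool <- max(pool_of)
  structure(list(node_id = node_id, pool_of = as.integer(pool_of),
                 edges = edges, n_pools = npool,
                 mode = if (npool > 1) "position_specific" else "single_pool"),
            class = "chain_graph")
}

#' Pose connectivity graph
#'
#' Directed graph over poses: an edge i -> j means pose j can continue
#' pose i toward 3'. In \code{position_specific} mode the pools are the
#' per-fragment pools and edges only connect pool p to pool p+1; in
#' \code{single_pool} mode all ordered pose pairs are tested. Connectivity
#' requires overlap energy at or below \code{max_violation} (exactly 0 in
#' hard mode). A conservative spatial pre-filter on restrained-bead
#' centroids prunes pairs without changing the edge set.
#'
#' @param pools a \code{docking_pool} (single-pool mode) or a list of them
#'   (position-specific mode).
#' @param params an \code{overlap_params}.
#' @param mode \code{"single_pool"} or \code{"position_specific"}; default
#'   chosen from the shape of \code{pools}.
#' @param prefilter use the spatial pre-filter (default TRUE; FALSE forces
#'   the brute-force all-pairs scan).
#' @return object of class \code{chain_graph}: node ids, pool index per
#'   node, edge data.frame (from, to, energy as integer node indices plus
#'   kcal/mol), mode.
#' @export
build_graph <- function(pools, params = overlap_params(), mode = NULL,
                        prefilter = TRUE) {
  if (inherits(pools, "docking_pool")) {
    if (is.null(mode)) mode <- "single_pool"
    pools <- list(pools)
  } else if (is.null(mode)) {
    mode <- "position_specific"
  }
  npool <- length(pools)
  stopifnot(all(vapply(pools, function(p) nrow(p$poses) > 0, TRUE)))
  node_id <- character()
  pool_of <- integer()
  structs <- list()
  for (p in seq_len(npool)) {
    ids <- pools[[p]]$poses$pose_id
    for (i in seq_along(ids)) {
      structs[[length(structs) + 1L]] <- pose_structure(pools[[p]], i)
    }
    node_id <- c(node_id, if (mode == "position_specific" && npool > 1)
      paste0("p", p, ":", ids) else ids)
    pool_of <- c(pool_of, rep(p, length(ids)))
  }
  nn <- length(node_id)
  parts <- lapply(structs, pose_overlap_parts)
  tails <- t(vapply(parts, function(x) colMeans(x$tail), numeric(3)))
  heads <- t(vapply(parts, function(x) colMeans(x$head), numeric(3)))
  # pre-filter bound: if every restrained bead pair were at the same
  # distance d, connectivity needs d <= m_max + sqrt(max_violation/k) per
  # pair; centroids cannot be farther than the max bead spread plus that.
  spread <- vapply(seq_len(nn), function(i) {
    max(sqrt(rowSums(sweep(parts[[i]]$tail, 2, tails[i, ])^2)),
        sqrt(rowSums(sweep(parts[[i]]$head, 2, heads[i, ])^2)))
  }, numeric(1))
  mmax <- max(params$margin_backbone, params$margin_base)
  slack <- if (params$hard_mode) 0 else sqrt(params$max_violation / params$k)
  edges <- list()
  pair_ok <- function(i, j) {
    if (prefilter) {
      bound <- spread[i] + spread[j] + mmax + slack
      if (sum((tails[i, ] - heads[j, ])^2) > bound^2) return(NULL)
    }
    e <- overlap_energy(structs[[i]], structs[[j]], params)
    thr <- if (params$hard_mode) 0 else params$max_violation
    if (e <= thr) c(i, j, e) else NULL
  }
  if (mode == "position_specific" && npool > 1) {
    for (p in seq_len(npool - 1L)) {
      for (i in which(pool_of == p)) {
        for (j in which(pool_of == p + 1L)) {
          r <- pair_ok(i, j)
          if (!is.null(r)) edges[[length(edges) + 1L]] <- r
        }
      }
    }
  } else {
    for (i in seq_len(nn)) {
      for (j in seq_len(nn)) {
        if (i == j) next
        r <- pair_ok(i, j)
        if (!is.null(r)) edges[[length(edges) + 1L]] <- r
      }
    }
  }
  ed <- if (length(edges)) {
    m <- do.call(rbind, edges)
    data.frame(from = as.integer(m[, 1]), to = as.integer(m[, 2]),
               energy = m[, 3])
  } else data.frame(from = integer(), to = integer(), energy = numeric())
  structure(list(node_id = node_id, pool_of = pool_of, edges = ed,
                 n_pools = npool, mode = if (npool > 1) "position_specific"
                 else "single_pool"),
            class = "chain_graph")
}

#' @export
print.chain_graph <- function(x, ...) {
  cat(sprintf("chain_graph (%s): %d nodes, %d edges\n", x$mode,
              length(x$node_id), nrow(x$edges)))
  invisible(x)
}

graph_adjacency <- function(graph) {
  n <- length(graph$node_id)
  Matrix::sparseMatrix(i = graph$edges$from, j = graph$edges$to,
                       x = 1, dims = c(n, n))
}

#' Count chains through every pose by forward-backward path counting
#'
#' Dynamic programming over the pose graph: the forward pass counts, for
#' every pose, the walks of each length ending there; the backward pass the
#' walks starting there; their products, summed over the position the pose
#' occupies, give the number of length-N chains each pose participates in
#' (each chain counted once per occupied position). In position-specific
#' mode chains run from pool 1 to pool N and are automatically simple; in
#' single-pool mode the counts are over walks, which may revisit a pose
#' (the enumeration, by contrast, reports only repeat-free chains).
#'
#' @param graph a \code{chain_graph}.
#' @param N chain length in fragments (>= 2). In position-specific mode it
#'   must equal the number of pools.
#' @return object of class \code{chain_count_result}: \code{N},
#'   \code{total_chains} (T), \code{counts} (c_v, named by node),
#'   \code{propensity} (c_v / T; zero when T = 0).
#' @export
count_chains <- function(graph, N) {
  if (N < 2) stop("chain length N must be >= 2")
  n <- length(graph$node_id)
  A <- graph_adjacency(graph)
  pos_spec <- graph$mode == "position_specific"
  if (pos_spec && N != graph$n_pools) {
    stop("position-specific counting requires N == number of pools (",
         graph$n_pools, ")")
  }
  f <- matrix(0, n, N)  # f[v,k]: walks of k nodes ending at v
  b <- matrix(0, n, N)  # b[v,k]: walks of k nodes starting at v
  f[, 1] <- if (pos_spec) as.numeric(graph$pool_of == 1L) else 1
  b[, 1] <- if (pos_spec) as.numeric(graph$pool_of == graph$n_pools) else 1
  for (k in 2:N) {
    f[, k] <- as.numeric(Matrix::crossprod(A, f[, k - 1]))
    b[, k] <- as.numeric(A %*% b[, k - 1])
  }
  total <- sum(f[, N])
  counts <- rowSums(f * b[, N:1, drop = FALSE])
  names(counts) <- graph$node_id
  structure(list(N = N, total_chains = total, counts = counts,
                 propensity = if (total > 0) counts / total
                 else stats::setNames(rep(0, n), graph$node_id)),
            class = "chain_count_result")
}

#' Filter poses by chain-forming propensity
#'
#' Keeps a pose iff it participates in at least \code{threshold} of all
#' length-N chains (published default: one out of 10,000). When no chains
#' form at all, returns an empty pool with a message.
#'
#' @param pool a \code{docking_pool} (or list of pools in
#'   position-specific mode).
#' @param counts a \code{chain_count_result} for the matching graph.
#' @param graph the \code{chain_graph} the counts were computed on.
#' @param threshold minimum fraction of total chains (default 1e-4).
#' @return the filtered pool (or list of pools); docking ranks are
#'   preserved.
#' @export
propensity_filter <- function(pool, counts, graph, threshold = 1e-4) {
  keep_node <- counts$counts >= threshold * counts$total_chains &
    counts$counts > 0
  if (counts$total_chains == 0) {
    message("no chains formed; all poses removed")
    keep_node[] <- FALSE
  }
  single <- inherits(pool, "docking_pool")
  pools <- if (single) list(pool) else pool
  out <- vector("list", length(pools))
  for (p in seq_along(pools)) {
    ids <- pools[[p]]$poses$pose_id
    node <- if (graph$mode == "position_specific" && graph$n_pools > 1 &&
                any(paste0("p", p, ":", ids) %in% graph$node_id)) {
      paste0("p", p, ":", ids)
    } else ids
    sel <- keep_node[match(node, graph$node_id)]
    sel[is.na(sel)] <- FALSE
    q <- pools[[p]]$poses[sel, , drop = FALSE]
    rownames(q) <- NULL
    out[[p]] <- docking_pool(q[order(q$energy), , drop = FALSE],
                             pools[[p]]$conformers,
                             c(pools[[p]]$provenance,
                               sprintf("propensity filter %.2g: %d/%d kept",
                                       threshold, nrow(q), length(ids))))
  }
  if (single) out[[1]] else out
}

#' Enumerate all length-N chains
#'
#' Depth-first enumeration in deterministic (lexicographic by node id)
#' order. In single-pool mode, walks that revisit a pose are dropped from
#' the report (their number is attached as the \code{dropped_repeats}
#' attribute); the DP counts in \code{\link{count_chains}} include them.
#'
#' @param graph a \code{chain_graph}.
#' @param N chain length (position-specific mode: must equal pool count).
#' @param cap refuse to enumerate when the DP chain total exceeds this.
#' @return list of chains; each chain is a list with \code{pose_ids}
#'   (length N) and \code{junction_energies} (length N-1, kcal/mol).
#' @export
enumerate_chains <- function(graph, N, cap = 1e6) {
  cc <- count_chains(graph, N)
  if (cc$total_chains > cap) {
    stop("chain count ", cc$total_chains, " exceeds cap ", cap,
         "; apply propensity_filter first")
  }
  n <- length(graph$node_id)
  adj <- vector("list", n)
  eng <- vector("list", n)
  ord <- order(graph$node_id)
  lexrank <- integer(n)
  lexrank[ord] <- seq_len(n)
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges$from[r]
    adj[[i]] <- c(adj[[i]], graph$edges$to[r])
    eng[[i]] <- c(eng[[i]], graph$edges$energy[r])
  }
  for (i in seq_len(n)) {
    if (length(adj[[i]]) > 1) {
      o <- order(lexrank[adj[[i]]])
      adj[[i]] <- adj[[i]][o]
      eng[[i]] <- eng[[i]][o]
    }
  }
  pos_spec <- graph$mode == "position_specific"
  starts <- if (pos_spec) which(graph$pool_of == 1L) else seq_len(n)
  starts <- starts[order(lexrank[starts])]
  chains <- list()
  dropped <- 0L
  path <- integer(N)
  junc <- numeric(max(N - 1, 0))
  dfs <- function(v, depth) {
    path[depth] <<- v
    if (depth == N) {
      if (anyDuplicated(path)) {
        dropped <<- dropped + 1L
      } else {
        chains[[length(chains) + 1L]] <<- list(
          pose_ids = graph$node_id[path],
          junction_energies = junc[seq_len(N - 1)])
      }
      return()
    }
    nb <- adj[[v]]
    for (t in seq_along(nb)) {
      junc[depth] <<- eng[[v]][t]
      dfs(nb[t], depth + 1L)
    }
  }
  for (s in starts) dfs(s, 1L)
  if (dropped > 0) {
    message(dropped, " pose-repeating walk(s) dropped from enumeration")
  }
  attr(chains, "dropped_repeats") <- dropped
  chains
}

#' Iterative coarse-to-rich chain assembly
#'
#' Memory-bounded assembly for very large pools: the top fraction of the
#' rank-sorted pool is propensity-filtered; each later stage admits poses
#' from the next fraction that lie within \code{radius} (ligand-RMSD) of an
#' already-selected pose and re-filters the union. Published schedule:
#' 0.5\%, 1\%, 2\%, 5\% with a 5 A radius.
#'
#' @param pool a rank-sorted \code{docking_pool}.
#' @param schedule strictly increasing fractions.
#' @param radius Angstrom proximity for admission.
#' @param params an \code{overlap_params}.
#' @param N chain length for the propensity filter.
#' @param threshold propensity threshold.
#' @return the final filtered \code{docking_pool}; the per-stage audit log
#'   is attached as attribute \code{"stages"}.
#' @export
iterative_assembly <- function(pool, schedule = c(0.005, 0.01, 0.02, 0.05),
                               radius = 5, params = overlap_params(),
                               N = 5, threshold = 1e-4) {
  stopifnot(length(schedule) >= 1, all(diff(schedule) > 0))
  ntot <- nrow(pool$poses)
  filter_once <- function(p) {
    if (nrow(p$poses) == 0) return(p)
    g <- build_graph(p, params, mode = "single_pool")
    cc <- count_chains(g, N)
    propensity_filter(p, cc, g, threshold)
  }
  sub_pool <- function(idx) {
    q <- pool$poses[idx, , drop = FALSE]
    rownames(q) <- NULL
    docking_pool(q[order(q$energy), , drop = FALSE], pool$conformers)
  }
  stages <- list()
  k1 <- ceiling(schedule[1] * ntot)
  selected <- filter_once(sub_pool(seq_len(min(k1, ntot))))
  proximity_on <- nrow(selected$poses) > 0
  if (!proximity_on) {
    warning("first stage empty after filtering; proximity seeding disabled")
  }
  stages[[1]] <- c(fraction = schedule[1], candidates = min(k1, ntot),
                   selected = nrow(selected$poses))
  for (s in seq_along(schedule)[-1]) {
    ks <- min(ceiling(schedule[s] * ntot), ntot)
    cand_idx <- setdiff(seq_len(ks),
                        match(selected$poses$pose_id, pool$poses$pose_id))
    if (length(cand_idx) > 0 && proximity_on && nrow(selected$poses) > 0) {
      cand_coords <- pose_coord_matrix(pool, cand_idx)
      sel_coords <- pose_coord_matrix(selected)
      d <- pose_rmsd_matrix_cpp(cand_coords, sel_coords)
      admit <- cand_idx[apply(d, 1, min) <= radius]
    } else if (!proximity_on) {
      admit <- cand_idx
    } else {
      admit <- integer()
    }
    union_idx <- sort(unique(c(match(selected$poses$pose_id,
                                     pool$poses$pose_id), admit)))
    selected <- filter_once(sub_pool(union_idx))
    if (nrow(selected$poses) > 0) proximity_on <- TRUE
    stages[[s]] <- c(fraction = schedule[s], candidates = length(cand_idx),
                     admitted = length(admit),
                     selected = nrow(selected$poses))
  }
  attr(selected, "stages") <- stages
  selected
}

#' Write a chain table
#'
#' Tab-separated: chain_id, pose_id_1..pose_id_N, junction energies
#' (kcal/mol) and their total.
#'
#' @param chains list of chains from \code{\link{enumerate_chains}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_chain_table <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# rnafragdock chain table; junction energies kcal/mol", con)
  if (length(chains) == 0) {
    writeLines("chain_id", con)
    return(invisible(path))
  }
  N <- length(chains[[1]]$pose_ids)
  hdr <- c("chain_id", paste0("pose_id_", seq_len(N)),
           paste0("junction_", seq_len(N - 1)), "total_overlap")
  writeLines(paste(hdr, collapse = "\t"), con)
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    writeLines(paste(c(i, ch$pose_ids, sprintf("%.6g", ch$junction_energies),
                       sprintf("%.6g", sum(ch$junction_energies))),
                     collapse = "\t"), con)
  }
  invisible(path)
}
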