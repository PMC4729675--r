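#' Hit classification thresholds
#'
#' Poses with ligand-RMSD strictly below 2 / 5 / 6 Angstrom from a
#' reference fragment count as hits / near-hits / close-hits.
#'
#' @param hit,near_hit,close_hit Angstrom; must be strictly increasing.
#' @return object of class \code{hit_thresholds}.
#' @export
hit_thresholds <- function(hit = 2, near_hit = 5, close_hit = 6) {
  stopifnot(hit < near_hit, near_hit < close_hit)
  structure(list(hit = hit, near_hit = near_hit, close_hit = close_hit),
            class = "hit_thresholds")
}

#' Ligand-RMSD of a pose against a reference
#'
#' Root-mean-square deviation over coarse-grained beads with no
#' re-superposition: both structures are taken in the fixed receptor frame.
#'
#' @param pose placed \code{cg_structure} (or a \code{docking_pool} plus a
#'   row index via \code{\link{pose_structure}}).
#' @param reference reference \code{cg_structure} with matching bead roles.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(pose, reference) {
  if (n_beads(pose) != n_beads(reference)) {
    stop("bead count mismatch: ", n_beads(pose), " vs ", n_beads(reference))
  }
  if (!all(pose$role == reference$role)) stop("bead roles do not match")
  fixed_rmsd(pose, reference)
}

#' Classify poses against reference fragments
#'
#' Computes every pose's ligand-RMSD to every reference fragment and
#' tabulates, per reference, the minimum RMSD and the number of poses
#' strictly below each threshold; the pooled per-pose minimum over all
#' references (the "closest bound fragment" convention) is attached.
#'
#' @param pool a \code{docking_pool}.
#' @param references list of reference \code{cg_structure} fragments.
#' @param thresholds a \code{hit_thresholds}.
#' @return data.frame with one row per reference (hits, near_hits,
#'   close_hits, total, min_rmsd); the poses x references RMSD matrix is
#'   attached as attribute \code{"rmsd"} and the per-pose minimum as
#'   \code{"min_rmsd_per_pose"}.
#' @export
classify_hits <- function(pool, references, thresholds = hit_thresholds()) {
  if (length(references) == 0) stop("references must be non-empty")
  coords <- pose_coord_matrix(pool)
  refmat <- do.call(rbind, lapply(references, function(r)
    as.numeric(t(r$pos))))
  if (ncol(refmat) != ncol(coords)) {
    stop("reference bead count does not match pool conformers")
  }
  rmsd <- pose_rmsd_matrix_cpp(coords, refmat)
  out <- data.frame(
    reference = seq_along(references),
    hits = colSums(rmsd < thresholds$hit),
    near_hits = colSums(rmsd < thresholds$near_hit),
    close_hits = colSums(rmsd < thresholds$close_hit),
    total = nrow(rmsd),
    min_rmsd = apply(rmsd, 2, min))
  attr(out, "rmsd") <- rmsd
  attr(out, "min_rmsd_per_pose") <- apply(rmsd, 1, min)
  out
}

#' Geometric-mean chain RMSD
#'
#' The RMSD of an assembled chain is the geometric mean of the per-position
#' ligand-RMSDs of its poses against the reference fragments. Any exact
#' zero per-position RMSD makes the geometric mean zero.
#'
#' @param chain a chain (list with \code{pose_ids}) from
#'   \code{\link{enumerate_chains}}, or a numeric vector of per-position
#'   RMSDs.
#' @param references list of reference \code{cg_structure}, one per chain
#'   position (ignored when \code{chain} is numeric).
#' @param pool the \code{docking_pool} holding the chain's poses.
#' @return geometric-mean RMSD, Angstrom.
#' @export
chain_rmsd <- function(chain, references = NULL, pool = NULL) {
  vals <- if (is.numeric(chain)) {
    chain
  } else {
    ids <- chain$pose_ids
    if (length(ids) != length(references)) {
      stop("chain length ", length(ids), " does not match ",
           length(references), " references")
    }
    vapply(seq_along(ids), function(k)
      ligand_rmsd(pose_structure(pool, ids[k]), references[[k]]),
      numeric(1))
  }
  if (any(vals == 0)) return(0)
  exp(mean(log(vals)))
}

#' Score poses by chain propensity and docking rank
#'
#' \eqn{S_{poses} = \ln(\mathrm{propensity}) / \mathrm{rank}} with the
#' propensity as a fraction in (0, 1] and the 1-based force-field rank.
#' Larger is better (a less negative log over a better rank); poses with
#' zero propensity are excluded.
#'
#' @param pool a \code{docking_pool} whose \code{rank} column holds the
#'   force-field ranks.
#' @param counts a \code{chain_count_result} over (at least) the pool's
#'   poses, matched by pose id.
#' @return data.frame (pose_id, propensity, rank, s_poses) sorted by
#'   decreasing score.
#' @export
score_poses <- function(pool, counts) {
  p <- pool$poses
  prop <- counts$propensity[match(p$pose_id, names(counts$propensity))]
  keep <- !is.na(prop) & prop > 0
  out <- data.frame(pose_id = p$pose_id[keep],
                    propensity = as.numeric(prop[keep]),
                    rank = p$rank[keep])
  out$s_poses <- log(out$propensity) / out$rank
  out <- out[order(-out$s_poses), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score chains by junction overlap and member ranks
#'
#' Default ("product") reading:
#' \eqn{S_{chains} = [\sum_i \mathrm{Overlap}(pose_i, pose_{i+1})] \cdot
#' [\sum_{poses} \mathrm{rank}^2] / N}, smaller is better (both factors are
#' penalties). The alternate "ratio" reading divides by the rank term
#' instead: \eqn{S = \sum \mathrm{Overlap} \cdot N / \sum \mathrm{rank}^2}.
#' The chosen reading is recorded in the result.
#'
#' @param chains list of chains from \code{\link{enumerate_chains}}.
#' @param pool the \code{docking_pool} with the members' ranks.
#' @param mode \code{"product"} (default) or \code{"ratio"}.
#' @return data.frame (chain_id, total_overlap, rank_term, s_chains)
#'   sorted by increasing score, with attribute \code{"mode"}.
#' @export
score_chains <- function(chains, pool, mode = c("product", "ratio")) {
  mode <- match.arg(mode)
  if (length(chains) == 0) {
    out <- data.frame(chain_id = integer(), total_overlap = numeric(),
                      rank_term = numeric(), s_chains = numeric())
    attr(out, "mode") <- mode
    return(out)
  }
  N <- length(chains[[1]]$pose_ids)
  ranks <- stats::setNames(pool$poses$rank, pool$poses$pose_id)
  ov <- vapply(chains, function(ch) sum(ch$junction_energies), numeric(1))
  rk <- vapply(chains, function(ch)
    sum(ranks[ch$pose_ids]^2), numeric(1))
  s <- if (mode == "product") ov * rk / N else ov * N / rk
  out <- data.frame(chain_id = seq_along(chains), total_overlap = ov,
                    rank_term = rk, s_chains = s)
  out <- out[order(out$s_chains), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  out
}

#' Binding-site delineation statistics
#'
#' For each pose, the ligand-RMSD to the closest reference fragment; the
#' summary gives the fraction of poses strictly under each cutoff and the
#' worst (maximum) distance.
#'
#' @param pool a \code{docking_pool}.
#' @param references list of reference \code{cg_structure} fragments.
#' @param cutoffs Angstrom (published summary: 10 and 15).
#' @return list with \code{fractions} (named by cutoff), \code{max}
#'   (Angstrom) and the per-pose distances as \code{distances}.
#' @export
binding_site_stats <- function(pool, references, cutoffs = c(10, 15)) {
  cls <- classify_hits(pool, references)
  d <- attr(cls, "min_rmsd_per_pose")
  fr <- vapply(cutoffs, function(co) mean(d < co), numeric(1))
  names(fr) <- as.character(cutoffs)
  list(fractions = fr, max = if (length(d)) max(d) else NA_real_,
       distances = d)
}

#' Pearson correlation between library fit quality and docking accuracy
#'
#' Sample Pearson correlation of (best-fitting-conformer RMSD, minimum
#' docked RMSD) pairs, with the two-sided t-test p-value on n-2 degrees of
#' freedom.
#'
#' @param pairs data.frame or 2-column matrix: best-fit RMSD, min docked
#'   RMSD (>= 3 rows).
#' @return list with \code{r}, \code{p_value}, \code{n}.
#' @export
fit_vs_dock_correlation <- function(pairs) {
  m <- as.matrix(pairs)
  if (nrow(m) < 3) stop("need at least 3 pairs")
  if (stats::sd(m[, 1]) == 0 || stats::sd(m[, 2]) == 0) {
    stop("zero variance in one coordinate; correlation undefined")
  }
  r <- stats::cor(m[, 1], m[, 2])
  n <- nrow(m)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(tt), n - 2), n = n)
}

#' Hypergeometric enrichment of hits among top-ranked poses
#'
#' Exact upper-tail probability \eqn{P(X \ge x)} of finding at least
#' \code{hits_in_top} hits when drawing \code{top_n} poses from a pool of
#' \code{pool_size} containing \code{hits_total} hits.
#'
#' @param top_n number of top-ranked poses considered.
#' @param pool_size total pool size.
#' @param hits_in_top hits observed among the top \code{top_n}.
#' @param hits_total hits in the whole pool.
#' @return tail probability.
#' @export
enrichment <- function(top_n, pool_size, hits_in_top, hits_total) {
  if (hits_total > pool_size || hits_in_top > min(top_n, hits_total) ||
      top_n > pool_size || any(c(top_n, pool_size, hits_in_top,
                                 hits_total) < 0)) {
    stop("inconsistent counts")
  }
  xs <- hits_in_top:min(top_n, hits_total)
  sum(stats::dhyper(xs, hits_total, pool_size - hits_total, top_n))
}

#' Full evaluation report for a pose pool and optional chains
#'
#' @param pool a \code{docking_pool}.
#' @param references list of reference fragments.
#' @param chains optional chain list.
#' @param thresholds a \code{hit_thresholds}.
#' @param site_cutoffs binding-site cutoffs, Angstrom.
#' @return list of class \code{evaluation_report} with \code{hits},
#'   \code{binding_site} and (when chains are given) \code{chain_rmsds}
#'   plus \code{best_chain_rmsd}.
#' @export
evaluate_pool <- function(pool, references, chains = NULL,
                          thresholds = hit_thresholds(),
                          site_cutoffs = c(10, 15)) {
  hits <- classify_hits(pool, references, thresholds)
  site <- binding_site_stats(pool, references, site_cutoffs)
  out <- list(hits = hits, binding_site = site)
  if (!is.null(chains) && length(chains) > 0) {
    rmsd_mat <- attr(hits, "rmsd")
    ids <- pool$poses$pose_id
    N <- length(chains[[1]]$pose_ids)
    nref <- length(references)
    if (N > nref) stop("chains longer than the reference fragment set")
    # a chain may start at any reference position; score it against every
    # contiguous reference window and keep the best alignment
    crmsd <- vapply(chains, function(ch) {
      rows <- match(ch$pose_ids, ids)
      min(vapply(seq_len(nref - N + 1L), function(s) {
        vals <- rmsd_mat[cbind(rows, s:(s + N - 1L))]
        if (any(vals == 0)) 0 else exp(mean(log(vals)))
      }, numeric(1)))
    }, numeric(1))
    out$chain_rmsds <- crmsd
    out$best_chain_rmsd <- min(crmsd)
  }
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report\n")
  cat("  per-reference hits/near-hits/close-hits (of",
      x$hits$total[1], "poses):\n")
  for (i in seq_len(nrow(x$hits))) {
    cat(sprintf("    ref%-2d %4d %4d %4d  min RMSD %.2f A\n", i,
                x$hits$hits[i], x$hits$near_hits[i], x$hits$close_hits[i],
                x$hits$min_rmsd[i]))
  }
  cat(sprintf("  binding site: %s; worst pose %.1f A\n",
              paste(sprintf("%.0f%%<%s A", 100 * x$binding_site$fractions,
                            names(x$binding_site$fractions)),
                    collapse = ", "), x$binding_site$max))
  if (!is.null(x$chain_rmsds)) {
    cat(sprintf("  chains: %d, best geometric-mean RMSD %.2f A\n",
                length(x$chain_rmsds), x$best_chain_rmsd))
  }
  invisible(x)
}
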