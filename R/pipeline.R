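#' Default pipeline configuration
#'
#' All stage parameters with their published defaults: 30,000 starts on a
#' 75 A sphere, a 0.0015 kcal/mol/A^2 COM restraint, 1000 minimization
#' steps, 0.05 A pose dedup, top-20% selection, 2.3/2.8 A overlap margins
#' with k = 100 kcal/mol/A^2 and a 2 kcal/mol violation budget, a 1/10,000
#' chain-propensity threshold and 5-fragment chains. The toy-scale
#' overrides used by the test suite shrink only the start count and sphere.
#'
#' @param ... name = value overrides of the defaults.
#' @return named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    nstarts = 30000L,
    start_radius = 75,
    steps = 1000L,
    dedup_tol = 0.05,
    top_fraction = 0.2,
    use_grid = TRUE,
    grid_spacing = 1.0,
    grid_padding = 10,
    margin_backbone = 2.3,
    margin_base = 2.8,
    overlap_k = 100,
    max_violation = 2,
    chain_length = 5L,
    propensity_threshold = 1e-4,
    chain_cap = 1e6,
    cluster = FALSE,
    cluster_radius = 3,
    loose_margin = 5,
    include_decoy_poses = TRUE,
    include_planted_poses = TRUE,
    use_decoy_conformers = FALSE,
    eval_thresholds = c(2, 5, 6),
    site_cutoffs = c(10, 15))
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config option(s): ", paste(bad, collapse = ", "))
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  stopifnot(cfg$nstarts >= 1, cfg$top_fraction > 0, cfg$top_fraction <= 1,
            cfg$chain_length >= 2, cfg$propensity_threshold >= 0,
            cfg$max_violation >= 0, cfg$dedup_tol >= 0)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the five-step fragment docking pipeline on a scenario
#'
#' Executes (i) fragment/library selection, (ii) ensemble docking,
#' (iii) top-fraction scoring, (iv) chain-propensity filtering and
#' (v) optional clustering plus chain building, then evaluates against the
#' scenario's ground-truth fragments. Every stage logs its in/out counts;
#' a stage that empties the pose set halts the pipeline with the stage
#' named.
#'
#' @param scenario a \code{toy_scenario} from \code{\link{make_scenario}}.
#' @param config a \code{pipeline_config}.
#' @return list of class \code{pipeline_result}: \code{docked},
#'   \code{top}, \code{pool} (assembly input), \code{filtered},
#'   \code{graph}, \code{counts}, \code{chains}, \code{report},
#'   \code{stage_log}, \code{config}.
#' @export
run_pipeline <- function(scenario, config = pipeline_config()) {
  stopifnot(inherits(scenario, "toy_scenario"),
            inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, n_in = n_in,
                                           n_out = n_out)
    if (n_out == 0) stop("pipeline halted: stage '", stage,
                         "' produced an empty set")
  }

  confs <- scenario$conformers
  if (config$use_decoy_conformers) {
    extra <- Filter(function(f) f$source_id == "decoy",
                    scenario$library$classes$UUU)
    for (i in seq_along(extra)) {
      confs[[paste0("decoy_conf", i)]] <- extra[[i]]$conformer
    }
  }
  note("library", length(scenario$library$classes$UUU), length(confs))

  docked <- dock(scenario$receptor, confs, scenario$ff,
                 nstarts = config$nstarts, seed = config$seed,
                 radius = config$start_radius, steps = config$steps,
                 use_grid = config$use_grid, spacing = config$grid_spacing,
                 padding = config$grid_padding,
                 dedup_tol = config$dedup_tol)
  note("docking", config$nstarts * length(confs), nrow(docked$poses))

  top <- select_top(docked, config$top_fraction)
  note("top_fraction", nrow(docked$poses), nrow(top$poses))

  pool <- top
  if (config$include_planted_poses || config$include_decoy_poses) {
    extra <- scenario$pool
    keep <- rep(TRUE, nrow(extra$poses))
    if (!config$include_planted_poses) {
      keep <- keep & !startsWith(extra$poses$pose_id, "planted")
    }
    if (!config$include_decoy_poses) {
      keep <- keep & !startsWith(extra$poses$pose_id, "decoy")
    }
    q <- extra$poses[keep, , drop = FALSE]
    rownames(q) <- NULL
    extra <- docking_pool(q[order(q$energy), , drop = FALSE],
                          extra$conformers)
    pool <- merge_pools(list(top, extra))
  }
  note("assembly_pool", nrow(top$poses), nrow(pool$poses))

  params <- overlap_params(config$margin_backbone, config$margin_base,
                           config$overlap_k, config$max_violation)
  graph <- build_graph(pool, params, mode = "single_pool")
  counts <- count_chains(graph, config$chain_length)
  filtered <- propensity_filter(pool, counts, graph,
                                config$propensity_threshold)
  note("propensity_filter", nrow(pool$poses), nrow(filtered$poses))

  if (config$cluster) {
    asm <- assemble_clustered(filtered, config$cluster_radius,
                              config$loose_margin, hard_mode = TRUE,
                              N = config$chain_length,
                              threshold = config$propensity_threshold,
                              cap = config$chain_cap)
    chains <- asm$chains
    chain_pool <- asm$pool
  } else {
    fgraph <- build_graph(filtered, params, mode = "single_pool")
    fcounts <- count_chains(fgraph, config$chain_length)
    chains <- if (fcounts$total_chains > 0 &&
                  fcounts$total_chains <= config$chain_cap) {
      enumerate_chains(fgraph, config$chain_length, config$chain_cap)
    } else list()
    chain_pool <- filtered
  }
  note("chains", nrow(filtered$poses), max(length(chains), 1L))

  thr <- hit_thresholds(config$eval_thresholds[1], config$eval_thresholds[2],
                        config$eval_thresholds[3])
  report <- evaluate_pool(chain_pool, unname(scenario$fragments),
                          chains = chains, thresholds = thr,
                          site_cutoffs = config$site_cutoffs)
  structure(list(docked = docked, top = top, pool = pool,
                 filtered = filtered, graph = graph, counts = counts,
                 chains = chains, chain_pool = chain_pool, report = report,
                 stage_log = do.call(rbind, log), config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(x$stage_log, row.names = FALSE)
  cat(sprintf("  chains: %d\n", length(x$chains)))
  if (!is.null(x$report$best_chain_rmsd)) {
    cat(sprintf("  best chain geometric-mean RMSD: %.2f A\n",
                x$report$best_chain_rmsd))
  }
  invisible(x)
}
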