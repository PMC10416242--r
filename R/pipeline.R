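# End-to-end pipeline: relabel -> filter -> aggregate -> infer ->
# bootstrap-filter -> hubs -> degradation, per requested rank, with all
# artifacts and a run manifest written to disk.

#' Default pipeline configuration
#'
#' Reference defaults mirror full-scale analyses (bootstrap B = 5000, alpha
#' = 0.05, 100 null replicates, top 20 hubs); [demo_config()] scales them
#' down for quick smoke runs.
#'
#' @param seed Master seed; all stage seeds are derived from it by counter.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthetic = list(n_samples = 200L, n_taxa = 40L, graph_model = "band",
                     edge_density = 0.1, condition_target = 10,
                     depth_range = c(2000L, 10000L),
                     mdm_fraction_by_rank = c(0.03, 0.06, 0.15, 0.30, 0.45, 0.70, 0.97)),
    input = NULL,  # list(abundance = path, taxonomy = path) overrides synthetic
    filter = list(min_samples = 2L, exclude_domains = "Eukaryota",
                  chloroplast_ranks = c("order", "family", "genus")),
    ranks = c("phylum", "class"),
    network = list(pseudocount = 1, path_length = 20L, min_ratio = 0.01,
                   n_subsamples = 20L, subsample_ratio = NULL,
                   threshold = 0.05, rule = "OR"),
    bootstrap = list(B = 5000L, alpha = 0.05, reuse_penalty = TRUE),
    degradation = list(n_reps = 100L),
    hubs = list(k = 20L)
  )
}

#' Scaled-down demo configuration
#'
#' @inheritParams default_config
#' @return Configuration list with a small synthetic community, B = 200
#'   bootstrap replicates and 25 null replicates.
#' @export
demo_config <- function(seed = 1L) {
  cfg <- default_config(seed)
  cfg$synthetic$n_samples <- 60L
  cfg$synthetic$n_taxa <- 20L
  cfg$bootstrap$B <- 200L
  cfg$degradation$n_reps <- 25L
  cfg
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run the full analysis pipeline
#'
#' Executes, for each requested rank: MDM relabeling, taxon filtering,
#' aggregation, network inference, the permutation edge bootstrap, edge
#' filtering, hub scoring and the degradation analysis; writes networks,
#' supports, hub tables, reports and a JSON run manifest under `out_dir`.
#' With a `synthetic` config block the input community is generated in
#' silico (and the ground-truth edges written alongside); an `input` block
#' with `abundance`/`taxonomy` paths analyses real tables instead.
#'
#' @param config Configuration list (see [default_config()]) or path to a
#'   YAML file with the same structure; partial configs are completed with
#'   defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the per-rank results and the manifest.
#' @examples
#' \donttest{
#' res <- run_pipeline(demo_config(seed = 1), out_dir = tempfile())
#' names(res$ranks)
#' }
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- input ---------------------------------------------------------------
  if (!is.null(cfg$input)) {
    abundance <- stage("read_abundance", read_abundance(cfg$input$abundance))
    taxonomy <- stage("read_taxonomy", read_taxonomy(cfg$input$taxonomy))
    truth <- NULL
  } else {
    seeds$synthetic <- child_seed(cfg$seed, 1)
    s <- cfg$synthetic
    comm <- stage("simulate",
                  sim_community(s$n_samples, s$n_taxa, s$graph_model,
                                s$edge_density, s$condition_target,
                                s$depth_range, s$mdm_fraction_by_rank,
                                seed = seeds$synthetic))
    abundance <- comm$abundance
    taxonomy <- comm$taxonomy
    truth <- comm$truth
  }

  # --- relabel + filter ----------------------------------------------------
  taxonomy <- stage("relabel", relabel_mdm(taxonomy))
  fcfg <- filter_config(cfg$filter$min_samples, cfg$filter$exclude_domains,
                        cfg$filter$chloroplast_ranks)
  abundance <- stage("filter", filter_taxa(abundance, taxonomy, fcfg))

  write_abundance(abundance, file.path(out_dir, "abundance_filtered.tsv"))
  write_taxonomy(taxonomy, file.path(out_dir, "taxonomy_mdm.tsv"))
  readr::write_tsv(filter_report(abundance),
                   file.path(out_dir, "filter_report.tsv"), progress = FALSE)
  if (!is.null(truth)) {
    readr::write_tsv(truth$true_edges, file.path(out_dir, "truth_edges.tsv"),
                     progress = FALSE)
  }

  # --- per-rank analysis ---------------------------------------------------
  ncfg <- cfg$network
  rank_results <- list()
  for (k in seq_along(cfg$ranks)) {
    rank <- cfg$ranks[k]
    rdir <- file.path(out_dir, rank)
    dir.create(rdir, showWarnings = FALSE)

    agg <- stage("aggregate", aggregate_to_rank(abundance, taxonomy, rank))
    seeds[[paste0("infer_", rank)]] <- child_seed(cfg$seed, 100 + k)
    clr <- clr_transform(agg$table, ncfg$pseudocount)
    net <- stage("infer",
                 infer_network(clr, clr = TRUE,
                               path = default_penalty_path(clr, ncfg$path_length,
                                                           ncfg$min_ratio),
                               rule = ncfg$rule, n_subsamples = ncfg$n_subsamples,
                               subsample_ratio = ncfg$subsample_ratio,
                               threshold = ncfg$threshold,
                               seed = seeds[[paste0("infer_", rank)]]))
    net$pseudocount <- ncfg$pseudocount
    write_network(net, file.path(rdir, "network_edges.tsv"),
                  graphml = file.path(rdir, "network.graphml"))
    if (!is.null(net$instability)) {
      readr::write_tsv(net$instability, file.path(rdir, "instability.tsv"),
                       progress = FALSE)
    }

    seeds[[paste0("bootstrap_", rank)]] <- child_seed(cfg$seed, 200 + k)
    supports <- stage("bootstrap",
                      bootstrap_edge_support(agg$table, net, B = cfg$bootstrap$B,
                                             alpha = cfg$bootstrap$alpha,
                                             reuse_penalty = cfg$bootstrap$reuse_penalty,
                                             seed = seeds[[paste0("bootstrap_", rank)]]))
    write_edge_support(supports, file.path(rdir, "edge_support.tsv"))
    filtered <- stage("filter_edges", filter_edges(net, supports))
    write_network(filtered, file.path(rdir, "network_filtered_edges.tsv"),
                  graphml = file.path(rdir, "network_filtered.graphml"))

    profile <- stage("hubs", centrality_profile(filtered))
    readr::write_tsv(profile, file.path(rdir, "centrality.tsv"), progress = FALSE)
    top <- top_hubs(profile, agg$lineage, k = cfg$hubs$k)
    readr::write_tsv(top, file.path(rdir, "top_hubs.tsv"), progress = FALSE)

    seeds[[paste0("degradation_", rank)]] <- child_seed(cfg$seed, 300 + k)
    mdm_nodes <- agg$lineage$node_id[agg$lineage$is_mdm]
    degr <- stage("degradation",
                  degradation_report(filtered, mdm_nodes,
                                     n_reps = cfg$degradation$n_reps,
                                     seed = seeds[[paste0("degradation_", rank)]]))
    readr::write_tsv(degr$metrics, file.path(rdir, "degradation_metrics.tsv"),
                     progress = FALSE)
    jsonlite::write_json(list(tests = degr$tests,
                              fragmentation = degr$fragmentation,
                              n_removed = degr$n_removed, n_reps = degr$n_reps),
                         file.path(rdir, "degradation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    rank_results[[rank]] <- list(network = net, supports = supports,
                                 filtered = filtered, profile = profile,
                                 top_hubs = top, degradation = degr,
                                 lineage = agg$lineage)
  }

  # --- manifest ------------------------------------------------------------
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    tool = "microdark",
    version = as.character(utils::packageVersion("microdark")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    config = cfg,
    seeds = seeds,
    digests = as.list(tools::md5sum(file.path(out_dir, files)) |>
                        setNames(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(abundance = abundance, taxonomy = taxonomy, truth = truth,
                 ranks = rank_results, manifest = manifest))
}
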