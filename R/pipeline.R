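#' Pipeline configuration
#'
#' Collects every stage threshold, the stage toggles and the seed into one
#' validated list. The defaults are the conventional values of the
#' screening and network workflow: OB ≥ 30 %, DL ≥ 0.18, Caco-2 ≥ −0.4,
#' at least 2 drug-likeness flags, DisGeNet score ≥ 0.3, GeneCards
#' relevance > 10, interaction confidence > 0.9, adjusted p < 0.05, top 20
#' pathways / top 10 ontology terms, core set size 10, affinity classes at
#' −5 / −7 kcal/mol, and the 0.2 nm / 5 ns stability rule.
#'
#' @param seed Integer seed driving every synthetic input.
#' @param spec A [synthetic_spec()]; defaults to `synthetic_spec(seed)`.
#' @param stages Character vector of stages to run, in dependency order
#'   among `"screen"`, `"targets"`, `"ppi"`, `"enrich"`, `"network"`,
#'   `"dock"`, `"md"`.
#' @param ob_min,dl_min,caco2_min,min_flags Compound screen thresholds.
#' @param disgenet_min,genecards_min Disease-target score filters.
#' @param string_min Strict interaction-confidence cutoff.
#' @param alpha,top_k_pathway,top_k_go Enrichment thresholds.
#' @param k_core Core components/targets kept by degree.
#' @param affinity_moderate,affinity_strong Affinity class boundaries
#'   (kcal/mol).
#' @param stability_threshold,stability_window Stability rule (nm, ns).
#' @return A list of class `herbnet_config`.
#' @export
herbnet_config <- function(seed = 101,
                           spec = synthetic_spec(seed = seed),
                           stages = c("screen", "targets", "ppi", "enrich",
                                      "network", "dock", "md"),
                           ob_min = 30, dl_min = 0.18, caco2_min = -0.4,
                           min_flags = 2,
                           disgenet_min = 0.3, genecards_min = 10,
                           string_min = 0.9,
                           alpha = 0.05, top_k_pathway = 20, top_k_go = 10,
                           k_core = 10,
                           affinity_moderate = -5, affinity_strong = -7,
                           stability_threshold = 0.2, stability_window = 5) {
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- list(seed = seed, spec = spec, stages = stages,
              ob_min = ob_min, dl_min = dl_min, caco2_min = caco2_min,
              min_flags = min_flags, disgenet_min = disgenet_min,
              genecards_min = genecards_min, string_min = string_min,
              alpha = alpha, top_k_pathway = top_k_pathway,
              top_k_go = top_k_go, k_core = k_core,
              affinity_moderate = affinity_moderate,
              affinity_strong = affinity_strong,
              stability_threshold = stability_threshold,
              stability_window = stability_window)
  check_number(cfg$alpha, "alpha", 0, 1)
  check_number(cfg$string_min, "string_min", 0, 1)
  structure(cfg, class = "herbnet_config")
}

stage_deps <- list(screen = character(0), targets = character(0),
                   ppi = "targets", enrich = c("targets", "ppi"),
                   network = c("screen", "targets", "ppi", "enrich"),
                   dock = character(0), md = character(0))

#' Run the synthetic end-to-end pipeline
#'
#' Executes the enabled stages in dependency order on inputs generated from
#' the configuration's synthetic spec: compound screening and merging;
#' target-set assembly and intersection; interaction-network construction
#' and six-centrality key-target selection; over-representation analysis of
#' the key targets; heterogeneous-network core ranking; docking
#' post-processing; and trajectory/energy post-processing. Each stage
#' writes its table under `dir`, and a JSON manifest records the seed,
#' parameters, stages and an MD5 hash of every output, so two runs with the
#' same seed produce identical manifests.
#'
#' @param config A [herbnet_config()].
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly, as a list; also written to
#'   `manifest.json` in `dir`. Stage results are attached in the
#'   `"results"` attribute.
#' @examples
#' \donttest{
#' cfg <- herbnet_config(seed = 1,
#'                       spec = synthetic_spec(seed = 1,
#'                                             n_compound_targets = 60,
#'                                             n_disease_targets = 50,
#'                                             planted_overlap = 25,
#'                                             graph_params = list(n = 25, p = 0.2)))
#' run_pipeline(cfg, dir = tempfile("herbnet"))
#' }
#' @export
run_pipeline <- function(config, dir = tempfile("herbnet_run")) {
  if (!inherits(config, "herbnet_config")) {
    abort("`config` must come from herbnet_config()")
  }
  for (st in config$stages) {
    need <- setdiff(stage_deps[[st]], config$stages)
    if (length(need) > 0) {
      abort(sprintf("stage '%s' requires disabled stage(s): %s",
                    st, paste(need, collapse = ", ")))
    }
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- config$spec
  results <- list()
  outputs <- character(0)
  save <- function(x, name) {
    path <- file.path(dir, name)
    readr::write_tsv(x, path)
    outputs[[name]] <<- path
    path
  }

  if ("screen" %in% config$stages) {
    raw <- sim_compound_table(spec)
    tcmsp_route <- raw |> filter(.data$source == "TCMSP")
    other_route <- raw |> filter(.data$source != "TCMSP")
    kept_tcmsp <- screen_tcmsp(tcmsp_route, config$ob_min, config$dl_min,
                               config$caco2_min)
    kept_other <- screen_swissadme(other_route, config$min_flags)
    compounds <- merge_compounds(kept_tcmsp, kept_other)
    results$compounds <- compounds
    save(compounds, "compounds.tsv")
  }

  if ("targets" %in% config$stages) {
    sets <- sim_target_sets(spec)
    overlap <- intersect_targets(sets$compound, sets$disease)
    results$target_sets <- sets
    results$overlap <- overlap
    save(tibble(gene = overlap$common$gene), "intersection_targets.tsv")
    venn_path <- file.path(dir, "venn.json")
    jsonlite::write_json(as.list(overlap$venn), venn_path, auto_unbox = TRUE)
    outputs[["venn.json"]] <- venn_path
  }

  if ("ppi" %in% config$stages) {
    genes <- results$overlap$common$gene
    spec_ppi <- spec
    spec_ppi$graph_params$n <- length(genes)
    g_true <- sim_ppi(spec_ppi, nodes = genes)
    string_tbl <- string_table_from_graph(g_true, spec$seed)
    save(string_tbl, "string_edges.tsv")
    g <- graph_from_string_edges(string_tbl, min_score = config$string_min,
                                 nodes = genes)
    centralities <- ppi_centralities(g)
    key_targets <- select_key_targets(centralities)
    results$graph <- g
    results$centralities <- centralities
    results$key_targets <- key_targets
    save(centralities, "centralities.tsv")
    save(tibble(gene = key_targets), "key_targets.tsv")
  }

  if ("enrich" %in% config$stages) {
    background <- union(results$target_sets$compound$gene,
                        results$target_sets$disease$gene)
    collection <- sim_annotations(spec, study = results$key_targets,
                                  background = background)
    ora <- run_ora(results$key_targets, collection, background = background,
                   alpha = config$alpha, top_k = config$top_k_pathway)
    results$collection <- collection
    results$ora <- ora
    flat <- as_tibble(ora) |>
      mutate(genes = map_chr(.data$genes, paste, collapse = ","))
    save(flat, "enrichment.tsv")
  }

  if ("network" %in% config$stages) {
    rel <- pipeline_relations(results)
    net <- build_hetero_network(rel)
    core_compounds <- rank_by_degree(net, "compound", config$k_core)
    core_targets <- rank_by_degree(net, "target", config$k_core)
    results$network <- net
    results$core_compounds <- core_compounds
    results$core_targets <- core_targets
    save(bind_rows(core_compounds, core_targets), "core_ranking.tsv")
    outputs[["network.sif"]] <- file.path(dir, "network.sif")
    write_sif(net, outputs[["network.sif"]])
  }

  if ("dock" %in% config$stages) {
    poses <- sim_docking_poses(spec)
    matrix <- best_pose(poses)
    best <- best_complex_table(matrix)
    results$affinity_matrix <- matrix
    results$best_complexes <- best
    save(matrix, "affinity_matrix.tsv")
    save(best, "best_complexes.tsv")
  }

  if ("md" %in% config$stages) {
    traj <- sim_trajectory(spec, label = "CPX01")
    stability <- assess_stability(traj,
                                  threshold = config$stability_threshold,
                                  window = config$stability_window)
    summary <- summarize_series(
      traj,
      from_time = if (isTRUE(stability$stable)) stability$equilibration_time else 0)
    energies <- mmpbsa_totals(sim_energy_table(spec))
    results$trajectory <- traj
    results$stability <- stability
    results$trajectory_summary <- summary
    results$energies <- energies
    save(energies, "mmpbsa.tsv")
    save(tidy(stability), "stability.tsv")
  }

  manifest <- list(
    seed = config$seed,
    stages = config$stages,
    parameters = config[setdiff(names(config), c("spec", "seed", "stages"))],
    spec = spec[c("n_compounds", "n_compound_targets", "n_disease_targets",
                  "planted_overlap", "graph_model", "n_terms")],
    outputs = lapply(sort(names(outputs)), function(n) {
      list(file = n, md5 = unname(tools::md5sum(outputs[[n]])))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(manifest, "results") <- results
  attr(manifest, "dir") <- dir
  invisible(manifest)
}

# Edge table in the STRING export shape: true edges get high confidence,
# decoy non-edges get sub-threshold scores, so the >0.9 filter recovers the
# planted graph exactly.
string_table_from_graph <- function(g, seed) {
  el <- igraph::as_edgelist(g)
  withr::with_seed(substream_seed(seed, "pipeline"), {
    n_decoy <- max(1L, nrow(el) %/% 5L)
    nodes <- igraph::V(g)$name
    decoys <- NULL
    if (length(nodes) >= 2) {
      from <- sample(nodes, n_decoy, replace = TRUE)
      to <- sample(nodes, n_decoy, replace = TRUE)
      ok <- from != to
      decoys <- tibble(node1 = from[ok], node2 = to[ok],
                       combined_score = round(runif(sum(ok), 0.3, 0.9), 3))
    }
    real <- tibble(node1 = el[, 1], node2 = el[, 2],
                   combined_score = round(runif(nrow(el), 0.905, 0.999), 3))
    bind_rows(real, decoys)
  })
}

# Relation tables feeding the heterogeneous network: compounds link to key
# targets, key targets to their enriched pathways/functions, the disease to
# every intersection target.
pipeline_relations <- function(results) {
  key <- results$key_targets
  compounds <- results$compounds$name
  # deterministic compound-target links: compound i covers every 3rd target
  ct <- bind_rows(imap(compounds, function(cmp, i) {
    idx <- seq(((i - 1) %% 3) + 1, length(key), by = 3)
    tibble(from = cmp, from_type = "compound", to = key[idx],
           to_type = "target")
  }))
  ora <- results$ora
  pt <- NULL
  if (nrow(ora) > 0) {
    type_of <- c(KEGG = "pathway", BP = "function_BP", CC = "function_CC",
                 MF = "function_MF")
    pt <- bind_rows(purrr::pmap(
      list(ora$term_id, ora$category, ora$genes),
      function(id, cat, genes) {
        tibble(from = id, from_type = unname(type_of[cat]), to = genes,
               to_type = "target")
      }))
  }
  dt <- tibble(from = "disease", from_type = "disease",
               to = results$overlap$common$gene, to_type = "target")
  bind_rows(ct, pt, dt)
}
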