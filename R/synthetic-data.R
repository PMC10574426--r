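#' Generate a synthetic compound/ADME property table
#'
#' Draws `n_compounds` compound records (duplicates included) whose ADME
#' properties are sampled so that a configurable fraction passes each of the
#' two screening routes: records drawn to pass the TCMSP-style screen get
#' OB ≥ 30, DL ≥ 0.18 and Caco-2 ≥ −0.4, records drawn to fail get at least
#' one property below threshold; likewise for the GI / drug-likeness-flag
#' screen. The last `n_duplicates` rows are exact copies of earlier rows, so
#' [merge_compounds()] must recover `n_compounds - n_duplicates` records.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with columns `name`, `pubchem_cid`, `smiles`,
#'   `molecular_formula`, `molecular_weight`, `source`, `ob`, `dl`, `caco2`,
#'   `gi_absorption` and five logical `dl_flag_*` columns (Lipinski, Ghose,
#'   Veber, Egan, Muegge style rules).
#' @examples
#' sim_compound_table(synthetic_spec(seed = 1))
#' @export
sim_compound_table <- function(spec) {
  validate_synthetic_spec(spec)
  cp <- spec$compound_params
  n_unique <- spec$n_compounds - cp$n_duplicates
  withr::with_seed(substream_seed(spec$seed, "compounds"), {
    pass_t <- runif(n_unique) < cp$pass_tcmsp
    pass_s <- runif(n_unique) < cp$pass_swissadme
    ob <- ifelse(pass_t, runif(n_unique, 30, 100), runif(n_unique, 0, 29.9))
    dl <- ifelse(pass_t, runif(n_unique, 0.18, 1), runif(n_unique, 0.18, 1))
    caco2 <- ifelse(pass_t, runif(n_unique, -0.4, 2), runif(n_unique, -0.4, 2))
    gi <- ifelse(pass_s, "High", sample(c("High", "Low"), n_unique, TRUE))
    n_true <- ifelse(pass_s, sample(2:5, n_unique, TRUE),
                     ifelse(gi == "High", sample(0:1, n_unique, TRUE),
                            sample(0:5, n_unique, TRUE)))
    flags <- t(vapply(n_true, function(k) {
      f <- rep(FALSE, 5)
      if (k > 0) f[sample(5, k)] <- TRUE
      f
    }, logical(5)))
    cid <- sample.int(1e7, n_unique)
    cid[runif(n_unique) < 0.1] <- NA_integer_
    tbl <- tibble(
      name = sprintf("Compound%03d", seq_len(n_unique)),
      pubchem_cid = cid,
      smiles = sprintf("SMI%05d", sample.int(99999, n_unique)),
      molecular_formula = sprintf("C%dH%dO%d", sample(10:30, n_unique, TRUE),
                                  sample(10:40, n_unique, TRUE),
                                  sample(1:10, n_unique, TRUE)),
      molecular_weight = round(runif(n_unique, 150, 600), 2),
      source = sample(c("TCMSP", "SymMap", "literature"), n_unique, TRUE),
      ob = round(ob, 2), dl = round(dl, 3), caco2 = round(caco2, 3),
      gi_absorption = gi
    )
    for (j in 1:5) tbl[[paste0("dl_flag_", j)]] <- flags[, j]
    if (cp$n_duplicates > 0) {
      dup <- tbl[sample.int(n_unique, cp$n_duplicates), ]
      tbl <- bind_rows(tbl, dup)
    }
    tbl
  })
}

#' Generate compound- and disease-target sets with a planted overlap
#'
#' Draws two deduplicated gene-symbol sets over a synthetic vocabulary
#' (`G000001`, ...) whose intersection has exactly `planted_overlap`
#' members, mirroring the compound-target / disease-target Venn structure.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `compound` and `disease`, each a
#'   `target_set` (see [target_set()]).
#' @examples
#' sets <- sim_target_sets(synthetic_spec(seed = 1, planted_overlap = 10,
#'                                        n_compound_targets = 30,
#'                                        n_disease_targets = 25))
#' intersect_targets(sets$compound, sets$disease)
#' @export
sim_target_sets <- function(spec) {
  validate_synthetic_spec(spec)
  n_a <- spec$n_compound_targets
  n_b <- spec$n_disease_targets
  k <- spec$planted_overlap
  withr::with_seed(substream_seed(spec$seed, "targets"), {
    universe <- sprintf("G%06d", sample.int(10 * (n_a + n_b) + 10,
                                            n_a + n_b - k))
    common <- universe[seq_len(k)]
    a_only <- universe[seq_len(n_a - k) + k]
    b_only <- universe[seq_len(n_b - k) + (n_a - k) + k]
    list(
      compound = target_set(c(common, a_only)),
      disease = target_set(c(common, b_only))
    )
  })
}

#' Generate a synthetic protein-protein interaction graph
#'
#' Produces a simple undirected graph (no self-loops, no multi-edges) under
#' the model named in the spec: Erdős–Rényi `G(n, p)`, Barabási–Albert
#' preferential attachment, or a fixed edge list passed through unchanged.
#'
#' @param spec A [synthetic_spec()].
#' @param nodes Optional character vector of node names; its length must
#'   match the model's `n`. Defaults to `G%06d` tokens.
#' @return An `igraph` object with a `name` vertex attribute.
#' @examples
#' g <- sim_ppi(synthetic_spec(seed = 1, graph_params = list(n = 20, p = 0.2)))
#' igraph::vcount(g)
#' @export
sim_ppi <- function(spec, nodes = NULL) {
  validate_synthetic_spec(spec)
  gp <- spec$graph_params
  g <- withr::with_seed(substream_seed(spec$seed, "ppi"), {
    switch(spec$graph_model,
      erdos_renyi = igraph::sample_gnp(gp$n, gp$p),
      barabasi_albert = igraph::as_undirected(
        igraph::sample_pa(gp$n, m = gp$m %||% 2), mode = "collapse"
      ),
      fixed_edge_list = {
        e <- gp$edges
        if (is.null(e) || ncol(e) < 2) {
          abort("`graph_params$edges` must be a two-column edge table")
        }
        igraph::graph_from_data_frame(e[, 1:2], directed = FALSE)
      },
      abort(sprintf("unknown graph model '%s'", spec$graph_model))
    )
  })
  g <- igraph::simplify(g)
  if (spec$graph_model != "fixed_edge_list") {
    nodes <- nodes %||% sprintf("G%06d", seq_len(igraph::vcount(g)))
    if (length(nodes) != igraph::vcount(g)) {
      abort("`nodes` must have one name per vertex")
    }
    igraph::V(g)$name <- nodes
  }
  g
}

#' Generate a gene-set collection with planted enriched terms
#'
#' Non-planted terms draw members uniformly from the background; each
#' planted term draws `round(effect * size)` members from the study set and
#' the remainder from the background outside the study set, so at effect 1
#' every member of the term is a study gene and the term attains the
#' smallest enrichment p-value achievable at its size.
#'
#' @param spec A [synthetic_spec()].
#' @param study,background Character vectors or `target_set`s; `study` must
#'   be contained in `background`.
#' @return A gene-set collection: tibble with `term_id`, `term_name`,
#'   `category` (`KEGG`/`BP`/`CC`/`MF`) and a `genes` list-column.
#' @examples
#' bg <- sprintf("G%03d", 1:100)
#' sim_annotations(synthetic_spec(seed = 1,
#'                                planted_terms = list(list(term_id = "T1",
#'                                                          size = 10,
#'                                                          effect = 1))),
#'                 study = bg[1:20], background = bg)
#' @export
sim_annotations <- function(spec, study, background) {
  validate_synthetic_spec(spec)
  study <- set_members(study)
  background <- set_members(background)
  if (!all(study %in% background)) {
    abort("`study` must be a subset of `background`")
  }
  planted_ids <- map_chr(spec$planted_terms, "term_id")
  n_free <- spec$n_terms - length(planted_ids)
  if (n_free < 0) abort("`n_terms` smaller than the number of planted terms")
  withr::with_seed(substream_seed(spec$seed, "annotations"), {
    planted <- map(spec$planted_terms, function(pt) {
      size <- min(pt$size, length(background))
      k <- min(round(pt$effect * size), length(study), size)
      members <- c(sample(study, k),
                   sample(setdiff(background, study), size - k))
      tibble(term_id = pt$term_id,
             term_name = paste0("planted ", pt$term_id),
             category = pt$category %||% "KEGG",
             genes = list(sort(members)))
    })
    sizes <- sample(seq(spec$term_size_range[1],
                        min(spec$term_size_range[2], length(background))),
                    n_free, replace = TRUE)
    free <- map2(seq_len(n_free), sizes, function(i, sz) {
      tibble(term_id = sprintf("T%04d", i + 1000),
             term_name = sprintf("term %04d", i + 1000),
             category = sample(c("KEGG", "BP", "CC", "MF"), 1),
             genes = list(sort(sample(background, sz))))
    })
    bind_rows(c(planted, free))
  })
}

#' Generate an RMSD-style trajectory with a planted equilibration time
#'
#' Before `equilibration_time` the series ramps from 0 toward
#' `plateau_level` while librating: successive samples alternate by
#' `pre_eq_amplitude`, the large-amplitude fluctuation of an unequilibrated
#' system. From `equilibration_time` on, values fluctuate about
#' `plateau_level` with standard deviation `noise_sd`. With `noise_sd = 0`
#' the post-equilibration samples equal `plateau_level` exactly and
#' [assess_stability()] recovers the planted time to within one sampling
#' interval.
#'
#' @param spec A [synthetic_spec()].
#' @param label Complex identifier stored on the series.
#' @return A `trajectory_series`: tibble with `time` (ns) and `value` (nm),
#'   with the label as an attribute.
#' @examples
#' s <- sim_trajectory(synthetic_spec(seed = 1))
#' summarize_series(s, from_time = 20)
#' @export
sim_trajectory <- function(spec, label = "complex") {
  validate_synthetic_spec(spec)
  tp <- spec$trajectory_params
  times <- seq(0, tp$t_end, by = tp$dt)
  withr::with_seed(substream_seed(spec$seed, "trajectory"), {
    pre <- times < tp$equilibration_time
    base <- ifelse(pre,
                   tp$plateau_level * times / max(tp$equilibration_time, tp$dt),
                   tp$plateau_level)
    libration <- ifelse(pre, tp$pre_eq_amplitude * (seq_along(times) %% 2), 0)
    noise <- if (tp$noise_sd > 0) rnorm(length(times), 0, tp$noise_sd) else 0
    values <- pmax(base + libration + noise, 0)
    trajectory_series(times, values, label = label)
  })
}

#' Generate MM/PBSA component rows with known sums
#'
#' Each row carries only the five base components (VDW, COU, PB, SA, −TΔS),
#' drawn uniformly from the spec ranges and rounded to 0.01 kcal/mol; the
#' derived totals MM, ΔH and ΔG are deliberately absent so that
#' [mmpbsa_totals()] must reconstruct them.
#'
#' @param spec A [synthetic_spec()].
#' @return Tibble with columns `complex`, `vdw`, `cou`, `pb`, `sa`,
#'   `minus_t_delta_s` (kcal/mol).
#' @examples
#' mmpbsa_totals(sim_energy_table(synthetic_spec(seed = 1)))
#' @export
sim_energy_table <- function(spec) {
  validate_synthetic_spec(spec)
  ep <- spec$energy_params
  n <- ep$n_complexes
  draw <- function(r) round(runif(n, r[1], r[2]), 2)
  withr::with_seed(substream_seed(spec$seed, "energy"), {
    tibble(
      complex = sprintf("CPX%02d", seq_len(n)),
      vdw = draw(ep$vdw), cou = draw(ep$cou), pb = draw(ep$pb),
      sa = draw(ep$sa), minus_t_delta_s = draw(ep$minus_t_delta_s)
    )
  })
}

#' Generate a docking pose table
#'
#' Every ligand–receptor pair receives `n_poses` conformations with
#' affinities drawn uniformly from `affinity_range` (kcal/mol), emulating
#' the tabular output of a docking engine.
#'
#' @param spec A [synthetic_spec()].
#' @return Tibble with `ligand`, `receptor`, `pose_index`, `affinity`.
#' @examples
#' best_pose(sim_docking_poses(synthetic_spec(seed = 1)))
#' @export
sim_docking_poses <- function(spec) {
  validate_synthetic_spec(spec)
  dp <- spec$docking_params
  grid <- expand.grid(
    ligand = sprintf("L%02d", seq_len(dp$n_ligands)),
    receptor = sprintf("R%02d", seq_len(dp$n_receptors)),
    pose_index = seq_len(dp$n_poses),
    stringsAsFactors = FALSE
  )
  withr::with_seed(substream_seed(spec$seed, "docking"), {
    grid$affinity <- round(runif(nrow(grid), dp$affinity_range[1],
                                 dp$affinity_range[2]), 2)
    as_tibble(grid[order(grid$ligand, grid$receptor, grid$pose_index), ])
  })
}

#' Generate a per-residue energy decomposition with a planted fraction
#'
#' Draws per-residue enthalpy contributions and rescales a chosen subset so
#' that it accounts for exactly `planted_fraction` of the total, the
#' construction used to verify [residue_fraction()].
#'
#' @param spec A [synthetic_spec()].
#' @param n_residues Number of residues.
#' @param planted_residues Indices of the planted subset.
#' @param planted_fraction Fraction of the total ΔH the subset must carry.
#' @return Tibble with `residue` and `delta_h` (kcal/mol); the total ΔH is
#'   stored in attribute `total_delta_h`.
#' @export
sim_residue_decomposition <- function(spec, n_residues = 50,
                                      planted_residues = c(36, 39, 156, 166) %% n_residues + 1,
                                      planted_fraction = 0.429) {
  validate_synthetic_spec(spec)
  check_number(planted_fraction, "planted_fraction", 1e-9, 1)
  withr::with_seed(substream_seed(spec$seed, "decomposition"), {
    contrib <- -abs(rnorm(n_residues, 0.5, 0.3))
    planted_residues <- unique(pmin(pmax(planted_residues, 1), n_residues))
    inside <- sum(contrib[planted_residues])
    outside <- sum(contrib[-planted_residues])
    # scale the subset so inside / (inside + outside) == planted_fraction
    scale <- planted_fraction * outside / ((1 - planted_fraction) * inside)
    contrib[planted_residues] <- contrib[planted_residues] * scale
    out <- tibble(residue = seq_len(n_residues), delta_h = contrib)
    attr(out, "total_delta_h") <- sum(contrib)
    attr(out, "unit") <- "kcal/mol"
    out
  })
}
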