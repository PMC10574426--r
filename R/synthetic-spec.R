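#' Specification for the synthetic study system
#'
#' `synthetic_spec()` collects every parameter of the synthetic-data
#' generators into one validated object. The generators plant known ground
#' truth — a fixed compound/disease target overlap, enriched annotation
#' terms, a known interaction graph, trajectories with a known equilibration
#' time, and energy tables whose totals are known sums — so that every
#' downstream pipeline stage can be checked against construction.
#'
#' The defaults mirror the scale of a typical herbal network-pharmacology
#' study: 30 compound records of which 3 are duplicate entries (27 unique),
#' 665 compound targets and 593 disease targets sharing exactly 119 genes,
#' an Erdős–Rényi interaction graph over the 119 shared genes, 50 annotation
#' terms with sizes in the usual 10–100 gene-set filter range, a 50 ns
#' trajectory equilibrating at 13 ns around a 0.35 nm plateau, and energy
#' components in the ranges seen for flavonoid–kinase complexes.
#'
#' A single integer `seed` drives one master stream; each generator uses its
#' own substream derived from it, so adding a generator never perturbs the
#' output of another.
#'
#' @param seed Integer master seed.
#' @param n_compounds Total compound records generated, duplicates included.
#' @param compound_params List: `pass_tcmsp` and `pass_swissadme`, the
#'   fractions of records drawn to pass each ADME screen; `n_duplicates`,
#'   the number of exact duplicate rows planted.
#' @param n_compound_targets,n_disease_targets Sizes of the two target sets.
#' @param planted_overlap Exact size of their intersection; must not exceed
#'   the smaller set.
#' @param graph_model One of `"erdos_renyi"`, `"barabasi_albert"`,
#'   `"fixed_edge_list"`.
#' @param graph_params Model parameters: `n`, `p` (Erdős–Rényi); `n`, `m`
#'   (Barabási–Albert edges added per step); `edges` (two-column data frame
#'   for `fixed_edge_list`).
#' @param n_terms Number of annotation terms generated.
#' @param term_size_range Integer range terms are drawn from (members per
#'   term), the usual gene-set size filter window.
#' @param planted_terms List of lists with `term_id`, `size`, `effect` and
#'   optional `category`; `effect` is the fraction of the term's members
#'   drawn from the study set (1 = every member is a study gene, the
#'   smallest achievable enrichment p for that term size).
#' @param trajectory_params List: `equilibration_time` (ns),
#'   `plateau_level` (nm), `noise_sd` (nm), `t_end` (ns), `dt` (ns sampling
#'   interval), `pre_eq_amplitude` (nm, amplitude of the alternating
#'   pre-equilibration libration that makes the planted equilibration time
#'   identifiable by the sliding-window range rule).
#' @param energy_params List of two-element ranges (kcal/mol) for `vdw`,
#'   `cou`, `pb`, `sa`, `minus_t_delta_s`, plus `n_complexes`.
#' @param docking_params List: `n_ligands`, `n_receptors`, `n_poses`,
#'   `affinity_range` (kcal/mol).
#'
#' @return An object of class `"synthetic_spec"` (a validated list).
#' @examples
#' spec <- synthetic_spec(seed = 1)
#' spec$planted_overlap
#' @export
synthetic_spec <- function(seed = 101,
                           n_compounds = 30,
                           compound_params = list(),
                           n_compound_targets = 665,
                           n_disease_targets = 593,
                           planted_overlap = 119,
                           graph_model = c("erdos_renyi", "barabasi_albert",
                                           "fixed_edge_list"),
                           graph_params = list(n = 119, p = 0.06),
                           n_terms = 50,
                           term_size_range = c(10, 100),
                           planted_terms = list(
                             list(term_id = "T0001", size = 40, effect = 1,
                                  category = "KEGG")
                           ),
                           trajectory_params = list(),
                           energy_params = list(),
                           docking_params = list()) {
  graph_model <- match.arg(graph_model)
  compound_params <- modifyList(
    list(pass_tcmsp = 0.6, pass_swissadme = 0.7, n_duplicates = 3),
    compound_params
  )
  trajectory_params <- modifyList(
    list(equilibration_time = 13, plateau_level = 0.35, noise_sd = 0.02,
         t_end = 50, dt = 0.05, pre_eq_amplitude = 0.3),
    trajectory_params
  )
  energy_params <- modifyList(
    list(n_complexes = 5, vdw = c(-50, -30), cou = c(-12, -3),
         pb = c(10, 36), sa = c(-6, -4), minus_t_delta_s = c(1, 6)),
    energy_params
  )
  docking_params <- modifyList(
    list(n_ligands = 10, n_receptors = 10, n_poses = 10,
         affinity_range = c(-11, -4)),
    docking_params
  )

  spec <- structure(
    list(
      seed = seed, n_compounds = n_compounds,
      compound_params = compound_params,
      n_compound_targets = n_compound_targets,
      n_disease_targets = n_disease_targets,
      planted_overlap = planted_overlap,
      graph_model = graph_model, graph_params = graph_params,
      n_terms = n_terms, term_size_range = term_size_range,
      planted_terms = planted_terms,
      trajectory_params = trajectory_params,
      energy_params = energy_params,
      docking_params = docking_params
    ),
    class = "synthetic_spec"
  )
  validate_synthetic_spec(spec)
}

validate_synthetic_spec <- function(spec) {
  if (!is.numeric(spec$seed) || length(spec$seed) != 1 || is.na(spec$seed)) {
    abort("`seed` must be a single integer")
  }
  for (fld in c("n_compounds", "n_compound_targets", "n_disease_targets",
                "planted_overlap", "n_terms")) {
    v <- spec[[fld]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v %% 1 != 0) {
      abort(sprintf("`%s` must be a single non-negative integer", fld))
    }
  }
  if (spec$planted_overlap >
      min(spec$n_compound_targets, spec$n_disease_targets)) {
    abort(paste0(
      "`planted_overlap` (", spec$planted_overlap,
      ") exceeds the smaller target set (",
      min(spec$n_compound_targets, spec$n_disease_targets), ")"
    ))
  }
  cp <- spec$compound_params
  check_number(cp$pass_tcmsp, "compound_params$pass_tcmsp", 0, 1)
  check_number(cp$pass_swissadme, "compound_params$pass_swissadme", 0, 1)
  if (cp$n_duplicates < 0 || cp$n_duplicates >= max(spec$n_compounds, 1)) {
    abort("`compound_params$n_duplicates` must be in [0, n_compounds)")
  }
  tp <- spec$trajectory_params
  check_number(tp$equilibration_time, "trajectory_params$equilibration_time", 0)
  check_number(tp$plateau_level, "trajectory_params$plateau_level", 0)
  check_number(tp$noise_sd, "trajectory_params$noise_sd", 0)
  check_number(tp$dt, "trajectory_params$dt", 1e-9)
  check_number(tp$t_end, "trajectory_params$t_end", tp$dt)
  if (spec$term_size_range[1] < 1 ||
      spec$term_size_range[2] < spec$term_size_range[1]) {
    abort("`term_size_range` must be an increasing positive range")
  }
  for (pt in spec$planted_terms) {
    if (is.null(pt$term_id) || is.null(pt$size) || is.null(pt$effect)) {
      abort("each planted term needs `term_id`, `size` and `effect`")
    }
    check_number(pt$effect, "planted term `effect`", 0, 1)
  }
  for (comp in c("vdw", "cou", "pb", "sa", "minus_t_delta_s")) {
    r <- spec$energy_params[[comp]]
    if (length(r) != 2 || any(!is.finite(r)) || r[2] < r[1]) {
      abort(sprintf("`energy_params$%s` must be a finite increasing range", comp))
    }
  }
  spec
}

# One master stream, fixed substream per generator: drawing all substream
# seeds up front means a new generator appends a stream without shifting
# the existing ones.
.substreams <- c(compounds = 1, targets = 2, ppi = 3, annotations = 4,
                 trajectory = 5, energy = 6, docking = 7, pipeline = 8,
                 decomposition = 9)

substream_seed <- function(seed, stream) {
  stopifnot(stream %in% names(.substreams))
  withr::with_seed(as.integer(seed) %% .Machine$integer.max,
                   sample.int(.Machine$integer.max - 1L,
                              length(.substreams)))[.substreams[[stream]]]
}
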