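#' Best docking pose per ligand-receptor pair
#'
#' Reduces a pose table (each pair typically carries around ten
#' conformations) to the best — lowest, i.e. most favorable — affinity per
#' ligand–receptor pair.
#'
#' @param poses Data frame with columns `ligand`, `receptor`, `affinity`
#'   (kcal/mol); a `pose_index` column is ignored.
#' @return An `affinity_matrix`: tibble with one row per pair (`ligand`,
#'   `receptor`, `affinity`).
#' @examples
#' poses <- tibble::tibble(ligand = "L", receptor = "R",
#'                         affinity = c(-6.1, -7.3, -5.0))
#' best_pose(poses)
#' @export
best_pose <- function(poses) {
  check_columns(poses, c("ligand", "receptor", "affinity"), "pose table")
  if (nrow(poses) == 0) abort("pose table is empty")
  if (any(!is.finite(poses$affinity))) abort("non-finite affinity in pose table")
  out <- as_tibble(poses) |>
    group_by(.data$ligand, .data$receptor) |>
    summarise(affinity = min(.data$affinity), .groups = "drop") |>
    arrange(.data$ligand, .data$receptor)
  structure(out, class = c("affinity_matrix", class(tibble())))
}

#' Classify a docking affinity
#'
#' The conventional reading of docking scores: affinities above −5 kcal/mol
#' predict no binding, at or below −5 moderate binding, at or below −7
#' strong binding. The boundary values −5 and −7 are assigned to the
#' stronger class.
#'
#' @param affinity Numeric vector (kcal/mol).
#' @param moderate,strong Class boundaries (defaults −5 and −7).
#' @return Factor with levels `none < moderate < strong`.
#' @examples
#' classify_affinity(c(-4.9, -6, -10.01))
#' @export
classify_affinity <- function(affinity, moderate = -5, strong = -7) {
  if (any(!is.finite(affinity))) abort("affinity must be finite")
  cls <- ifelse(affinity <= strong, "strong",
                ifelse(affinity <= moderate, "moderate", "none"))
  factor(cls, levels = c("none", "moderate", "strong"), ordered = TRUE)
}

#' Best complex per receptor and the global minimum
#'
#' For each receptor, selects the ligand with the minimum affinity (ties
#' broken by lexicographically smaller ligand id) and classifies it with
#' [classify_affinity()]. The global minimum cell is stored as attribute
#' `global_best` and reported by [glance()].
#'
#' @param m An [best_pose()] affinity matrix (or any tibble with `ligand`,
#'   `receptor`, `affinity`).
#' @param ... Unused.
#' @return A `best_complex_table` tibble with `receptor`, `ligand`,
#'   `affinity`, `predicted_binding`.
#' @export
best_complex_table <- function(m) {
  check_columns(m, c("ligand", "receptor", "affinity"), "affinity matrix")
  if (nrow(m) == 0) abort("affinity matrix is empty")
  out <- as_tibble(m) |>
    arrange(.data$receptor, .data$affinity, .data$ligand) |>
    group_by(.data$receptor) |>
    slice_head(n = 1) |>
    ungroup() |>
    select("receptor", "ligand", "affinity") |>
    mutate(predicted_binding = classify_affinity(.data$affinity))
  best <- out |> arrange(.data$affinity, .data$ligand, .data$receptor) |> head(1)
  structure(out, class = c("best_complex_table", class(tibble())),
            global_best = as.list(best[, c("ligand", "receptor", "affinity")]))
}

#' @rdname best_complex_table
#' @param x A `best_complex_table`.
#' @export
glance.best_complex_table <- function(x, ...) {
  gb <- attr(x, "global_best")
  tibble(best_ligand = gb$ligand, best_receptor = gb$receptor,
         best_affinity = gb$affinity,
         n_strong = sum(x$predicted_binding == "strong"),
         n_moderate = sum(x$predicted_binding == "moderate"),
         n_none = sum(x$predicted_binding == "none"))
}

#' Compare one target's affinities against all others
#'
#' For each receptor, a two-sided Wilcoxon rank-sum test of its ligand
#' affinities against the pooled affinities of every other receptor. This
#' is one possible formalization of per-target "significantly lower
#' affinity" statements; the normal approximation is used because docking
#' grids produce ties.
#'
#' @param m An affinity matrix (`ligand`, `receptor`, `affinity`).
#' @return Tibble with `receptor`, `n`, `median_affinity`, `p_value`.
#' @export
compare_target_affinities <- function(m) {
  check_columns(m, c("ligand", "receptor", "affinity"), "affinity matrix")
  receptors <- sort(unique(m$receptor))
  bind_rows(map(receptors, function(r) {
    a <- m$affinity[m$receptor == r]
    b <- m$affinity[m$receptor != r]
    p <- if (length(a) > 0 && length(b) > 0) {
      suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
    } else NA_real_
    tibble(receptor = r, n = length(a), median_affinity = median(a),
           p_value = p)
  }))
}

#' Read a docking pose table or a Vina log
#'
#' Auto-detects the format: a tab-separated table with a header containing
#' `affinity` is read as a generic pose table; otherwise the file is parsed
#' as an AutoDock-Vina-style log whose result block lines are
#' `mode | affinity | rmsd l.b. | rmsd u.b.`.
#'
#' @param path File to read.
#' @param ligand,receptor Pair identifiers, required for the Vina log
#'   dialect (a log holds one pair).
#' @return Tibble with `ligand`, `receptor`, `pose_index`, `affinity`.
#' @export
read_poses <- function(path, ligand = NULL, receptor = NULL) {
  first <- readLines(path, n = 50, warn = FALSE)
  if (any(grepl("\t", first[1]) & grepl("affinity", tolower(first[1])))) {
    tbl <- readr::read_tsv(path, show_col_types = FALSE)
    check_columns(tbl, c("ligand", "receptor", "affinity"), "pose table")
    if (!"pose_index" %in% names(tbl)) tbl$pose_index <- seq_len(nrow(tbl))
    return(tbl[, c("ligand", "receptor", "pose_index", "affinity")])
  }
  if (is.null(ligand) || is.null(receptor)) {
    abort("Vina log input needs explicit `ligand` and `receptor`")
  }
  lines <- readLines(path, warn = FALSE)
  hits <- regmatches(lines,
                     regexec("^\\s*(\\d+)\\s+(-?\\d+(?:\\.\\d+)?)\\s+", lines))
  hits <- hits[lengths(hits) == 3]
  if (length(hits) == 0) abort("no pose lines found in Vina log")
  tibble(ligand = ligand, receptor = receptor,
         pose_index = as.integer(map_chr(hits, 2)),
         affinity = as.numeric(map_chr(hits, 3)))
}
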