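#' Screen compounds on TCMSP-style ADME thresholds
#'
#' Keeps the records with oral bioavailability (OB) ≥ 30 %, drug-likeness
#' (DL) ≥ 0.18 and Caco-2 permeability ≥ −0.4, all boundaries inclusive,
#' preserving input order. These are the standard screening thresholds for
#' herbal compound databases.
#'
#' @param compounds Data frame with numeric columns `ob`, `dl`, `caco2`.
#' @param ob_min,dl_min,caco2_min Thresholds (defaults 30, 0.18, −0.4).
#' @param missing How to treat records with a missing property: `"error"`
#'   (default) fails naming the field and record; `"drop"` silently
#'   excludes them.
#' @return The surviving rows, as a tibble, in input order.
#' @examples
#' screen_tcmsp(tibble::tibble(name = "x", ob = 45, dl = 0.2, caco2 = 0.1))
#' @export
screen_tcmsp <- function(compounds, ob_min = 30, dl_min = 0.18,
                         caco2_min = -0.4, missing = c("error", "drop")) {
  missing <- match.arg(missing)
  check_columns(compounds, c("ob", "dl", "caco2"), "compound table")
  compounds <- as_tibble(compounds)
  na_rows <- which(is.na(compounds$ob) | is.na(compounds$dl) |
                     is.na(compounds$caco2))
  if (length(na_rows) > 0) {
    if (missing == "error") {
      fields <- vapply(na_rows, function(i) {
        paste(c("ob", "dl", "caco2")[is.na(unlist(
          compounds[i, c("ob", "dl", "caco2")]))], collapse = ", ")
      }, character(1))
      abort(paste0("missing ADME propert(ies) in record(s): ",
                   paste(sprintf("row %d (%s)", na_rows, fields),
                         collapse = "; ")))
    }
    compounds <- compounds[-na_rows, ]
  }
  compounds[compounds$ob >= ob_min & compounds$dl >= dl_min &
              compounds$caco2 >= caco2_min, ]
}

#' Screen compounds on GI absorption and drug-likeness flags
#'
#' Keeps records whose gastrointestinal absorption rating is `"High"` and
#' that satisfy at least `min_flags` of the boolean drug-likeness rules
#' (Lipinski, Ghose, Veber, Egan, Muegge style "Yes" items).
#'
#' @param compounds Data frame with a `gi_absorption` column and either
#'   logical `dl_flag_*` columns or a `druglikeness_flags` list-column.
#' @param min_flags Minimum number of rules met (default 2).
#' @param missing As in [screen_tcmsp()].
#' @return The surviving rows, in input order.
#' @export
screen_swissadme <- function(compounds, min_flags = 2,
                             missing = c("error", "drop")) {
  missing <- match.arg(missing)
  check_columns(compounds, "gi_absorption", "compound table")
  compounds <- as_tibble(compounds)
  if ("druglikeness_flags" %in% names(compounds)) {
    n_yes <- map_int(compounds$druglikeness_flags,
                     function(f) sum(as.logical(f), na.rm = TRUE))
  } else {
    flag_cols <- grep("^dl_flag_", names(compounds), value = TRUE)
    if (length(flag_cols) == 0) {
      abort("compound table needs `dl_flag_*` columns or `druglikeness_flags`")
    }
    n_yes <- rowSums(compounds[flag_cols], na.rm = TRUE)
  }
  na_rows <- which(is.na(compounds$gi_absorption))
  if (length(na_rows) > 0) {
    if (missing == "error") {
      abort(paste0("missing `gi_absorption` in record(s): ",
                   paste(na_rows, collapse = ", ")))
    }
    keep <- rep(TRUE, nrow(compounds))
    keep[na_rows] <- FALSE
    compounds <- compounds[keep, ]
    n_yes <- n_yes[keep]
  }
  compounds[compounds$gi_absorption == "High" & n_yes >= min_flags, ]
}

#' Merge compound lists and remove duplicate entries
#'
#' Combines one or more screened compound tables into one, removing
#' duplicates. Two records are the same compound when both carry a PubChem
#' CID and the CIDs match, or otherwise when their case- and
#' whitespace-normalized names match (some deposited compounds have no
#' CID). The first occurrence wins; output is sorted by name. Records under
#' the same key whose molecular weights differ by more than `mw_tol`
#' (relative) trigger a warning.
#'
#' @param ... Data frames of compound records with at least a `name`
#'   column; `pubchem_cid` and `molecular_weight` are used when present.
#' @param mw_tol Relative molecular-weight discrepancy tolerated silently
#'   (default 0.01).
#' @return A deduplicated tibble sorted by `name`.
#' @examples
#' a <- tibble::tibble(name = c("Quercetin", "Luteolin"),
#'                     pubchem_cid = c(5280343L, 5280445L))
#' b <- tibble::tibble(name = "quercetin ", pubchem_cid = 5280343L)
#' merge_compounds(a, b)
#' @export
merge_compounds <- function(..., mw_tol = 0.01) {
  tables <- list(...)
  tables <- keep(tables, function(t) !is.null(t) && nrow(t) > 0)
  if (length(tables) == 0) return(tibble(name = character(0)))
  all <- bind_rows(tables)
  check_columns(all, "name", "compound table")
  if (!"pubchem_cid" %in% names(all)) all$pubchem_cid <- NA_integer_
  norm <- normalize_name(all$name)
  kept <- integer(0)
  for (i in seq_len(nrow(all))) {
    dup_of <- 0L
    for (j in kept) {
      same <- if (!is.na(all$pubchem_cid[i]) && !is.na(all$pubchem_cid[j])) {
        all$pubchem_cid[i] == all$pubchem_cid[j]
      } else {
        norm[i] == norm[j]
      }
      if (same) { dup_of <- j; break }
    }
    if (dup_of == 0L) {
      kept <- c(kept, i)
    } else if ("molecular_weight" %in% names(all)) {
      mi <- all$molecular_weight[i]; mj <- all$molecular_weight[dup_of]
      if (!is.na(mi) && !is.na(mj) && mj != 0 &&
          abs(mi - mj) / abs(mj) > mw_tol) {
        warn(sprintf(
          "conflicting molecular weight for '%s' (%.2f vs %.2f); keeping first",
          all$name[dup_of], mj, mi))
      }
    }
  }
  out <- all[kept, ]
  out[order(out$name), ]
}
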