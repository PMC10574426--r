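#' Construct a trajectory series
#'
#' @param time Times in ns, strictly increasing.
#' @param value Nonnegative values (nm for RMSD, nm² for SASA).
#' @param label Complex identifier.
#' @return A `trajectory_series` tibble with columns `time`, `value`.
#' @export
trajectory_series <- function(time, value, label = "complex") {
  if (length(time) != length(value)) abort("`time` and `value` lengths differ")
  if (any(!is.finite(time)) || any(diff(time) <= 0)) {
    abort("`time` must be finite and strictly increasing")
  }
  if (any(time < 0)) abort("negative times in trajectory")
  if (any(!is.finite(value)) || any(value < 0)) {
    abort("trajectory values must be finite and nonnegative")
  }
  structure(tibble(time = time, value = value),
            class = c("trajectory_series", class(tibble())), label = label)
}

#' Mean and standard deviation of a trajectory tail
#'
#' Arithmetic mean and sample (n−1) standard deviation over the samples at
#' or after `from_time`, the usual "average RMSD over the analyzed
#' segment" summary.
#'
#' @param s A [trajectory_series()] (or tibble with `time`, `value`).
#' @param from_time Start of the analyzed segment (ns, default 0).
#' @return One-row tibble with `n`, `mean`, `sd`.
#' @export
summarize_series <- function(s, from_time = 0) {
  check_columns(s, c("time", "value"), "trajectory")
  v <- s$value[s$time >= from_time]
  if (length(v) < 2) abort("fewer than 2 samples at or after `from_time`")
  tibble(n = length(v), mean = mean(v), sd = stats::sd(v))
}

#' Assess trajectory stability by the sliding-window range rule
#'
#' A system is deemed stable once the RMSD fluctuation range stays below
#' `threshold`: the equilibration time is the earliest sample time `t` such
#' that every window of length `window` within `[t, end]` has
#' `max − min < threshold`. Fluctuation is operationalized as the range
#' over the window.
#'
#' @param s A [trajectory_series()].
#' @param threshold Range threshold in nm (default 0.2, the conventional
#'   stability criterion).
#' @param window Window length in ns (default 5).
#' @return A `stability_assessment`: list with `stable` (logical),
#'   `equilibration_time` (ns or `NA`), `threshold`, `window`, `label`.
#'   [tidy()] returns it as a one-row tibble.
#' @examples
#' s <- trajectory_series(0:19, rep(0.3, 20))
#' assess_stability(s)$equilibration_time
#' @export
assess_stability <- function(s, threshold = 0.2, window = 5) {
  check_columns(s, c("time", "value"), "trajectory")
  t <- s$time; v <- s$value
  t_end <- t[length(t)]
  if (t_end - t[1] < window) abort("trajectory spans less than one window")
  eps <- 1e-9
  starts <- which(t + window <= t_end + eps)
  rng <- vapply(starts, function(i) {
    j <- which(t >= t[i] - eps & t <= t[i] + window + eps)
    max(v[j]) - min(v[j])
  }, numeric(1))
  ok <- rng < threshold
  # earliest start from which every later window is quiet
  stable_from <- NA_integer_
  all_ok_after <- rev(cumprod(rev(ok))) > 0
  if (any(all_ok_after)) stable_from <- starts[which(all_ok_after)[1]]
  structure(
    list(stable = !is.na(stable_from),
         equilibration_time = if (is.na(stable_from)) NA_real_ else t[stable_from],
         threshold = threshold, window = window,
         label = attr(s, "label") %||% "complex"),
    class = "stability_assessment"
  )
}

#' @rdname assess_stability
#' @param x A `stability_assessment`.
#' @param ... Unused.
#' @export
tidy.stability_assessment <- function(x, ...) {
  tibble(label = x$label, stable = x$stable,
         equilibration_time = x$equilibration_time,
         threshold = x$threshold, window = x$window)
}

#' @export
print.stability_assessment <- function(x, ...) {
  cat(sprintf("%s: %s (equilibration at %s ns; range < %g nm over %g ns windows)\n",
              x$label, if (x$stable) "stable" else "not stable",
              format(x$equilibration_time), x$threshold, x$window))
  invisible(x)
}

#' Complete MM/PBSA component rows with their totals
#'
#' Fills in the derived totals from the five base components:
#' `MM = VDW + COU`, `ΔH = MM + PB + SA`, `ΔG = ΔH + (−TΔS)`, all in
#' kcal/mol. In validation mode, totals already present in the input are
#' checked against the recomputed ones; table-style inputs are usually
#' pre-rounded to 0.01 kcal/mol, so each printed total may drift from the
#' recomputed sum by a rounding step per addend (default tolerance 0.02).
#'
#' @param components Data frame with numeric columns `vdw`, `cou`, `pb`,
#'   `sa`, `minus_t_delta_s`.
#' @param validate Check any supplied `mm`, `delta_h`, `delta_g` columns
#'   against the recomputed totals (default `FALSE`).
#' @param tolerance Allowed absolute discrepancy in validation (kcal/mol).
#' @return The input tibble with (re)computed `mm`, `delta_h`, `delta_g`.
#' @examples
#' mmpbsa_totals(tibble::tibble(vdw = -42.13, cou = -3.20, pb = 14.48,
#'                              sa = -4.53, minus_t_delta_s = 5.35))
#' @export
mmpbsa_totals <- function(components, validate = FALSE, tolerance = 0.02) {
  base <- c("vdw", "cou", "pb", "sa", "minus_t_delta_s")
  missing <- setdiff(base, names(components))
  if (length(missing) > 0) {
    abort(paste0("missing energy component(s): ", paste(missing, collapse = ", ")))
  }
  components <- as_tibble(components)
  for (col in base) {
    if (any(!is.finite(components[[col]]))) {
      abort(paste0("non-finite values in `", col, "`"))
    }
  }
  mm <- components$vdw + components$cou
  delta_h <- mm + components$pb + components$sa
  delta_g <- delta_h + components$minus_t_delta_s
  if (validate) {
    recomputed <- list(mm = mm, delta_h = delta_h, delta_g = delta_g)
    for (col in names(recomputed)) {
      if (col %in% names(components)) {
        off <- which(abs(components[[col]] - recomputed[[col]]) > tolerance)
        if (length(off) > 0) {
          abort(sprintf("supplied `%s` deviates from recomputed total by more than %g kcal/mol in row(s) %s",
                        col, tolerance, paste(off, collapse = ", ")))
        }
      }
    }
  }
  components$mm <- mm
  components$delta_h <- delta_h
  components$delta_g <- delta_g
  components
}

#' Fraction of the total binding enthalpy carried by chosen residues
#'
#' `100 × (sum of the residues' ΔH contributions) / total ΔH`. When the
#' decomposition is tagged kJ/mol, contributions are converted to kcal/mol
#' (factor 4.184) before dividing, so the fraction is unit-invariant as
#' long as `total_delta_h` is in kcal/mol.
#'
#' @param decomposition Data frame with columns `residue` and `delta_h`, or
#'   a numeric vector named by residue index.
#' @param residues Residue indices to sum over.
#' @param total_delta_h Total binding enthalpy in kcal/mol (nonzero).
#' @param unit Unit of the decomposition values (default from the input's
#'   `unit` attribute, else kcal/mol).
#' @return The percentage, a single number.
#' @export
residue_fraction <- function(decomposition, residues, total_delta_h,
                             unit = NULL) {
  if (is.numeric(decomposition) && !is.data.frame(decomposition)) {
    decomposition <- tibble(residue = as.integer(names(decomposition)),
                            delta_h = unname(decomposition))
  }
  check_columns(decomposition, c("residue", "delta_h"), "decomposition")
  unit <- unit %||% attr(decomposition, "unit") %||% "kcal/mol"
  if (!unit %in% c("kcal/mol", "kJ/mol")) {
    abort("`unit` must be 'kcal/mol' or 'kJ/mol'")
  }
  if (!is.finite(total_delta_h) || total_delta_h == 0) {
    abort("`total_delta_h` must be finite and nonzero")
  }
  unknown <- setdiff(residues, decomposition$residue)
  if (length(unknown) > 0) {
    abort(paste0("unknown residue(s): ", paste(unknown, collapse = ", ")))
  }
  contrib <- decomposition$delta_h[match(residues, decomposition$residue)]
  if (unit == "kJ/mol") contrib <- contrib / 4.184
  100 * sum(contrib) / total_delta_h
}
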