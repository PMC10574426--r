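test_that("series summary gives arithmetic mean and sample sd", {
  s <- trajectory_series(c(0, 1), c(0.1, 0.3))
  out <- summarize_series(s)
  expect_equal(out$mean, 0.2)
  expect_equal(out$sd, sqrt(0.02), tolerance = 1e-12)

  const <- trajectory_series(0:9, rep(0.4, 10))
  expect_equal(summarize_series(const)$sd, 0)
  expect_error(summarize_series(s, from_time = 1), "fewer than 2")
})

test_that("summary agrees with a two-pass reference and recovers noise sd", {
  spec <- synthetic_spec(seed = 21,
                         trajectory_params = list(noise_sd = 0.05, dt = 0.1))
  s <- sim_trajectory(spec)
  out <- summarize_series(s, from_time = 13)
  v <- s$value[s$time >= 13]
  two_pass <- sqrt(sum((v - sum(v) / length(v))^2) / (length(v) - 1))
  expect_equal(out$sd, two_pass, tolerance = 1e-12)
  expect_equal(out$mean, sum(v) / length(v), tolerance = 1e-12)
  expect_lt(abs(out$sd - 0.05) / 0.05, 0.2)  # n = 371 samples
})

test_that("stability rule recovers planted equilibration times", {
  for (eq in c(5, 13, 20)) {
    spec <- synthetic_spec(seed = 2, trajectory_params = list(
      noise_sd = 0, equilibration_time = eq, dt = 0.1))
    st <- assess_stability(sim_trajectory(spec))
    expect_true(st$stable)
    expect_lte(abs(st$equilibration_time - eq), 0.1 + 1e-9)
  }
})

test_that("unstable and constant trajectories are classified correctly", {
  ramp <- trajectory_series(seq(0, 10, 0.5), seq(0, 1, 0.05))
  st <- assess_stability(ramp)  # rises 0.25 per 5 ns window > 0.2
  expect_false(st$stable)
  expect_true(is.na(st$equilibration_time))

  const <- trajectory_series(seq(0, 10, 0.5), rep(0.3, 21))
  st2 <- assess_stability(const)
  expect_true(st2$stable)
  expect_equal(st2$equilibration_time, 0)

  expect_error(assess_stability(trajectory_series(0:3, rep(0, 4))), "window")
})

test_that("stability is monotone in the threshold", {
  spec <- synthetic_spec(seed = 33, trajectory_params = list(noise_sd = 0.05))
  s <- sim_trajectory(spec)
  thresholds <- c(0.1, 0.2, 0.3, 0.5)
  stable <- vapply(thresholds,
                   function(th) assess_stability(s, threshold = th)$stable,
                   logical(1))
  expect_true(all(diff(stable) >= 0))  # once stable, stays stable
})

test_that("MM/PBSA totals reproduce the published component table", {
  tbl <- readr::read_tsv(system.file("extdata", "mmpbsa_components.tsv",
                                     package = "herbnet"),
                         show_col_types = FALSE)
  filled <- mmpbsa_totals(tbl[c("complex", "vdw", "cou", "pb", "sa",
                                "minus_t_delta_s")])
  expect_true(all(abs(filled$delta_g - tbl$delta_g) <= 0.0105))
  expect_true(all(abs(filled$delta_h - tbl$delta_h) <= 0.0105))
  expect_true(all(abs(filled$mm - tbl$mm) <= 0.0105))
  # validation mode accepts the pre-rounded printed totals
  expect_silent(mmpbsa_totals(tbl, validate = TRUE))
  broken <- tbl
  broken$delta_g[1] <- broken$delta_g[1] + 1
  expect_error(mmpbsa_totals(broken, validate = TRUE), "delta_g")
})

test_that("MM/PBSA bookkeeping round-trips and handles zeros", {
  zero <- tibble::tibble(vdw = 0, cou = 0, pb = 0, sa = 0,
                         minus_t_delta_s = 0)
  filled <- mmpbsa_totals(zero)
  expect_equal(unlist(filled[c("mm", "delta_h", "delta_g")]),
               c(mm = 0, delta_h = 0, delta_g = 0))
  again <- mmpbsa_totals(filled, validate = TRUE)
  expect_identical(again, filled)
  expect_error(mmpbsa_totals(zero[-1]), "vdw")
})

test_that("residue fractions recover planted values and add up", {
  spec <- synthetic_spec(seed = 12)
  dec <- sim_residue_decomposition(spec, n_residues = 50,
                                   planted_residues = c(4, 9, 16, 25),
                                   planted_fraction = 0.429)
  total <- attr(dec, "total_delta_h")
  expect_equal(residue_fraction(dec, c(4, 9, 16, 25), total), 42.9,
               tolerance = 1e-9)
  # additivity over disjoint residue sets
  fa <- residue_fraction(dec, 1:3, total)
  fb <- residue_fraction(dec, 10:12, total)
  expect_equal(fa + fb, residue_fraction(dec, c(1:3, 10:12), total))
  # single residue equal to the total
  one <- tibble::tibble(residue = 1L, delta_h = -12.5)
  expect_equal(residue_fraction(one, 1, -12.5), 100)
  expect_error(residue_fraction(one, 2, -12.5), "unknown")
  expect_error(residue_fraction(one, 1, 0), "nonzero")
})

test_that("kJ/mol decompositions convert before dividing", {
  kcal <- tibble::tibble(residue = 1:2, delta_h = c(-1, -2))
  kj <- tibble::tibble(residue = 1:2, delta_h = c(-1, -2) * 4.184)
  expect_equal(residue_fraction(kj, 1, -3, unit = "kJ/mol"),
               residue_fraction(kcal, 1, -3))
})

test_that("XVG reader skips headers and converts ps to ns", {
  xvg <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c(
    "# GROMACS-style comment",
    "@    title \"RMSD\"",
    "@ xaxis  label \"Time (ps)\"",
    "0.0    0.001",
    "1000.0    0.150",
    "2000.0    0.210"
  ), xvg)
  s <- read_xvg(xvg, time_unit = "ps")
  expect_equal(s$time, c(0, 1, 2))
  expect_equal(s$value[3], 0.21)
  expect_error(read_xvg(withr::local_tempfile(lines = "@ only headers")),
               "no data")
})
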