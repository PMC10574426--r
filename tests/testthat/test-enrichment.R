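test_that("hypergeometric upper tail matches hand-enumerated fractions", {
  expect_equal(hypergeom_upper(10, 4, 3, 2), 1 / 3)
  expect_equal(hypergeom_upper(5, 2, 2, 2), 1 / 10)
  expect_equal(hypergeom_upper(10, 4, 3, 0), 1)
  expect_error(hypergeom_upper(10, 11, 3, 1), "infeasible")
  expect_error(hypergeom_upper(10, 4, 3, 4), "infeasible")
})

test_that("hypergeometric upper tail equals exhaustive enumeration, N <= 12", {
  for (N in c(5, 8, 12)) {
    for (K in c(1, N %/% 2, N - 1)) {
      for (n in c(1, N %/% 2)) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeom_upper(N, K, n, k),
                       bf_hypergeom_upper(N, K, n, k),
                       tolerance = 1e-12,
                       info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("BH adjustment matches the hand-evaluated step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.05, 4)), rep(0.05, 4))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("BH adjustment is monotone and bounded", {
  withr::with_seed(1, {
    for (rep in 1:20) {
      p <- stats::runif(sample(1:30, 1))
      adj <- bh_adjust(p)
      expect_true(all(adj >= p - 1e-15))
      expect_true(all(adj <= 1))
      expect_true(all(diff(adj[order(p)]) >= -1e-15))  # order respected
    }
  })
})

make_collection <- function(study, background, n_null = 10, seed = 99) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_null), function(i) {
      tibble::tibble(term_id = sprintf("N%02d", i),
                     term_name = sprintf("null %02d", i),
                     category = sample(c("KEGG", "BP", "CC", "MF"), 1),
                     genes = list(sample(background, 20)))
    }))
  })
}

test_that("ORA drops zero-overlap terms and sorts by adjusted p", {
  bg <- sprintf("G%03d", 1:100)
  study <- bg[1:10]
  coll <- dplyr::bind_rows(
    tibble::tibble(term_id = "hit", term_name = "hit", category = "KEGG",
                   genes = list(bg[1:10])),
    tibble::tibble(term_id = "miss", term_name = "miss", category = "KEGG",
                   genes = list(bg[51:60]))
  )
  res <- run_ora(study, coll, background = bg, alpha = 1)
  expect_equal(res$term_id, "hit")
  expect_equal(res$count, 10)
  expect_equal(res$gene_ratio * res$n_study, res$count)
  expect_error(run_ora(c("ZZZ"), coll, background = bg), "background")
})

test_that("planted term at full effect ranks first below alpha", {
  spec <- synthetic_spec(seed = 8, n_terms = 25,
                         planted_terms = list(list(term_id = "T0001",
                                                   size = 40, effect = 1)))
  bg <- sprintf("G%06d", 1:500)
  study <- bg[1:50]
  coll <- sim_annotations(spec, study, bg)
  res <- run_ora(study, coll, background = bg, alpha = 0.05, top_k = 20)
  kegg <- res[res$category == "KEGG", ]
  expect_equal(kegg$term_id[1], "T0001")
  expect_lt(kegg$p_adjust[1], 0.05)
})

test_that("adjustment is applied within each category separately", {
  bg <- sprintf("G%03d", 1:60)
  study <- bg[1:10]
  coll <- dplyr::bind_rows(
    tibble::tibble(term_id = "k1", term_name = "k1", category = "KEGG",
                   genes = list(bg[1:10])),
    tibble::tibble(term_id = "b1", term_name = "b1", category = "BP",
                   genes = list(bg[1:10]))
  )
  res <- run_ora(study, coll, background = bg, alpha = 1)
  # each category has m = 1 tested term, so p_adjust equals the raw p
  expect_equal(res$p_adjust, res$p_value)
})

test_that("top_k truncates per category after sorting", {
  bg <- sprintf("G%03d", 1:100)
  study <- bg[1:20]
  coll <- dplyr::bind_rows(lapply(1:6, function(i) {
    tibble::tibble(term_id = sprintf("k%d", i), term_name = sprintf("k%d", i),
                   category = "KEGG", genes = list(bg[seq_len(10 + i)]))
  }))
  res <- run_ora(study, coll, background = bg, alpha = 1, top_k = 3)
  expect_equal(nrow(res), 3)
  expect_true(all(diff(res$p_adjust) >= 0))
})

test_that("ORA null exceedance matches its exact discrete level", {
  # Conservative discrete test: the exact attainable level P(p < 0.05) is
  # computed analytically per term size and the simulation must agree with
  # it to binomial 99% accuracy (and never exceed nominal anticonservatively).
  bg <- sprintf("G%06d", 1:500)
  study <- bg[1:50]
  n_sig <- 0L; n_tested <- 0L; e_sig <- 0; e_tested <- 0
  for (r in 1:100) {
    spec <- synthetic_spec(seed = 10000 + r, planted_terms = list(),
                           n_terms = 20)
    coll <- sim_annotations(spec, study, bg)
    res <- run_ora(study, coll, background = bg, alpha = 1.0000001)
    n_sig <- n_sig + sum(res$p_value < 0.05)
    n_tested <- n_tested + nrow(res)
    sizes <- vapply(coll$genes, length, integer(1))
    for (K in sizes) {
      k <- 1:min(K, 50)
      pk <- stats::dhyper(k, K, 500 - K, 50)
      pup <- stats::phyper(k - 1, K, 500 - K, 50, lower.tail = FALSE)
      e_sig <- e_sig + sum(pk[pup < 0.05])
      e_tested <- e_tested + sum(pk)
    }
  }
  level <- e_sig / e_tested
  half_width <- stats::qnorm(0.995) * sqrt(level * (1 - level) / n_tested)
  expect_gt(n_sig / n_tested, level - half_width)
  expect_lt(n_sig / n_tested, level + half_width)
  expect_lt(n_sig / n_tested, 0.05 + half_width)  # never anti-conservative
})
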