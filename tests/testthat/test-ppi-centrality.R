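test_that("edge confidence filter is strict and collapses duplicates", {
  tbl <- tibble::tibble(
    node1 = c("A", "A", "B", "A"),
    node2 = c("B", "C", "A", "D"),
    combined_score = c(0.90, 0.95, 0.97, 0.5)
  )
  g <- graph_from_string_edges(tbl, min_score = 0.9)
  expect_equal(igraph::ecount(g), 2)  # A-B at 0.90 dropped once, kept at 0.97
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))

  with_universe <- graph_from_string_edges(tbl, nodes = c("A", "B", "C", "Z"))
  expect_true("Z" %in% igraph::V(with_universe)$name)

  scaled <- tibble::tibble(node1 = "A", node2 = "B", combined_score = 950)
  expect_equal(igraph::ecount(graph_from_string_edges(scaled)), 1)

  bad <- tibble::tibble(node1 = c("A", NA), node2 = c("B", "C"),
                        combined_score = c(0.95, 0.95))
  expect_error(graph_from_string_edges(bad), "row")
})

test_that("centralities match hand-derived values on canonical graphs", {
  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("a", "b", "c")
  ct <- ppi_centralities(k3)
  expect_equal(ct$bc, c(0, 0, 0))
  expect_equal(ct$dc, c(2, 2, 2))
  expect_equal(ct$lac, c(1, 1, 1))
  expect_equal(ct$nc, c(2, 2, 2))
  expect_equal(ct$ec, rep(1 / sqrt(3), 3), tolerance = 1e-9)

  star <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3")
  ct_star <- ppi_centralities(star)
  expect_equal(ct_star$bc[1], 3)
  expect_equal(ct_star$lac[1], 0)
  expect_equal(ct_star$nc[1], 0)

  path <- igraph::make_graph(~ a - b, b - c)
  ct_path <- ppi_centralities(path)
  expect_equal(ct_path$bc[ct_path$node == "b"], 1)
  expect_equal(ct_path$cc[ct_path$node == "b"], 1)
  expect_equal(ct_path$cc[ct_path$node == "a"], 2 / 3)
})

test_that("all six centralities agree with brute force on random graphs", {
  withr::with_seed(2024, {
    for (rep in 1:60) {
      n <- sample(2:8, 1)
      A <- random_adjacency(n, stats::runif(1, 0.1, 0.9))
      ct <- ppi_centralities(graph_from_adjacency(A))
      ord <- match(as.character(seq_len(n)), ct$node)
      expect_equal(ct$bc[ord], bf_betweenness(A))
      expect_equal(ct$dc[ord], unname(rowSums(A)))
      expect_equal(ct$lac[ord], bf_lac(A))
      expect_equal(ct$nc[ord], bf_nc(A))
      expect_equal(ct$cc[ord], bf_closeness(A), tolerance = 1e-9)
      expect_equal(ct$ec[ord], bf_eigenvector(A), tolerance = 1e-9)
    }
  })
})

test_that("median key-target rule handles boundaries deterministically", {
  one <- tibble::tibble(node = "a", bc = 1, cc = 1, dc = 1, ec = 1,
                        lac = 1, nc = 1)
  expect_equal(select_key_targets(one), "a")

  same <- tibble::tibble(node = c("a", "b", "c"), bc = 2, cc = 2, dc = 2,
                         ec = 2, lac = 2, nc = 2)
  expect_setequal(select_key_targets(same), c("a", "b", "c"))

  # one node strictly below the median on exactly one metric
  tbl <- tibble::tibble(node = c("a", "b", "c"),
                        bc = c(5, 5, 5), cc = c(1, 1, 1), dc = c(3, 3, 3),
                        ec = c(0.5, 0.5, 0.5), lac = c(2, 2, 2),
                        nc = c(1, 2, 2))
  expect_setequal(select_key_targets(tbl), c("b", "c"))
})

test_that("key-target selection is row-order invariant and contains the argmax", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      n <- sample(3:15, 1)
      tbl <- tibble::tibble(
        node = sprintf("n%02d", seq_len(n)),
        bc = stats::runif(n), cc = stats::runif(n), dc = stats::runif(n),
        ec = stats::runif(n), lac = stats::runif(n), nc = stats::runif(n))
      shuffled <- tbl[sample(n), ]
      expect_identical(select_key_targets(tbl), select_key_targets(shuffled))
      expect_identical(select_key_targets(tbl), bf_key_targets(tbl))
      # a node that is argmax on all six metrics is always selected
      winner <- tbl
      winner[1, c("bc", "cc", "dc", "ec", "lac", "nc")] <- 2
      expect_true("n01" %in% select_key_targets(winner))
    }
  })
})

test_that("degenerate graphs are handled", {
  expect_error(ppi_centralities(igraph::make_empty_graph(0, directed = FALSE)),
               "empty")
  lone <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(lone)$name <- "a"
  ct <- ppi_centralities(lone)
  expect_equal(unlist(ct[1, -1]), c(bc = 0, cc = 0, dc = 0, ec = 0,
                                    lac = 0, nc = 0))
})
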