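# Disconnectivity graphs: union-find semantics, ultrametric structure,
# oracle equivalence against minimax paths, display operations.

test_that("elementary graphs build as expected", {
  g <- build_graph(data.frame(id = 1:2, energy = c(-10, -8)),
                   data.frame(a = 1, b = 2, lid = -4), seq(-10, 0, 2))
  expect_equal(nrow(g$leaves), 2)
  expect_equal(sum(!g$nodes$leaf), 1)
  expect_equal(merge_energy(g, 1, 2), -4)
  # no connections: a forest of isolated leaves
  g2 <- build_graph(data.frame(id = 1:3, energy = c(-5, -4, -3)),
                    data.frame(a = integer(0), b = integer(0),
                               lid = numeric(0)), seq(-5, 0, 1))
  expect_equal(length(g2$roots), 3)
  expect_equal(merge_energy(g2, 1, 3), Inf)
  # two-level merge
  g3 <- build_graph(data.frame(id = 1:4, energy = c(-10, -9, -8, -7)),
                    data.frame(a = c(1, 3, 1), b = c(2, 4, 3),
                               lid = c(-8, -6, -2)), seq(-10, 0, 1))
  expect_equal(merge_energy(g3, 1, 2), -8)
  expect_equal(merge_energy(g3, 3, 4), -6)
  expect_equal(merge_energy(g3, 2, 4), -2)
})

test_that("data errors are caught", {
  m <- data.frame(id = 1:2, energy = c(-10, -8))
  expect_error(build_graph(m, data.frame(a = 1, b = 9, lid = -4),
                           seq(-10, 0, 2)), "unknown minimum")
  expect_error(build_graph(m, data.frame(a = 1, b = 2, lid = -4.7),
                           seq(-10, 0, 2)), "on the grid")
  expect_error(build_graph(m, data.frame(a = 1, b = 2, lid = -10),
                           seq(-10, 0, 2)), "below")
})

test_that("leaf-pair merge energies equal the Floyd-Warshall minimax oracle", {
  set.seed(17)
  for (rep in 1:100) {
    n <- sample(3:8, 1)
    rc <- random_connection_set(n)
    g <- build_graph(rc$minima, rc$connections, rc$grid)
    D <- minimax_oracle(rc$minima$id, rc$connections)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      oracle <- D[i, j]
      got <- merge_energy(g, i, j)
      if (is.infinite(oracle)) {
        expect_equal(got, Inf)
      } else {
        # graph merges happen on the grid: the merge energy is the smallest
        # grid value at or above the minimax path value
        snapped <- rc$grid[min(which(rc$grid >= oracle - 1e-9))]
        expect_equal(got, snapped, tolerance = 1e-9)
      }
    }
  }
})

test_that("merge energies are ultrametric on all built graphs", {
  set.seed(23)
  for (rep in 1:20) {
    rc <- random_connection_set(sample(4:8, 1))
    g <- build_graph(rc$minima, rc$connections, rc$grid)
    n <- nrow(rc$minima)
    trip <- combn(n, 3)
    for (t in seq_len(ncol(trip))) {
      e <- sort(c(merge_energy(g, trip[1, t], trip[2, t]),
                  merge_energy(g, trip[1, t], trip[3, t]),
                  merge_energy(g, trip[2, t], trip[3, t])),
                decreasing = TRUE)
      expect_true((is.infinite(e[1]) && is.infinite(e[2])) ||
                    abs(e[1] - e[2]) < 1e-9)
    }
  }
})

test_that("the graph is independent of connection-event ordering", {
  set.seed(29)
  rc <- random_connection_set(7)
  g1 <- build_graph(rc$minima, rc$connections, rc$grid)
  perm <- sample(nrow(rc$connections))
  g2 <- build_graph(rc$minima, rc$connections[perm, ], rc$grid)
  for (i in 1:6) for (j in (i + 1):7) {
    expect_equal(merge_energy(g1, i, j), merge_energy(g2, i, j))
  }
})

test_that("display truncation removes only minima above the landmark limit", {
  minima <- data.frame(id = 1:4, energy = c(-10, -9, -8, -7))
  conn <- data.frame(a = c(1, 1, 1), b = c(2, 3, 4), lid = c(-6, -4, -1))
  g <- build_graph(minima, conn, seq(-10, 0, 1))
  tr <- truncate_display(g, landmarks = c(1, 3)) # limit = merge(1,3) = -4
  expect_true(all(c(1, 2, 3) %in% tr$leaves$id))
  expect_false(4 %in% tr$leaves$id) # connects only at -1 > limit
  expect_false(is.null(attr(tr, "full_graph")))
  expect_true(4 %in% attr(tr, "full_graph")$leaves$id)
  # all below the limit: unchanged
  tr2 <- truncate_display(g, landmarks = c(1, 4))
  expect_equal(sort(tr2$leaves$id), 1:4)
})

test_that("landmark simplification contracts chains but preserves merges", {
  # one landmark with many satellites: a single branch remains
  n <- 18
  minima <- data.frame(id = 1:n, energy = c(-20, rep(-15, n - 2), -19))
  conn <- rbind(
    data.frame(a = 1, b = 2:(n - 1), lid = -12), # 16 satellites join low
    data.frame(a = 1, b = n, lid = -2)           # second landmark joins high
  )
  g <- build_graph(minima, conn, seq(-20, 0, 1))
  gs <- simplify_to_landmarks(g, c(1, n))
  expect_equal(sort(gs$leaves$id), c(1, n))
  expect_equal(merge_energy(gs, 1, n), merge_energy(g, 1, n))
  # landmarks = all leaves: merge energies unchanged
  gall <- simplify_to_landmarks(g, 1:n)
  expect_equal(merge_energy(gall, 2, 3), merge_energy(g, 2, 3))
})

test_that("plotting produces a layout grouping low-barrier siblings", {
  minima <- data.frame(id = 1:4, energy = c(-10, -9, -8, -7))
  conn <- data.frame(a = c(1, 3, 1), b = c(2, 4, 3), lid = c(-8, -6, -2))
  g <- build_graph(minima, conn, seq(-10, 0, 1))
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f)
  xpos <- plot(g, color_by = c(`1` = 1, `2` = 2, `3` = 3, `4` = 4))
  grDevices::dev.off()
  expect_true(file.exists(f))
  # siblings 1,2 adjacent and 3,4 adjacent in the layout
  expect_equal(abs(xpos[1] - xpos[2]), 1)
  expect_equal(abs(xpos[3] - xpos[4]), 1)
  # serialization round structure
  lst <- graph_to_list(g)
  expect_equal(length(lst$leaves), 4)
  expect_equal(length(lst$nodes), 3)
})
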