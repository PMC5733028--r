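test_that("independent steps produce no arcs; shared edges produce weak arcs", {
  # two chromosomes, each sorted by one op acting on its own component
  gs <- parse_genomes(">P\n+a +b @\n+c +d @\n>Q\n+a -b @\n+c -d @\n")
  t <- sort_scenario(gs[[1]], gs[[2]])
  expect_equal(scenario_length(t), 2L)
  dg <- build_dependency_graph(t)
  expect_equal(nrow(dg$arcs), 0L)

  # transposition pair: two weakly dependent steps, a single weak arc
  tp <- transposition_pair()
  t2 <- sort_scenario(tp$P, tp$Q)
  expect_equal(scenario_length(t2), 2L)
  dg2 <- build_dependency_graph(t2)
  expect_equal(nrow(dg2$arcs), 1L)
  expect_equal(dg2$arcs$weight, 1L)
  expect_equal(dg2$arcs$from, 1L)
  expect_equal(dg2$arcs$to, 2L)
})

test_that("the worked-example scenario has at least 2d - s = 3 arcs", {
  fp <- fig_pair()
  t <- sort_scenario(fp$P, fp$Q)
  dg <- build_dependency_graph(t)
  expect_true(nrow(dg$arcs) >= 3L)
  expect_true(all(dg$arcs$from < dg$arcs$to))  # scenario order is topological
  expect_true(all(tabulate(dg$arcs$from, dg$n_steps) <= 2L))
  expect_true(all(tabulate(dg$arcs$to, dg$n_steps) <= 2L))
})

test_that("shortcut detection distinguishes transitive arcs", {
  tri <- fake_dg(3, from = c(1, 2, 1), to = c(2, 3, 3))
  expect_true(is_shortcut(tri, 1, 3))
  expect_false(is_shortcut(tri, 1, 2))
  expect_false(is_shortcut(tri, 2, 3))
  single <- fake_dg(2, from = 1, to = 2)
  expect_false(is_shortcut(single, 1, 2))
  path <- fake_dg(3, from = c(1, 2), to = c(2, 3))
  expect_false(is_shortcut(path, 1, 2))
  expect_error(is_shortcut(path, 1, 3), "no arc")
  long <- fake_dg(4, from = c(1, 2, 3, 1), to = c(2, 3, 4, 4))
  expect_true(is_shortcut(long, 1, 4))
})

test_that("T1 swaps exchange independent neighbors and refuse dependent ones", {
  gs <- parse_genomes(">P\n+a +b @\n+c +d @\n>Q\n+a -b @\n+c -d @\n")
  t <- sort_scenario(gs[[1]], gs[[2]])
  t2 <- t1_swap(t, 1)
  expect_true(scenario_sorts(t2))
  expect_equal(dg_sig(t2), dg_sig(t))  # dependency graph unchanged
  expect_identical(step_sig(t2$steps[[1]]), step_sig(t$steps[[2]]))

  tp <- transposition_pair()
  tw <- sort_scenario(tp$P, tp$Q)
  expect_error(t1_swap(tw, 1), "dependent")
  expect_error(t1_swap(tw, 5), "out of range")
})

test_that("T1 closure of a scenario equals the topological orders of its DG", {
  # interconvertibility property, checked exhaustively on short scenarios
  for (seed in c(2, 5, 9)) {
    pr <- random_pair(5, seed = 300 + seed)
    t <- sort_scenario(pr$P, pr$Q, seed = seed, policy = "random")
    L <- scenario_length(t)
    if (L < 2L || L > 5L) next
    dg <- build_dependency_graph(t)
    # closure under T1 swaps
    seen <- new.env(parent = emptyenv())
    queue <- list(list(t = t, perm = seq_len(L)))
    seen[[paste(seq_len(L), collapse = ",")]] <- TRUE
    reached <- list(seq_len(L))
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (i in seq_len(L - 1L)) {
        ok <- tryCatch({
          t_next <- t1_swap(cur$t, i)
          TRUE
        }, error = function(e) FALSE)
        if (!ok) next
        perm <- cur$perm
        perm[c(i, i + 1L)] <- perm[c(i + 1L, i)]
        key <- paste(perm, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          reached[[length(reached) + 1L]] <- perm
          queue[[length(queue) + 1L]] <- list(t = t_next, perm = perm)
          expect_true(scenario_sorts(t_next))
          expect_equal(dg_sig(t_next), dg_sig(t))
        }
      }
    }
    topo <- oracle_all_topo_orders(L, dg$arcs)
    reached_keys <- sort(vapply(reached, paste, "", collapse = ","))
    topo_keys <- sort(apply(topo, 1, paste, collapse = ","))
    expect_equal(reached_keys, topo_keys)
  }
})

test_that("reorder_with_adjacency makes matched pairs adjacent and is
           T1-faithful", {
  fp <- fig_pair()
  t <- sort_scenario(fp$P, fp$Q)
  dg <- build_dependency_graph(t)
  # pick a non-shortcut arc
  ok_arcs <- which(!vapply(seq_len(nrow(dg$arcs)), function(r) {
    is_shortcut(dg, dg$arcs$from[r], dg$arcs$to[r])
  }, TRUE))
  arc <- dg$arcs[ok_arcs[1], ]
  t2 <- reorder_with_adjacency(t, arc[, c("from", "to")])
  ord <- attr(t2, "order")
  pa <- match(arc$from, ord)
  expect_equal(ord[pa + 1L], arc$to)
  expect_true(scenario_sorts(t2))
  expect_equal(dg_sig(t2), dg_sig(t))
  # the audit trail replays to the same order
  swaps <- attr(t2, "t1_swaps")
  t3 <- t
  for (r in seq_len(nrow(swaps))) t3 <- t1_swap(t3, swaps[r, 1])
  expect_identical(order_sig(t3), order_sig(t2))
})

test_that("reorder_with_adjacency handles empty and already-adjacent matchings", {
  fp <- fig_pair()
  t <- sort_scenario(fp$P, fp$Q)
  t_same <- reorder_with_adjacency(t, data.frame(from = integer(0), to = integer(0)))
  expect_identical(order_sig(t_same), order_sig(t))
  dg <- build_dependency_graph(t)
  adj <- dg$arcs[dg$arcs$to == dg$arcs$from + 1L, ]
  if (nrow(adj)) {
    t_adj <- reorder_with_adjacency(t, adj[1, c("from", "to")])
    expect_identical(order_sig(t_adj), order_sig(t))
  }
  # a shortcut arc is rejected
  tri_t <- t
  expect_error(reorder_with_adjacency(t, data.frame(from = 1, to = 1)),
               "share a vertex|no arc")
})

test_that("shortcuts are exactly the arcs that can never become adjacent
           (exhaustive on labeled DAGs with up to 4 vertices)", {
  mismatches <- 0L
  for (n in 2:4) {
    for (arcs in oracle_all_dags(n)) {
      if (nrow(arcs) == 0L) next
      dg <- fake_dg(n, arcs$from, arcs$to)
      for (r in seq_len(nrow(arcs))) {
        sc <- is_shortcut(dg, arcs$from[r], arcs$to[r])
        adj <- oracle_adjacent_in_some_topo(n, arcs, arcs$from[r], arcs$to[r])
        if (sc != !adj) mismatches <- mismatches + 1L
      }
    }
  }
  expect_identical(mismatches, 0L)
})
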