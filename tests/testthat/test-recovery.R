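test_that("layered_forest keeps one previous-layer arc per non-source vertex", {
  empty <- fake_dg(3, integer(0), integer(0))
  expect_equal(nrow(layered_forest(empty)$arcs), 0L)

  path <- fake_dg(3, from = c(1, 2), to = c(2, 3))
  lf <- layered_forest(path)
  expect_equal(nrow(lf$arcs), 2L)

  tri <- fake_dg(3, from = c(1, 2, 1), to = c(2, 3, 3))
  lf2 <- layered_forest(tri)
  expect_equal(nrow(lf2$arcs), 2L)  # |V| - #sources = 3 - 1
  kept <- paste(lf2$arcs$from, lf2$arcs$to)
  expect_true(all(kept %in% c("1 2", "2 3")))  # the shortcut (1,3) is excluded
  # kept arcs are never shortcuts in the original graph
  for (r in seq_len(nrow(lf2$arcs))) {
    expect_false(is_shortcut(tri, lf2$arcs$from[r], lf2$arcs$to[r]))
  }
})

test_that("greedy leaf matching meets the ceiling(e/degree) guarantee", {
  expect_equal(nrow(greedy_matching(fake_dg(2, integer(0), integer(0)), 3)), 0L)
  expect_equal(nrow(greedy_matching(fake_dg(2, 1, 2), 3)), 1L)
  p3 <- fake_dg(4, from = c(1, 2, 3), to = c(2, 3, 4))
  m <- greedy_matching(p3, 4)
  expect_equal(nrow(m), 2L)  # brute-force maximum for a 3-arc path
  expect_true(nrow(m) >= ceiling(3 / 4))
  expect_false(anyDuplicated(c(m$from, m$to)) > 0)
  # a cycle is not a forest
  cyc <- fake_dg(3, from = c(1, 2, 1), to = c(2, 3, 3))
  expect_error(greedy_matching(cyc, 4), "not a forest")
  # degree bound is enforced
  star <- fake_dg(5, from = c(1, 1, 1, 1), to = c(2, 3, 4, 5))
  expect_error(greedy_matching(star, 3), "degree")
  expect_equal(nrow(greedy_matching(star, 4)), 1L)
})

test_that("DIT bounds follow the ceiling formulas with a witnessing matching", {
  g <- random_genome(5, 1, 0.5, seed = 2)
  empty <- sort_scenario(g, g)
  expect_equal(dit_lower_bound(empty, "shortest")$bound, 0L)
  expect_equal(dit_lower_bound(empty, "proper")$bound, 0L)

  fp <- fig_pair()
  t <- sort_scenario(fp$P, fp$Q)
  b <- dit_lower_bound(t, "shortest")
  expect_equal(b$e, 3L)
  expect_equal(b$bound, 1L)  # ceiling(3/4)
  expect_true(nrow(b$matching) >= b$bound)
  bp <- dit_lower_bound(t, "proper")
  expect_equal(bp$bound, 1L)  # ceiling(3/6)
  expect_true(nrow(bp$matching) >= bp$bound)
  # shortest mode refuses non-shortest scenarios
  pr <- random_pair(8, seed = 123)
  det <- detour_scenario(pr$P, pr$Q, extra = 1, seed = 4)
  expect_error(dit_lower_bound(det, "shortest"), "minimum length")
})

test_that("a weakly dependent pair merges into a genuine 3-break", {
  tp <- transposition_pair()
  t <- sort_scenario(tp$P, tp$Q)
  dg <- build_dependency_graph(t)
  ms <- recover_transpositions(t, dg$arcs[, c("from", "to")])
  expect_equal(length(ms$steps), 1L)
  expect_equal(ms$dit, 1L)
  expect_equal(ms$rate, 1)
  tb <- ms$steps[[1]]
  expect_s3_class(tb, "threebreak_op")
  expect_length(tb$removed, 3L)
  expect_length(tb$created, 3L)
  # same six endpoints
  ends <- function(recs) sort(unlist(lapply(recs, function(e) c(e$v1, e$v2))))
  expect_equal(ends(tb$removed), ends(tb$created))
  expect_true(mixed_sorts(ms))
})

test_that("recovery with an empty matching returns the original scenario", {
  fp <- fig_pair()
  t <- sort_scenario(fp$P, fp$Q)
  ms <- recover_transpositions(t, data.frame(from = integer(0), to = integer(0)))
  expect_equal(length(ms$steps), scenario_length(t))
  expect_equal(ms$dit, 0L)
  expect_equal(ms$rate, 0)
  expect_true(mixed_sorts(ms))
})

test_that("the worked-example recovery yields a rate of one third", {
  fp <- fig_pair()
  t <- sort_scenario(fp$P, fp$Q)
  b <- dit_lower_bound(t, "shortest")
  ms <- recover_transpositions(t, b$matching[1, , drop = FALSE])
  expect_equal(length(ms$steps), 3L)
  expect_equal(ms$rate, 1 / 3)
  expect_true(mixed_sorts(ms))
})

test_that("implicit_rate arithmetic, degenerate cases and monotonicity", {
  expect_equal(implicit_rate(1, 4), 1 / 3)
  expect_equal(implicit_rate(0, 7), 0)
  expect_equal(implicit_rate(2, 4), 1)
  expect_equal(implicit_rate(0, 0), 0)
  expect_error(implicit_rate(3, 4), "at most")
  rates <- vapply(0:5, implicit_rate, 0, length = 10)
  expect_true(all(diff(rates) > 0))
})

test_that("genome-only rate bounds match the closed forms", {
  fp <- fig_pair()
  expect_equal(rate_bound_proper(fp$P, fp$Q), 1 / 7)
  expect_equal(rate_bound_shortest(fp$P, fp$Q), 1 / 3)
  sp <- swap_pair()
  expect_equal(rate_bound_proper(sp$P, sp$Q), 0)
  expect_equal(rate_bound_shortest(sp$P, sp$Q), 0)
  g <- random_genome(6, 1, 0.5, seed = 3)
  expect_equal(rate_bound_proper(g, g), 0)
  expect_equal(rate_bound_shortest(g, g), 0)
})

test_that("brute-force DIT dominates the constructive bounds on short
           scenarios and equals hand values", {
  g <- random_genome(5, 1, 0.5, seed = 2)
  expect_equal(max_dit_bruteforce(sort_scenario(g, g)), 0L)
  tp <- transposition_pair()
  expect_equal(max_dit_bruteforce(sort_scenario(tp$P, tp$Q)), 1L)
  found <- 0L
  for (i in 1:20) {
    pr <- random_pair(6, seed = 600 + i)
    t <- sort_scenario(pr$P, pr$Q, seed = i, policy = "random")
    if (scenario_length(t) > 8L) next
    found <- found + 1L
    mx <- max_dit_bruteforce(t)
    expect_true(mx >= dit_lower_bound(t, "shortest")$bound)
    expect_true(mx >= dit_lower_bound(t, "proper")$bound)
  }
  expect_true(found >= 5L)
})

test_that("recovered scenarios transform source to target at the right length
           and at or above the genome-only bound", {
  for (i in 1:15) {
    pr <- random_pair(10 + (i %% 8), seed = 900 + i)
    t <- sort_scenario(pr$P, pr$Q, seed = i, policy = "random")
    b <- dit_lower_bound(t, "shortest")
    ms <- recover_transpositions(t, b$matching)
    expect_equal(length(ms$steps), scenario_length(t) - nrow(b$matching))
    expect_true(mixed_sorts(ms))
    expect_true(ms$rate >= rate_bound_shortest(pr$P, pr$Q) - 1e-12)
    st <- component_stats(build_breakpoint_graph(pr$P, pr$Q))
    expect_true(b$e >= E_statistic(st))
    # every merged step is the composition of its two source DCJs
    for (stp in ms$steps) {
      if (inherits(stp, "threebreak_op")) {
        reg <- function(recs) {
          v <- unlist(lapply(recs, function(e) c(e$v1, e$v2)))
          sort(v[!grepl("^\\*", v)])
        }
        expect_equal(reg(stp$removed), reg(stp$created))
      }
    }
  }
})
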