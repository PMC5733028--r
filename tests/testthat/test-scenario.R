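test_that("sorting the worked-example pair takes 4 steps with one fission", {
  fp <- fig_pair()
  t <- sort_scenario(fp$P, fp$Q)
  expect_s3_class(t, "dcj_scenario")
  expect_equal(scenario_length(t), 4L)
  forms <- vapply(t$steps, `[[`, "", "form")
  expect_equal(sum(forms == "fission"), 1L)
  expect_equal(sum(forms == "fusion"), 0L)
  expect_true(scenario_sorts(t))
})

test_that("identical genomes yield the empty scenario", {
  g <- random_genome(6, 2, 0.5, seed = 11)
  t <- sort_scenario(g, g)
  expect_equal(scenario_length(t), 0L)
  expect_true(scenario_sorts(t))
})

test_that("the two-gene swap sorts in 2 steps with one fusion and one fission", {
  sp <- swap_pair()
  t <- sort_scenario(sp$P, sp$Q)
  expect_equal(scenario_length(t), 2L)
  forms <- vapply(t$steps, `[[`, "", "form")
  expect_equal(sum(forms == "fusion"), 1L)
  expect_equal(sum(forms == "fission"), 1L)
  expect_true(scenario_sorts(t))
})

test_that("sorted scenarios reach the distance with unit decrements and the
           exact fusion/fission counts", {
  for (i in 1:30) {
    n <- 8L + (i %% 23L)  # up to 30 genes
    pr <- random_pair(n, seed = 40L + i)
    st <- component_stats(build_breakpoint_graph(pr$P, pr$Q))
    d <- dcj_distance(pr$P, pr$Q)
    t <- sort_scenario(pr$P, pr$Q, seed = i, policy = "random")
    expect_equal(scenario_length(t), d)
    forms <- vapply(t$steps, `[[`, "", "form")
    expect_equal(sum(forms == "fusion"), st$p_odd_P)
    expect_equal(sum(forms == "fission"), st$p_odd_Q)
    # every prefix reduces the remaining distance by exactly one
    for (k in seq_len(min(d, 5L))) {
      bg_k <- replay_scenario(t, upto = k)
      expect_equal(dcjtrans:::stats_distance(component_stats(bg_k)), d - k)
    }
    expect_true(scenario_sorts(t))
  }
})

test_that("scenario construction is reproducible under seed and policy", {
  pr <- random_pair(12, seed = 77)
  t1 <- sort_scenario(pr$P, pr$Q, seed = 5, policy = "random")
  t2 <- sort_scenario(pr$P, pr$Q, seed = 5, policy = "random")
  expect_identical(write_scenario(t1), write_scenario(t2))
  d1 <- sort_scenario(pr$P, pr$Q)
  d2 <- sort_scenario(pr$P, pr$Q)
  expect_identical(write_scenario(d1), write_scenario(d2))
})

test_that("exhaustive enumeration agrees with the closed form on tiny pairs", {
  g <- parse_genomes(">G\n+a +b @\n")[[1]]
  expect_equal(lapply(enumerate_shortest_scenarios(g, g), scenario_length),
               list(0L))
  sp <- swap_pair()
  sc <- enumerate_shortest_scenarios(sp$P, sp$Q, cap = 5000)
  expect_false(attr(sc, "truncated"))
  expect_true(length(sc) >= 1L)
  expect_true(all(vapply(sc, scenario_length, 0L) == 2L))
  expect_true(all(vapply(sc, scenario_sorts, TRUE)))
  fp <- fig_pair()
  sc4 <- enumerate_shortest_scenarios(fp$P, fp$Q, cap = 200)
  expect_true(all(vapply(sc4, scenario_length, 0L) == 4L))
})

test_that("apply_dcj rejects stale ids, endpoint mismatches and reused ids", {
  fp <- fig_pair()
  bg <- build_breakpoint_graph(fp$P, fp$Q)
  t <- sort_scenario(fp$P, fp$Q)
  op1 <- t$steps[[1]]
  bg2 <- apply_dcj(bg, op1)
  expect_error(apply_dcj(bg2, op1), "not present|fresh")
  bad <- op1
  bad$removed[[1]]$v1 <- "a:h"
  bad$removed[[1]]$v2 <- "b:h"
  expect_error(apply_dcj(bg, bad), "mismatch|not present")
  # an internal DCJ preserves vertex degrees: every regular vertex keeps
  # exactly one black edge
  ends <- c(bg2$black$v1, bg2$black$v2)
  expect_false(anyDuplicated(ends[!grepl("^\\*", ends)]) > 0)
})

test_that("check_proper flags recreated adjacencies and strong dependence", {
  fp <- fig_pair()
  for (i in 1:5) {
    t <- sort_scenario(fp$P, fp$Q, seed = i, policy = "random")
    expect_true(check_proper(t)$is_proper)
  }
  # fission then refusion of the same adjacency: P1 (recreate) and P2
  # (second step removes both edges created by the first)
  g <- parse_genomes(">G\n+a +b @\n>H\n+a +b @\n")
  bg <- build_breakpoint_graph(g[[1]], g[[2]])
  row <- bg$black[bg$black$v1 == "b:h" | bg$black$v2 == "b:h", ][1, ]
  fis <- dcjtrans:::new_dcj(
    dcjtrans:::edge_records(row),
    list(list(id = 100L, v1 = row$v1, v2 = "*T90"),
         list(id = 101L, v1 = row$v2, v2 = "*T91")),
    "fission")
  fus <- dcjtrans:::new_dcj(
    list(list(id = 100L, v1 = row$v1, v2 = "*T90"),
         list(id = 101L, v1 = row$v2, v2 = "*T91")),
    list(list(id = 102L, v1 = row$v1, v2 = row$v2)),
    "fusion")
  bad <- dcjtrans:::new_scenario(g[[1]], g[[2]], list(fis, fus))
  rep <- check_proper(bad)
  expect_false(rep$is_proper)
  expect_true("P1" %in% rep$violations$condition)
  expect_true("P2" %in% rep$violations$condition)
  expect_true("P3" %in% rep$violations$condition)  # fission with no QQ-path
})

test_that("scenario serialization follows the REMOVE/CREATE grammar", {
  sp <- swap_pair()
  t <- sort_scenario(sp$P, sp$Q)
  lines <- write_scenario(t)
  expect_length(lines, 2L)
  expect_true(all(grepl("^REMOVE \\{.*\\} CREATE \\{.*\\}$", lines)))
  expect_true(any(grepl("\\*", lines)))  # telomeres print as *
})
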