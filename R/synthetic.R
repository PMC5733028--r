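# Seeded generators: random genomes, scramble histories with planted
# 3-breaks (ground truth for recovery experiments), and proper non-shortest
# "detour" scenarios.

#' Generate a random genome
#'
#' Genes are labeled `g1 ... gn`, permuted and signed at random, then split
#' into `chroms` non-empty chromosomes; each chromosome is circular with
#' probability `topology_mix`.
#'
#' @param n gene count.
#' @param chroms number of chromosomes (`1 <= chroms <= n`).
#' @param topology_mix probability that a chromosome is circular.
#' @param seed integer seed (`NULL` uses the ambient RNG).
#' @param name genome name.
#' @return a `dcj_genome`.
#' @export
random_genome <- function(n, chroms = 1L, topology_mix = 0.5, seed = NULL,
                          name = "random") {
  stopifnot(n >= 1L, chroms >= 1L)
  if (chroms > n) stop("chroms must not exceed n")
  with_seed(seed, {
    perm <- sample.int(n)
    signs <- sample(c("+", "-"), n, replace = TRUE)
    toks <- paste0(signs, "g", perm)
    cuts <- if (chroms > 1L) sort(sample(seq_len(n - 1L), chroms - 1L)) else integer(0)
    starts <- c(1L, cuts + 1L)
    ends <- c(cuts, n)
    chrs <- lapply(seq_len(chroms), function(i) {
      chromosome(toks[starts[i]:ends[i]],
                 circular = stats::runif(1) < topology_mix)
    })
    genome(chrs, name = name)
  })
}

#' Recipe for scrambling a genome
#'
#' Describes an evolutionary simulation: `k` rearrangement events of which
#' a fraction `transposition_prob` are planted as transpositions (3-breaks,
#' realized as ordered pairs of weakly dependent DCJs so that the
#' dependency-graph machinery sees them exactly as implicit
#' transpositions); the rest are single DCJs. The default
#' `transposition_prob = 0.1` mirrors the commonly cited estimate that
#' transpositions make up under 10% of rearrangements. `topology_mix` is a
#' convenience default for generating the base genome in paired pipelines.
#'
#' @param k number of events (>= 0).
#' @param transposition_prob fraction of events planted as 3-breaks.
#' @param seed integer seed.
#' @param topology_mix fraction of circular chromosomes for companion
#'   genome generation.
#' @return an object of class `scramble_recipe`.
#' @export
scramble_recipe <- function(k, transposition_prob = 0.1, seed = NULL,
                            topology_mix = 0.5) {
  stopifnot(k >= 0, transposition_prob >= 0, transposition_prob <= 1)
  structure(list(k = as.integer(k), transposition_prob = transposition_prob,
                 seed = seed, topology_mix = topology_mix),
            class = "scramble_recipe")
}

# state: data.frame(id, v1, v2) of adjacencies of a single genome,
# telomeres as unique "*S<k>" vertices
random_dcj_event <- function(state, counters) {
  ne <- nrow(state)
  repeat {
    if (ne >= 2L && stats::runif(1) < 0.9) {
      rows <- sample.int(ne, 2L)
      a <- state$v1[rows[1L]]; b <- state$v2[rows[1L]]
      c_ <- state$v1[rows[2L]]; d <- state$v2[rows[2L]]
      pairing <- if (stats::runif(1) < 0.5) list(c(a, c_), c(b, d)) else
        list(c(a, d), c(b, c_))
      keep <- Filter(function(pr) !(is_telomere(pr[1]) && is_telomere(pr[2])),
                     pairing)
      if (length(keep) == 2L &&
          sum(vapply(keep, function(pr) any(is_telomere(pr)), TRUE)) == 2L) {
        next  # telomere swap no-op; resample
      }
      ids <- counters$next_id + seq_along(keep) - 1L
      counters$next_id <- counters$next_id + length(keep)
      removed <- edge_records(state[rows, ])
      created <- lapply(seq_along(keep), function(kk) {
        list(id = ids[kk], v1 = keep[[kk]][1], v2 = keep[[kk]][2])
      })
      return(new_dcj(removed, created, classify_form(removed, created)))
    }
    # fission of a regular adjacency
    reg <- which(!is_telomere(state$v1) & !is_telomere(state$v2))
    if (length(reg) == 0L) next
    row <- reg[sample.int(length(reg), 1L)]
    removed <- edge_records(state[row, , drop = FALSE])
    ids <- counters$next_id + 0:1
    counters$next_id <- counters$next_id + 2L
    t1 <- paste0("*S", counters$next_tel)
    t2 <- paste0("*S", counters$next_tel + 1L)
    counters$next_tel <- counters$next_tel + 2L
    created <- list(list(id = ids[1L], v1 = state$v1[row], v2 = t1),
                    list(id = ids[2L], v1 = state$v2[row], v2 = t2))
    return(new_dcj(removed, created, "fission"))
  }
}

apply_event <- function(state, op) {
  rm_ids <- step_ids(op, "removed")
  state <- state[!state$id %in% rm_ids, , drop = FALSE]
  add <- data.frame(id = step_ids(op, "created"),
                    v1 = vapply(op$created, `[[`, "", "v1"),
                    v2 = vapply(op$created, `[[`, "", "v2"),
                    stringsAsFactors = FALSE)
  rbind(state, add)
}

#' Scramble a genome, returning the ground-truth event history
#'
#' Applies `recipe$k` random events to the genome graph of `g`. A plain
#' event is a uniform random DCJ (internal, end, fusion or fission forms).
#' A transposition event is a 3-break realized as two weakly dependent
#' DCJs applied back to back: the second DCJ removes exactly one of the
#' edges created by the first, plus one pre-existing edge. The returned
#' truth is a `mixed_scenario`-style record of the planted events.
#'
#' @param g a `dcj_genome`.
#' @param recipe a [scramble_recipe()].
#' @return list with elements `genome` (the scrambled `dcj_genome`) and
#'   `truth` (list with `events`, each either a `dcj_op` or a
#'   `threebreak_op` with its DCJ pair in `$pair`, and `n_transpositions`).
#' @export
scramble <- function(g, recipe) {
  stopifnot(inherits(g, "dcj_genome"), inherits(recipe, "scramble_recipe"))
  with_seed(recipe$seed, {
    adj <- genome_adjacencies(g, tag = "S")
    state <- data.frame(id = seq_len(nrow(adj)), adj, stringsAsFactors = FALSE)
    ntel <- sum(is_telomere(c(state$v1, state$v2)))
    counters <- new.env(parent = emptyenv())
    counters$next_id <- nrow(state) + 1L
    counters$next_tel <- ntel + 1L
    events <- list()
    n3 <- 0L
    for (i in seq_len(recipe$k)) {
      if (stats::runif(1) < recipe$transposition_prob && nrow(state) >= 3L) {
        op1 <- random_dcj_event(state, counters)
        state1 <- apply_event(state, op1)
        # second DCJ: remove one created edge of op1 plus another edge
        created_ids <- step_ids(op1, "created")
        pick_created <- created_ids[sample.int(length(created_ids), 1L)]
        others <- setdiff(state1$id, created_ids)
        if (length(others) == 0L) {  # degenerate; fall back to a plain DCJ
          state <- state1
          events[[length(events) + 1L]] <- op1
          next
        }
        pick_other <- others[sample.int(length(others), 1L)]
        rows <- match(c(pick_created, pick_other), state1$id)
        a <- state1$v1[rows[1L]]; b <- state1$v2[rows[1L]]
        c_ <- state1$v1[rows[2L]]; d <- state1$v2[rows[2L]]
        pairing <- if (stats::runif(1) < 0.5) list(c(a, c_), c(b, d)) else
          list(c(a, d), c(b, c_))
        keep <- Filter(function(pr) !(is_telomere(pr[1]) && is_telomere(pr[2])),
                       pairing)
        if (length(keep) == 2L &&
            sum(vapply(keep, function(pr) any(is_telomere(pr)), TRUE)) == 2L) {
          # telomere-swap no-op would not be a real second cut; plain DCJ instead
          state <- state1
          events[[length(events) + 1L]] <- op1
          next
        }
        ids <- counters$next_id + seq_along(keep) - 1L
        counters$next_id <- counters$next_id + length(keep)
        removed <- edge_records(state1[rows, ])
        created <- lapply(seq_along(keep), function(kk) {
          list(id = ids[kk], v1 = keep[[kk]][1], v2 = keep[[kk]][2])
        })
        op2 <- new_dcj(removed, created, classify_form(removed, created))
        state <- apply_event(state1, op2)
        tb <- merge_pair(op1, op2, provenance = c(NA_integer_, NA_integer_))
        tb$pair <- list(op1, op2)
        events[[length(events) + 1L]] <- tb
        n3 <- n3 + 1L
      } else {
        op <- random_dcj_event(state, counters)
        state <- apply_event(state, op)
        events[[length(events) + 1L]] <- op
      }
    }
    scrambled <- genome_from_adjacencies(state[, c("v1", "v2")], gene_set(g),
                                         name = paste0(g$name, "_scrambled"))
    list(genome = scrambled,
         truth = list(events = events, n_transpositions = n3,
                      n_events = recipe$k))
  })
}

#' Convenience: a random genome and its scrambled partner
#'
#' @param n gene count.
#' @param chroms chromosome count for the base genome.
#' @param recipe a [scramble_recipe()] (its `topology_mix` and `seed` drive
#'   the base genome as well).
#' @return list `P`, `Q`, `truth`.
#' @export
scrambled_pair <- function(n, chroms, recipe) {
  P <- random_genome(n, chroms, topology_mix = recipe$topology_mix,
                     seed = recipe$seed, name = "P")
  sc <- scramble(P, recipe)
  sc$genome$name <- "Q"
  list(P = P, Q = sc$genome, truth = sc$truth)
}

# distance-neutral internal DCJ candidates for the detour wander phase
neutral_internal_ops <- function(bg, d_now, removed_keys, red_keys, creator_of) {
  bl <- bg$black
  reg <- which(!is_telomere(bl$v1) & !is_telomere(bl$v2))
  reg <- reg[!(adj_key(bl$v1[reg], bl$v2[reg]) %in% red_keys)]
  ops <- list()
  if (length(reg) < 2L) return(ops)
  for (i in reg) {
    for (j in reg) {
      if (j <= i) next
      a <- bl$v1[i]; b <- bl$v2[i]; c_ <- bl$v1[j]; d <- bl$v2[j]
      for (pairing in list(list(c(a, c_), c(b, d)), list(c(a, d), c(b, c_)))) {
        keys <- vapply(pairing, function(pr) adj_key(pr[1], pr[2]), "")
        if (any(keys %in% removed_keys)) next  # would recreate a removed adjacency
        # strong dependence guard: both removed edges created by one step
        cr <- c(creator_of[[as.character(bl$id[i])]] %||% NA_integer_,
                creator_of[[as.character(bl$id[j])]] %||% NA_integer_)
        if (!anyNA(cr) && cr[1L] == cr[2L]) next
        ids <- bg$next_id + 0:1
        removed <- edge_records(bl[c(i, j), ])
        created <- list(list(id = ids[1L], v1 = pairing[[1L]][1], v2 = pairing[[1L]][2]),
                        list(id = ids[2L], v1 = pairing[[2L]][1], v2 = pairing[[2L]][2]))
        op <- new_dcj(removed, created, "internal")
        bg2 <- apply_dcj(bg, op)
        if (stats_distance(component_stats(bg2)) == d_now) {
          ops[[length(ops) + 1L]] <- op
        }
      }
    }
  }
  ops
}

#' Generate a proper, non-shortest DCJ scenario
#'
#' Produces a scenario of length `dcj_distance(P, Q) + extra` satisfying
#' the proper-scenario conditions: a wander phase of `extra`
#' distance-neutral internal DCJs (rejected when they would recreate a
#' removed adjacency, strongly depend on an earlier step, or break a final
#' adjacency), followed by a randomized shortest sorting of the wandered
#' state. Candidates failing [check_proper()] are rejected and regenerated;
#' after 100 failed attempts an error reports the seed.
#'
#' @param P,Q genomes over the same gene set.
#' @param extra number of surplus steps (>= 0).
#' @param seed integer seed.
#' @return a proper `dcj_scenario` of length `d + extra`.
#' @export
detour_scenario <- function(P, Q, extra, seed = NULL) {
  stopifnot(extra >= 0L)
  validate_pair(P, Q)
  if (extra == 0L) return(sort_scenario(P, Q, seed = seed, policy = "random"))
  d <- dcj_distance(P, Q)
  with_seed(seed, {
    for (attempt in seq_len(100L)) {
      bg <- build_breakpoint_graph(P, Q)
      red_keys <- adj_key(bg$red$v1, bg$red$v2)
      removed_keys <- character(0)
      creator_of <- new.env(parent = emptyenv())
      steps <- list()
      ok <- TRUE
      for (w in seq_len(extra)) {
        cands <- neutral_internal_ops(bg, d, removed_keys, red_keys, creator_of)
        if (length(cands) == 0L) {
          ok <- FALSE
          break
        }
        op <- cands[[sample.int(length(cands), 1L)]]
        for (e in op$removed) {
          removed_keys <- c(removed_keys, adj_key(e$v1, e$v2))
        }
        for (e in op$created) {
          creator_of[[as.character(e$id)]] <- length(steps) + 1L
        }
        bg <- apply_dcj(bg, op)
        steps[[length(steps) + 1L]] <- op
      }
      if (!ok) next
      # sort the wandered state with the structural moves
      repeat {
        plans <- sorting_moves(bg)
        if (length(plans) == 0L) break
        res <- apply_plan(bg, plans[[sample.int(length(plans), 1L)]])
        bg <- res$bg
        steps[[length(steps) + 1L]] <- res$op
      }
      cand <- new_scenario(P, Q, steps)
      if (scenario_length(cand) == d + extra && check_proper(cand)$is_proper &&
          scenario_sorts(cand)) {
        return(cand)
      }
    }
    stop("detour generation failed after 100 attempts (seed = ",
         seed %||% "NULL", "); try a larger genome or smaller extra")
  })
}
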