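# Recovery of implicit transpositions: shortcut-free matchings, the
# constructive DIT lower bounds, 3-break merging and the genome-only rate
# bounds for proper and shortest scenarios.

#' Layered spanning forest of an acyclic dependency graph
#'
#' Labels each vertex with the length of the longest directed path reaching
#' it from a source, then keeps exactly one incoming arc per non-source
#' vertex, chosen from the previous layer (smallest source index first).
#' The kept arcs can never be shortcuts in the original graph, the subgraph
#' has `|V| - #sources` arcs, and vertex degrees are at most 3 when the
#' input degrees are at most 2 in and 2 out.
#'
#' @param dg a `dep_graph` (acyclic; scenario order topological).
#' @return a `dep_graph` holding only the kept arcs.
#' @export
layered_forest <- function(dg) {
  stopifnot(inherits(dg, "dep_graph"))
  n <- dg$n_steps
  arcs <- dg$arcs
  layer <- integer(n)
  for (v in seq_len(n)) {
    ins <- which(arcs$to == v)
    if (length(ins)) layer[v] <- max(layer[arcs$from[ins]]) + 1L
  }
  keep <- integer(0)
  for (v in seq_len(n)) {
    if (layer[v] == 0L) next
    ins <- which(arcs$to == v & layer[arcs$from] == layer[v] - 1L)
    if (length(ins) == 0L) stop("internal error: no incoming arc from previous layer")
    keep <- c(keep, ins[which.min(arcs$from[ins])])
  }
  out <- dg
  out$arcs <- arcs[keep, , drop = FALSE]
  rownames(out$arcs) <- NULL
  out$arc_ids <- dg$arc_ids[keep]
  out$e <- sum(out$arcs$weight)
  out$layers <- layer
  out
}

#' Greedy leaf matching in a directed forest
#'
#' Iteratively takes a leaf of the underlying undirected forest (smallest
#' step index first), adds its unique incident arc to the matching and
#' deletes every arc incident to the matched pair. When every vertex degree
#' is at most `degree_bound`, each round deletes at most `degree_bound`
#' arcs, so the matching has at least `ceiling(e / degree_bound)` arcs.
#'
#' @param forest_dg a `dep_graph` whose underlying undirected graph is a
#'   forest (checked with igraph).
#' @param degree_bound maximum vertex degree (3 after [layered_forest()] on
#'   a proper scenario, 4 for the dependency graph of a shortest scenario).
#' @return a data.frame (`from`, `to`) of vertex-disjoint arcs.
#' @export
greedy_matching <- function(forest_dg, degree_bound) {
  stopifnot(inherits(forest_dg, "dep_graph"))
  arcs <- forest_dg$arcs
  n <- forest_dg$n_steps
  if (nrow(arcs)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = arcs$from, to = arcs$to),
      directed = FALSE,
      vertices = data.frame(name = seq_len(n)))
    if (!igraph::is_forest(g)) stop("underlying undirected graph is not a forest")
  }
  deg <- tabulate(c(arcs$from, arcs$to), nbins = n)
  if (any(deg > degree_bound)) {
    stop("vertex degree exceeds degree_bound = ", degree_bound)
  }
  active <- rep(TRUE, nrow(arcs))
  m_from <- integer(0)
  m_to <- integer(0)
  while (any(active)) {
    ends <- c(arcs$from[active], arcs$to[active])
    deg <- tabulate(ends, nbins = n)
    leaves <- which(deg == 1L)
    leaf <- min(leaves)
    row <- which(active & (arcs$from == leaf | arcs$to == leaf))[1L]
    a <- arcs$from[row]
    b <- arcs$to[row]
    m_from <- c(m_from, a)
    m_to <- c(m_to, b)
    active <- active & !(arcs$from %in% c(a, b) | arcs$to %in% c(a, b))
  }
  data.frame(from = m_from, to = m_to)
}

#' Constructive lower bound on recoverable disjoint transpositions
#'
#' For a proper scenario the bound is `ceiling(e(t)/6)`, witnessed by a
#' shortcut-free matching built by [layered_forest()] followed by
#' [greedy_matching()] with degree bound 3. For a shortest scenario the
#' dependency graph is itself a directed forest with degrees at most 4, and
#' the refined bound `ceiling(e(t)/4)` is witnessed by greedy matching
#' directly. The witnessing matching always has at least `bound` arcs and
#' can be fed to [recover_transpositions()].
#'
#' @param t a `dcj_scenario` (proper; for `mode = "shortest"` its length
#'   must equal the DCJ distance of its genome pair).
#' @param mode `"proper"` or `"shortest"`.
#' @return an object of class `dit_bound`: list with `bound`, `matching`
#'   (data.frame `from`, `to`), `e` (dependency arc count) and `mode`.
#' @export
dit_lower_bound <- function(t, mode = c("proper", "shortest")) {
  mode <- match.arg(mode)
  stopifnot(inherits(t, "dcj_scenario"))
  dg <- build_dependency_graph(t)
  if (any(dg$arcs$weight >= 2L)) {
    stop("scenario has strongly dependent steps and is not proper")
  }
  e <- dg$e
  if (mode == "shortest") {
    if (scenario_length(t) != dcj_distance(t$source, t$target)) {
      stop("mode = 'shortest' requires a scenario of minimum length")
    }
    m <- greedy_matching(dg, 4L)
    bound <- as.integer(ceiling(e / 4))
  } else {
    m <- greedy_matching(layered_forest(dg), 3L)
    bound <- as.integer(ceiling(e / 6))
  }
  if (nrow(m) < bound) stop("internal error: matching smaller than bound")
  structure(list(bound = bound, matching = m, e = e, mode = mode, graph = dg),
            class = "dit_bound")
}

#' @export
print.dit_bound <- function(x, ...) {
  cat("DIT lower bound (", x$mode, " mode): ", x$bound,
      "  [e(t) = ", x$e, ", matching size ", nrow(x$matching), "]\n", sep = "")
  invisible(x)
}

#' Rate of implicit transpositions
#'
#' After merging `dit` disjoint weakly dependent DCJ pairs of a scenario of
#' `length` DCJs into 3-breaks, the mixed scenario has `length - dit` steps
#' of which `dit` are transpositions; their proportion is
#' `dit / (length - dit)`. Defined as 0 for an empty scenario. Strictly
#' increasing in `dit` at fixed `length`.
#'
#' @param dit number of recovered transpositions.
#' @param length number of DCJ steps of the original scenario.
#' @return numeric rate in `[0, 1]`.
#' @export
implicit_rate <- function(dit, length) {
  stopifnot(dit >= 0, length >= 0)
  if (2 * dit > length) stop("at most length/2 transpositions can be recovered")
  if (length == 0) return(0)
  dit / (length - dit)
}

merge_pair <- function(a, b, provenance) {
  shared <- intersect(step_ids(a, "created"), step_ids(b, "removed"))
  if (length(shared) != 1L) {
    stop("matched steps are not weakly dependent (shared edges: ",
         length(shared), ")")
  }
  removed <- c(a$removed, Filter(function(e) e$id != shared, b$removed))
  created <- c(Filter(function(e) e$id != shared, a$created), b$created)
  structure(list(removed = removed, created = created, form = "3-break",
                 provenance = provenance),
            class = "threebreak_op")
}

#' @export
format.threebreak_op <- function(x, ...) {
  f <- function(recs) paste(vapply(recs, function(e) {
    paste0("{", fmt_vertex(e$v1), ",", fmt_vertex(e$v2), "}")
  }, ""), collapse = " ")
  paste("3BREAK REMOVE", f(x$removed), "CREATE", f(x$created))
}

#' @export
print.threebreak_op <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Recover transpositions from a scenario along a matching
#'
#' Reorders the scenario with independence (T1) swaps so that every matched
#' weakly dependent pair becomes adjacent ([reorder_with_adjacency()]),
#' then merges each pair into a single 3-break replacing three edges by
#' three other edges on the same endpoints. The result is a mixed scenario
#' of `|t| - |m|` steps that still transforms the source genome into the
#' target.
#'
#' @param t a proper `dcj_scenario`.
#' @param m a shortcut-free matching as produced by [dit_lower_bound()]
#'   (data.frame of arcs `from`, `to` in step indices of `t`).
#' @return an object of class `mixed_scenario`: list with `steps` (DCJs and
#'   3-breaks), `dit`, `original_length`, `rate`, `source`, `target`.
#' @export
recover_transpositions <- function(t, m) {
  stopifnot(inherits(t, "dcj_scenario"))
  m <- as.data.frame(m)
  if (nrow(m)) names(m)[1:2] <- c("from", "to")
  t2 <- reorder_with_adjacency(t, m)
  ord <- attr(t2, "order")
  n <- length(t2$steps)
  pos_from <- match(m$from, ord)
  steps <- list()
  k <- 1L
  while (k <= n) {
    r <- match(k, pos_from)
    if (!is.na(r)) {
      steps[[length(steps) + 1L]] <-
        merge_pair(t2$steps[[k]], t2$steps[[k + 1L]],
                   provenance = c(m$from[r], m$to[r]))
      k <- k + 2L
    } else {
      steps[[length(steps) + 1L]] <- t2$steps[[k]]
      k <- k + 1L
    }
  }
  structure(list(source = t$source, target = t$target, steps = steps,
                 dit = nrow(m), original_length = length(t$steps),
                 rate = implicit_rate(nrow(m), length(t$steps))),
            class = "mixed_scenario")
}

#' @export
print.mixed_scenario <- function(x, ...) {
  cat("Mixed scenario '", x$source$name, "' -> '", x$target$name, "': ",
      length(x$steps), " step(s), ", x$dit, " transposition(s), rate ",
      format(x$rate, digits = 4), "\n", sep = "")
  for (i in seq_along(x$steps)) {
    cat(sprintf("%3d  %s\n", i, format(x$steps[[i]])))
  }
  invisible(x)
}

#' Replay a mixed scenario on its breakpoint graph
#'
#' @param ms a `mixed_scenario`.
#' @return the resulting `bp_graph`.
#' @export
replay_mixed <- function(ms) {
  bg <- build_breakpoint_graph(ms$source, ms$target)
  for (op in ms$steps) {
    bg <- apply_dcj(bg, op)
    tel_created <- sum(vapply(op$created, function(e) {
      is_telomere(e$v1) + is_telomere(e$v2)
    }, 0))
    bg$next_tel <- bg$next_tel + tel_created
  }
  bg
}

#' Does a mixed scenario fully sort its source into its target?
#' @param ms a `mixed_scenario`.
#' @return logical.
#' @export
mixed_sorts <- function(ms) {
  stats_distance(component_stats(replay_mixed(ms))) == 0L
}

#' Genome-only rate bound for proper scenarios
#'
#' For any proper DCJ scenario `t` between `P` and `Q`, the rate of
#' recoverable disjoint implicit transpositions satisfies
#' `r(t) >= 1/2 - 3 s / (8 d + 2 s)` where `d` is the DCJ distance and `s`
#' is [s_statistic()]. The bound is clipped at 0 (a negative lower bound is
#' vacuous) and defined as 0 for identical genomes.
#'
#' @param P,Q genomes over the same gene set.
#' @return numeric lower bound in `[0, 1)`.
#' @export
#' @examples
#' gs <- parse_genomes(">P\n+a -b +c -d @\n>Q\n+a +b +d +c $\n")
#' rate_bound_proper(gs[[1]], gs[[2]])  # 1/7
rate_bound_proper <- function(P, Q) {
  stats <- component_stats(build_breakpoint_graph(P, Q))
  d <- stats_distance(stats)
  if (d == 0L) return(0)
  s <- s_statistic(stats)
  max(0, 0.5 - 3 * s / (8 * d + 2 * s))
}

#' Genome-only rate bound for shortest scenarios
#'
#' For any shortest DCJ scenario `t` between `P` and `Q`,
#' `r(t) >= ceiling(E/4) / (d - ceiling(E/4))` with `E` the
#' [E_statistic()] clipped below at 0 and `d` the DCJ distance. Defined as
#' 0 for identical genomes.
#'
#' @param P,Q genomes over the same gene set.
#' @return numeric lower bound in `[0, 1)`.
#' @export
#' @examples
#' gs <- parse_genomes(">P\n+a -b +c -d @\n>Q\n+a +b +d +c $\n")
#' rate_bound_shortest(gs[[1]], gs[[2]])  # 1/3
rate_bound_shortest <- function(P, Q) {
  stats <- component_stats(build_breakpoint_graph(P, Q))
  d <- stats_distance(stats)
  if (d == 0L) return(0)
  E <- max(0, E_statistic(stats))
  k <- ceiling(E / 4)
  k / (d - k)
}

#' Exact maximum number of disjoint implicit transpositions (brute force)
#'
#' Exhaustively enumerates vertex-disjoint sets of non-shortcut arcs of the
#' dependency graph and returns the maximum size. A test oracle for short
#' scenarios (length <= 8 recommended); the constructive bounds of
#' [dit_lower_bound()] are guaranteed not to exceed it.
#'
#' @param t a proper `dcj_scenario`.
#' @return integer DIT(t).
#' @export
max_dit_bruteforce <- function(t) {
  dg <- build_dependency_graph(t)
  arcs <- dg$arcs
  if (nrow(arcs) == 0L) return(0L)
  ok <- !vapply(seq_len(nrow(arcs)), function(r) {
    is_shortcut(dg, arcs$from[r], arcs$to[r])
  }, TRUE)
  cand <- arcs[ok, , drop = FALSE]
  nc <- nrow(cand)
  if (nc == 0L) return(0L)
  best <- 0L
  recurse <- function(r, used, size) {
    if (size + (nc - r + 1L) <= best) return()  # cannot beat current best
    if (r > nc) {
      best <<- max(best, size)
      return()
    }
    a <- cand$from[r]
    b <- cand$to[r]
    if (!(a %in% used) && !(b %in% used)) {
      recurse(r + 1L, c(used, a, b), size + 1L)
    }
    recurse(r + 1L, used, size)
  }
  recurse(1L, integer(0), 0L)
  best
}
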