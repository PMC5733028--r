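# Dependency graphs of DCJ scenarios: construction, shortcut detection,
# (T1) reordering, and the contraction-based adjacent-pair ordering.

#' Build the dependency graph of a DCJ scenario
#'
#' Vertices are scenario step positions; there is an arc (a, b) whenever
#' step b removes an edge created by step a, detected through persistent
#' edge ids. An arc carrying one shared edge id is a weak dependence
#' (weight 1); two shared ids make it strong (weight 2). Proper scenarios
#' contain no strong arcs, and their arcs are in one-to-one correspondence
#' with created-then-removed edges. The scenario order is a topological
#' order of the graph, so the graph is acyclic by construction.
#'
#' @param t a `dcj_scenario`. A warning is emitted when strong arcs are
#'   found (the scenario then cannot be proper).
#' @return an object of class `dep_graph`: list with `n_steps`, `arcs`
#'   (data.frame `from`, `to`, `weight`), `arc_ids` (list of shared edge
#'   ids per arc) and `e` (total created-then-removed edge count, equal to
#'   the arc count for proper scenarios).
#' @export
build_dependency_graph <- function(t) {
  stopifnot(inherits(t, "dcj_scenario"))
  creator <- new.env(parent = emptyenv())
  from <- integer(0); to <- integer(0); ids <- list()
  key <- function(a, b) paste(a, b)
  arc_at <- new.env(parent = emptyenv())
  for (i in seq_along(t$steps)) {
    op <- t$steps[[i]]
    for (e in op$removed) {
      cr <- creator[[as.character(e$id)]]
      if (!is.null(cr)) {
        k <- key(cr, i)
        j <- arc_at[[k]]
        if (is.null(j)) {
          from <- c(from, cr); to <- c(to, i)
          ids[[length(ids) + 1L]] <- e$id
          arc_at[[k]] <- length(from)
        } else {
          ids[[j]] <- c(ids[[j]], e$id)
        }
      }
    }
    for (e in op$created) creator[[as.character(e$id)]] <- i
  }
  weight <- vapply(ids, length, 0L)
  if (any(weight >= 2L)) {
    warning("strong dependence present: scenario is not proper")
  }
  structure(list(n_steps = length(t$steps),
                 arcs = data.frame(from = from, to = to, weight = weight),
                 arc_ids = ids,
                 e = sum(weight)),
            class = "dep_graph")
}

#' @export
print.dep_graph <- function(x, ...) {
  cat("Dependency graph: ", x$n_steps, " step(s), ", nrow(x$arcs),
      " arc(s) (", sum(x$arcs$weight == 2L), " strong)\n", sep = "")
  if (nrow(x$arcs)) print(x$arcs)
  invisible(x)
}

#' Is an arc of a dependency graph a shortcut?
#'
#' An arc (a, b) is a shortcut when some other directed path leads from a
#' to b. The two steps of a shortcut can never be made adjacent by
#' independence swaps, so a shortcut never yields a recoverable
#' transposition.
#'
#' @param dg a `dep_graph`.
#' @param from,to endpoints of an arc present in `dg`.
#' @return logical.
#' @export
is_shortcut <- function(dg, from, to) {
  af <- dg$arcs$from
  at <- dg$arcs$to
  row <- which(af == from & at == to)
  if (length(row) != 1L) stop("no arc (", from, ", ", to, ") in the graph")
  af <- af[-row]
  at <- at[-row]
  # DFS from `from` avoiding the direct arc
  stack <- from
  seen <- logical(dg$n_steps)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (w in at[af == v]) {
      if (w == to) return(TRUE)
      if (!seen[w]) {
        seen[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  FALSE
}

step_ids <- function(op, field) {
  vapply(op[[field]], `[[`, 0, "id")
}

steps_independent <- function(a, b) {
  length(intersect(step_ids(a, "created"), step_ids(b, "removed"))) == 0L
}

#' Swap two adjacent independent DCJs (operation T1)
#'
#' Exchanges steps `i` and `i + 1` of a scenario, which is allowed exactly
#' when step `i + 1` removes no edge created by step `i`. The result is a
#' scenario of the same length between the same genomes with the same
#' dependency graph.
#'
#' @param t a `dcj_scenario`.
#' @param i position of the first step of the adjacent pair.
#' @return the reordered `dcj_scenario`.
#' @export
t1_swap <- function(t, i) {
  stopifnot(inherits(t, "dcj_scenario"))
  if (i < 1L || i + 1L > length(t$steps)) stop("position out of range")
  a <- t$steps[[i]]
  b <- t$steps[[i + 1L]]
  if (!steps_independent(a, b)) {
    stop("steps ", i, " and ", i + 1L, " are dependent; (T1) does not apply")
  }
  t$steps[[i]] <- b
  t$steps[[i + 1L]] <- a
  t
}

# Kahn topological order with smallest-original-index tie-break.
# nodes: integer ids 1..k; arcs: data.frame(from, to) on those ids;
# priority: numeric vector, smaller first. Errors on a cycle.
kahn_order <- function(k, arcs, priority) {
  indeg <- tabulate(arcs$to, nbins = k)
  out <- split(arcs$to, factor(arcs$from, levels = seq_len(k)))
  ready <- which(indeg == 0L)
  order <- integer(0)
  while (length(ready)) {
    v <- ready[which.min(priority[ready])]
    ready <- setdiff(ready, v)
    order <- c(order, v)
    for (w in out[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) ready <- c(ready, w)
    }
  }
  if (length(order) < k) stop("graph contains a cycle")
  order
}

# Verify `ord` is a topological order of dg (arcs respect positions).
is_topological <- function(dg, ord) {
  pos <- match(seq_len(dg$n_steps), ord)
  all(pos[dg$arcs$from] < pos[dg$arcs$to])
}

#' Reorder a scenario so that matched dependent pairs become adjacent
#'
#' Given a matching in the dependency graph containing no shortcuts, finds
#' a (T1)-reachable reordering of the scenario in which each matched pair
#' (a, b) appears as consecutive steps a, b. The construction contracts
#' each matched arc into a single super-vertex, topologically orders the
#' contracted graph (smallest original index first) and expands; the
#' sequence of adjacent independent swaps realizing the new order is
#' attached as `attr(, "t1_swaps")` (a matrix of swap positions).
#'
#' @param t a `dcj_scenario`.
#' @param m a matching: data.frame or 2-column matrix of step index pairs
#'   (`from`, `to`), vertex-disjoint arcs of `build_dependency_graph(t)`
#'   none of which is a shortcut.
#' @return the reordered `dcj_scenario` with attributes `order` (the
#'   permutation of original step positions) and `t1_swaps`.
#' @export
reorder_with_adjacency <- function(t, m) {
  stopifnot(inherits(t, "dcj_scenario"))
  m <- as.data.frame(m)
  if (nrow(m) == 0L) {
    attr(t, "order") <- seq_along(t$steps)
    attr(t, "t1_swaps") <- matrix(integer(0), ncol = 2)
    return(t)
  }
  names(m)[1:2] <- c("from", "to")
  dg <- build_dependency_graph(t)
  if (anyDuplicated(c(m$from, m$to))) stop("matching arcs share a vertex")
  for (r in seq_len(nrow(m))) {
    if (is_shortcut(dg, m$from[r], m$to[r])) {
      stop("arc (", m$from[r], ", ", m$to[r], ") is a shortcut")
    }
  }
  n <- dg$n_steps
  # contract matched pairs
  super <- seq_len(n)
  for (r in seq_len(nrow(m))) super[m$to[r]] <- m$from[r]
  nodes <- sort(unique(super))
  node_id <- match(super, nodes)
  arcs <- dg$arcs
  carcs <- data.frame(from = node_id[arcs$from], to = node_id[arcs$to])
  carcs <- carcs[carcs$from != carcs$to, , drop = FALSE]
  ord_nodes <- kahn_order(length(nodes), carcs, priority = nodes)
  # expansion: arcs always point from the earlier to the later step, so the
  # matched pair inside a super-vertex expands as (min, max) = (from, to)
  order <- unlist(lapply(ord_nodes, function(nd) {
    members <- which(node_id == nd)
    if (length(members) == 2L) c(min(members), max(members)) else members
  }))
  if (!is_topological(dg, order)) stop("internal error: order not topological")
  # realize by adjacent independent swaps (audit trail)
  cur <- seq_len(n)
  swaps <- list()
  t2 <- t
  for (k in seq_len(n)) {
    j <- match(order[k], cur)
    while (j > k) {
      t2 <- t1_swap(t2, j - 1L)
      cur[c(j - 1L, j)] <- cur[c(j, j - 1L)]
      swaps[[length(swaps) + 1L]] <- c(j - 1L, j)
      j <- j - 1L
    }
  }
  attr(t2, "order") <- order
  attr(t2, "t1_swaps") <- do.call(rbind, c(swaps, list(matrix(integer(0), ncol = 2))))
  t2
}

#' Export a dependency graph in DOT format
#'
#' Weak arcs are solid, strong arcs bold.
#'
#' @param dg a `dep_graph`.
#' @param path output file; when `NULL` the DOT text is returned.
#' @return the DOT text, invisibly when written to a file.
#' @export
dep_graph_dot <- function(dg, path = NULL) {
  style <- ifelse(dg$arcs$weight >= 2L, " [style=bold]", "")
  lines <- c("digraph dependency {",
             paste0("  ", dg$arcs$from, " -> ", dg$arcs$to, style, ";"),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
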