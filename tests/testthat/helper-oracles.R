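# Independent test oracles. These deliberately re-derive quantities through
# different representations and algorithms than the package:
#  - oracle_bfs_distance: breadth-first search over adjacency-matching states
#    under all single-DCJ moves (integer partner-vector encoding);
#  - oracle_component_table: igraph component decomposition of the
#    breakpoint graph edge list;
#  - oracle_adjacent_in_some_topo / oracle_all_dags: direct enumeration of
#    topological orders of small DAGs.

# ---- genome -> partner vector (independent of package internals) ----------
# Extremity numbering over sorted gene labels: gene i has tail 2i-1, head 2i.
# partner[x] = matched extremity, or 0 for a telomere.
oracle_partner_vector <- function(g) {
  genes <- sort(unlist(lapply(g$chromosomes, function(ch) ch$genes)))
  idx <- function(gene, end) {
    i <- match(gene, genes)
    if (end == "t") 2L * i - 1L else 2L * i
  }
  p <- integer(2L * length(genes))
  for (ch in g$chromosomes) {
    k <- length(ch$genes)
    ent <- integer(k)  # entry extremity per gene in reading order
    ext <- integer(k)  # exit extremity
    for (i in seq_len(k)) {
      if (ch$signs[i] > 0) {
        ent[i] <- idx(ch$genes[i], "t"); ext[i] <- idx(ch$genes[i], "h")
      } else {
        ent[i] <- idx(ch$genes[i], "h"); ext[i] <- idx(ch$genes[i], "t")
      }
    }
    if (k > 1L) {
      for (i in seq_len(k - 1L)) {
        p[ext[i]] <- ent[i + 1L]
        p[ent[i + 1L]] <- ext[i]
      }
    }
    if (ch$circular) {
      p[ext[k]] <- ent[1L]
      p[ent[1L]] <- ext[k]
    }
  }
  p
}

oracle_state_key <- function(p) paste(p, collapse = ",")

# all single-DCJ neighbors of a partner-vector state
oracle_neighbors <- function(p) {
  m <- length(p)
  firsts <- which(seq_len(m) < p)           # adjacency reps (i, p[i])
  tels <- which(p == 0L)
  out <- list()
  push <- function(q) out[[length(out) + 1L]] <<- q
  na <- length(firsts)
  # two adjacencies, two rejoinings each
  if (na >= 2L) {
    for (ii in seq_len(na - 1L)) {
      for (jj in seq((ii + 1L), na)) {
        a <- firsts[ii]; b <- p[a]; c <- firsts[jj]; d <- p[c]
        q <- p; q[a] <- c; q[c] <- a; q[b] <- d; q[d] <- b; push(q)
        q <- p; q[a] <- d; q[d] <- a; q[b] <- c; q[c] <- b; push(q)
      }
    }
  }
  # one adjacency and one telomere (reversal at a chromosome end)
  for (a in firsts) {
    b <- p[a]
    for (x in tels) {
      q <- p; q[a] <- x; q[x] <- a; q[b] <- 0L; push(q)
      q <- p; q[b] <- x; q[x] <- b; q[a] <- 0L; push(q)
    }
  }
  # fusion of two telomeres
  if (length(tels) >= 2L) {
    for (ii in seq_len(length(tels) - 1L)) {
      for (jj in seq(ii + 1L, length(tels))) {
        q <- p; q[tels[ii]] <- tels[jj]; q[tels[jj]] <- tels[ii]; push(q)
      }
    }
  }
  # fission of an adjacency
  for (a in firsts) {
    q <- p; q[p[a]] <- 0L; q[a] <- 0L; push(q)
  }
  out
}

# BFS distance in genome space under single DCJ moves
oracle_bfs_distance <- function(P, Q, max_depth = 12L) {
  start <- oracle_partner_vector(P)
  target <- oracle_state_key(oracle_partner_vector(Q))
  if (oracle_state_key(start) == target) return(0L)
  seen <- new.env(parent = emptyenv())
  seen[[oracle_state_key(start)]] <- TRUE
  frontier <- list(start)
  for (depth in seq_len(max_depth)) {
    nxt <- list()
    for (st in frontier) {
      for (nb in oracle_neighbors(st)) {
        key <- oracle_state_key(nb)
        if (key == target) return(depth)
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          nxt[[length(nxt) + 1L]] <- nb
        }
      }
    }
    frontier <- nxt
    if (length(frontier) == 0L) break
  }
  stop("oracle BFS exceeded max_depth")
}

# ---- igraph component oracle ----------------------------------------------
# Classify breakpoint graph components with igraph instead of the package's
# alternating traversal. Returns the same counts as component_stats().
oracle_component_table <- function(bg) {
  edges <- rbind(
    data.frame(a = bg$black$v1, b = bg$black$v2, color = "black"),
    data.frame(a = bg$red$v1, b = bg$red$v2, color = "red"))
  verts <- unique(c(edges$a, edges$b))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = verts))
  comp <- igraph::components(g)
  res <- list(c = 0L, c2 = 0L, p = 0L, p2 = 0L, p_even = 0L, p_odd = 0L,
              p_odd_P = 0L, p_odd_Q = 0L)
  for (ci in seq_len(comp$no)) {
    vs <- names(comp$membership)[comp$membership == ci]
    sub <- igraph::induced_subgraph(g, vs)
    ne <- igraph::ecount(sub)
    degs <- igraph::degree(sub)
    if (all(degs == 2L)) {
      res$c <- res$c + 1L
      if (ne == 2L) res$c2 <- res$c2 + 1L
    } else {
      res$p <- res$p + 1L
      if (ne %% 2L == 0L) {
        res$p_even <- res$p_even + 1L
        if (ne == 2L) res$p2 <- res$p2 + 1L
      } else {
        res$p_odd <- res$p_odd + 1L
        # end edges are those at degree-1 vertices (telomeres)
        endv <- names(degs)[degs == 1L]
        cols <- igraph::edge_attr(sub, "color",
                                  unlist(igraph::incident_edges(sub, endv)))
        if (all(cols == "black")) res$p_odd_P <- res$p_odd_P + 1L
        else if (all(cols == "red")) res$p_odd_Q <- res$p_odd_Q + 1L
        else stop("odd path with mixed end colors")
      }
    }
  }
  res
}

# ---- small-DAG oracles -----------------------------------------------------

# Exhaustively enumerate all labeled DAGs on n vertices as arc matrices.
# Every DAG is a subgraph of the complete order of some permutation; dedup
# by canonical arc-set key.
oracle_all_dags <- function(n) {
  stopifnot(n >= 1L, n <= 5L)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  np <- nrow(pairs)
  perms <- permutations_of(n)
  seen <- new.env(parent = emptyenv())
  dags <- list()
  for (pi in seq_len(nrow(perms))) {
    perm <- perms[pi, ]
    for (mask in 0:(2^np - 1L)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(np) - 1L)) > 0L)
      if (length(sel)) {
        from <- perm[pairs[sel, 1L]]
        to <- perm[pairs[sel, 2L]]
        o <- order(from, to)
        key <- paste(from[o], to[o], sep = ">", collapse = ";")
      } else {
        key <- ""
      }
      if (is.null(seen[[paste0("k", key)]])) {
        seen[[paste0("k", key)]] <- TRUE
        dags[[length(dags) + 1L]] <-
          if (length(sel)) data.frame(from = from[o], to = to[o])
          else data.frame(from = integer(0), to = integer(0))
      }
    }
  }
  dags
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    ins <- cbind(sub[, seq_len(i - 1L), drop = FALSE], n,
                 sub[, seq(i, n - 1L)[seq_len(n - i)], drop = FALSE])
    out <- rbind(out, ins)
  }
  out
}

# Is there a topological order of the DAG (n vertices, arcs df) in which a
# immediately precedes b? Direct recursive enumeration with early exit.
oracle_adjacent_in_some_topo <- function(n, arcs, a, b) {
  indeg <- tabulate(arcs$to, nbins = n)
  outs <- split(arcs$to, factor(arcs$from, levels = seq_len(n)))
  placed <- logical(n)
  found <- FALSE
  recurse <- function(last) {
    if (found) return()
    if (all(placed)) {
      # the pruning below forces b directly after a whenever a is not final
      if (last != a) found <<- TRUE
      return()
    }
    ready <- which(!placed & indeg == 0L)
    if (!is.na(last) && last == a) ready <- intersect(ready, b)
    for (v in ready) {
      placed[v] <<- TRUE
      for (w in outs[[v]]) indeg[w] <<- indeg[w] - 1L
      recurse(v)
      for (w in outs[[v]]) indeg[w] <<- indeg[w] + 1L
      placed[v] <<- FALSE
      if (found) return()
    }
  }
  recurse(NA_integer_)
  found
}

# all topological orders of a dependency graph (small n only)
oracle_all_topo_orders <- function(n, arcs) {
  perms <- permutations_of(n)
  keep <- apply(perms, 1L, function(ord) {
    pos <- match(seq_len(n), ord)
    all(pos[arcs$from] < pos[arcs$to])
  })
  perms[keep, , drop = FALSE]
}

# fabricate a dep_graph object from a plain arc list (for unit tests of the
# pure graph operations)
fake_dg <- function(n, from, to, weight = NULL) {
  weight <- weight %||% rep(1L, length(from))
  structure(list(n_steps = n,
                 arcs = data.frame(from = from, to = to, weight = weight),
                 arc_ids = as.list(seq_along(from)),
                 e = sum(weight)),
            class = "dep_graph")
}
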