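#' Build the breakpoint graph of two genomes
#'
#' The breakpoint graph G(P,Q) is the superposition of the adjacency
#' structures of `P` (black edges) and `Q` (red edges) on the shared gene
#' extremities. Every extremity carries exactly one black and one red edge;
#' each chromosome end contributes its own telomere vertex (degree 1), so
#' components are literally alternating black-red cycles and paths. Parallel
#' black/red edges on the same extremity pair (a shared adjacency) are kept
#' as two distinct edges and form a trivial cycle.
#'
#' Every edge carries a persistent integer id. Ids are never reused when the
#' graph is transformed by DCJs; this is what makes the arcs of the
#' dependency graph correspond one-to-one with created-then-removed edges.
#'
#' @param P,Q genomes over the same gene set (`P` supplies black edges,
#'   `Q` red edges).
#' @return an object of class `bp_graph` with fields `genes`, `n`,
#'   `black`/`red` (data.frames `id`, `v1`, `v2`), `next_id`, `next_tel`.
#' @export
#' @examples
#' gs <- parse_genomes(">P\n+a -b +c -d @\n>Q\n+a +b +d +c $\n")
#' bg <- build_breakpoint_graph(gs[[1]], gs[[2]])
#' component_stats(bg)
build_breakpoint_graph <- function(P, Q) {
  n <- validate_pair(P, Q)
  black <- genome_adjacencies(P, tag = "P")
  red <- genome_adjacencies(Q, tag = "Q")
  black <- data.frame(id = seq_len(nrow(black)), black, stringsAsFactors = FALSE)
  red <- data.frame(id = nrow(black) + seq_len(nrow(red)), red,
                    stringsAsFactors = FALSE)
  ntel <- sum(grepl("^\\*", c(black$v1, black$v2, red$v1, red$v2)))
  structure(list(genes = gene_set(P), n = n, black = black, red = red,
                 next_id = nrow(black) + nrow(red) + 1L,
                 next_tel = ntel + 1L,
                 used_ids = c(black$id, red$id)),
            class = "bp_graph")
}

#' @export
print.bp_graph <- function(x, ...) {
  cat("Breakpoint graph: ", x$n, " genes, ", nrow(x$black), " black / ",
      nrow(x$red), " red edges\n", sep = "")
  s <- component_stats(x)
  cat("  cycles:", s$c, "(trivial", paste0(s$c2, ");"),
      "paths:", s$p, "(even", s$p_even, "/ odd", paste0(s$p_odd, ")"), "\n")
  invisible(x)
}

# map vertex -> row index, one environment per color
edge_index <- function(df) {
  env <- new.env(parent = emptyenv(), size = max(2L * nrow(df), 16L))
  for (i in seq_len(nrow(df))) {
    env[[df$v1[i]]] <- i
    env[[df$v2[i]]] <- i
  }
  env
}

#' Enumerate the components of a breakpoint graph
#'
#' Exhaustive alternating traversal. Each component is returned with its
#' edge ids in walk order, its length (edge count) and a classification:
#' `"cycle"`, or `"path"` with the colors of its two end edges (an odd path
#' has equal end colors: black-black is a PP-path, red-red a QQ-path).
#'
#' @param bg a `bp_graph`.
#' @return a list of components, each a list with fields `type`, `len`,
#'   `edge_ids`, `colors`, and for paths `end_colors`.
#' @export
bp_components <- function(bg) {
  bl <- bg$black
  rd <- bg$red
  bidx <- edge_index(bl)
  ridx <- edge_index(rd)
  vis_b <- logical(nrow(bl))
  vis_r <- logical(nrow(rd))
  comps <- list()

  walk <- function(start_v, start_color, stop_at_start) {
    ids <- integer(0)
    cols <- character(0)
    v <- start_v
    color <- start_color
    repeat {
      if (color == "black") {
        i <- bidx[[v]]
        if (is.null(i) || vis_b[i]) break
        vis_b[i] <<- TRUE
        e <- bl[i, ]
      } else {
        i <- ridx[[v]]
        if (is.null(i) || vis_r[i]) break
        vis_r[i] <<- TRUE
        e <- rd[i, ]
      }
      ids <- c(ids, e$id)
      cols <- c(cols, color)
      v <- if (e$v1 == v) e$v2 else e$v1
      color <- if (color == "black") "red" else "black"
      if (is_telomere(v)) break
      if (stop_at_start && v == start_v && color == start_color) break
    }
    list(ids = ids, cols = cols, end_v = v)
  }

  # paths start at telomere vertices
  tel_starts <- unique(c(
    bl$v1[is_telomere(bl$v1)], bl$v2[is_telomere(bl$v2)],
    rd$v1[is_telomere(rd$v1)], rd$v2[is_telomere(rd$v2)]
  ))
  for (t in tel_starts) {
    color <- if (!is.null(bidx[[t]])) "black" else "red"
    done <- if (color == "black") vis_b[bidx[[t]]] else vis_r[ridx[[t]]]
    if (done) next
    w <- walk(t, color, stop_at_start = FALSE)
    comps[[length(comps) + 1L]] <- list(
      type = "path", len = length(w$ids), edge_ids = w$ids, colors = w$cols,
      end_colors = c(w$cols[1L], w$cols[length(w$cols)])
    )
  }
  # remaining black edges lie on cycles
  for (i in seq_len(nrow(bl))) {
    if (vis_b[i]) next
    w <- walk(bl$v1[i], "black", stop_at_start = TRUE)
    comps[[length(comps) + 1L]] <- list(
      type = "cycle", len = length(w$ids), edge_ids = w$ids, colors = w$cols
    )
  }
  comps
}

#' Component counts of a breakpoint graph
#'
#' Classifies components by exhaustive traversal and tallies the closed-form
#' ingredients: cycles `c` and trivial cycles `c2`; paths `p`, trivial paths
#' `p2`, even paths `p_even` and odd paths `p_odd`, the latter split into
#' PP-paths (`p_odd_P`, black end edges) and QQ-paths (`p_odd_Q`, red end
#' edges). Also reports the linear-chromosome counts implied by the graph:
#' `lin_P = p_odd_P + p_even/2`, `lin_Q = p_odd_Q + p_even/2`.
#'
#' @param bg a `bp_graph`, or precomputed components from [bp_components()].
#' @param n gene count (only needed when passing raw components).
#' @return an object of class `bp_stats`: a list with fields `n`, `c`, `c2`,
#'   `p`, `p2`, `p_even`, `p_odd`, `p_odd_P`, `p_odd_Q`, `lin_P`, `lin_Q`.
#' @export
component_stats <- function(bg, n = NULL) {
  if (inherits(bg, "bp_graph")) {
    comps <- bp_components(bg)
    n <- bg$n
  } else {
    comps <- bg
    if (is.null(n)) stop("n required when passing raw components")
  }
  s <- list(n = n, c = 0L, c2 = 0L, p = 0L, p2 = 0L,
            p_even = 0L, p_odd = 0L, p_odd_P = 0L, p_odd_Q = 0L)
  for (cm in comps) {
    if (cm$type == "cycle") {
      s$c <- s$c + 1L
      if (cm$len == 2L) s$c2 <- s$c2 + 1L
    } else {
      s$p <- s$p + 1L
      if (cm$len %% 2L == 0L) {
        s$p_even <- s$p_even + 1L
        if (cm$len == 2L) s$p2 <- s$p2 + 1L
      } else {
        s$p_odd <- s$p_odd + 1L
        if (cm$end_colors[1L] == "black") s$p_odd_P <- s$p_odd_P + 1L
        else s$p_odd_Q <- s$p_odd_Q + 1L
      }
    }
  }
  s$lin_P <- s$p_odd_P + s$p_even %/% 2L
  s$lin_Q <- s$p_odd_Q + s$p_even %/% 2L
  structure(s, class = "bp_stats")
}

#' @export
print.bp_stats <- function(x, ...) {
  cat("Breakpoint graph components (n = ", x$n, ")\n", sep = "")
  cat("  cycles c =", x$c, " trivial c2 =", x$c2, "\n")
  cat("  paths p =", x$p, " trivial p2 =", x$p2,
      " even =", x$p_even, " odd =", x$p_odd,
      " (PP =", x$p_odd_P, ", QQ =", x$p_odd_Q, ")\n")
  invisible(x)
}

stats_distance <- function(s) s$n - s$c - s$p_even %/% 2L

#' DCJ distance between two genomes
#'
#' Closed form `n - c - p_even/2` on the breakpoint graph component counts,
#' where `n` is the gene count, `c` the number of cycles and `p_even` the
#' number of even paths. The distance is 0 exactly when all components are
#' trivial, and is symmetric in its arguments.
#'
#' @param P,Q genomes over the same gene set.
#' @return integer DCJ distance.
#' @export
#' @examples
#' gs <- parse_genomes(">P\n+a -b +c -d @\n>Q\n+a +b +d +c $\n")
#' dcj_distance(gs[[1]], gs[[2]])  # 4
dcj_distance <- function(P, Q) {
  stats_distance(component_stats(build_breakpoint_graph(P, Q)))
}

#' Genome-pair statistic s(P,Q)
#'
#' `s = n + p_odd + p_even/2 - c2 - p2`. This counts the P-edges of the
#' breakpoint graph that lie on non-trivial components plus the QQ-path
#' allowance, and upper-bounds `2|t| - e(t)` for every proper scenario `t`;
#' it feeds the proper-scenario rate bound of [rate_bound_proper()].
#' Always non-negative.
#'
#' @param stats a `bp_stats` object from [component_stats()].
#' @return numeric value of s(P,Q).
#' @export
s_statistic <- function(stats) {
  with(stats, n + p_odd + p_even / 2 - c2 - p2)
}

#' Genome-pair statistic E(P,Q)
#'
#' `E = n - 2c - p - p_even/2 + c2 + p2`, a genome-only lower bound on the
#' number of dependency-graph arcs of any shortest scenario. Satisfies the
#' identity `E = 2 * d_DCJ - s`. May be negative for fragmented pairs; the
#' rate bound clips it at 0.
#'
#' @param stats a `bp_stats` object from [component_stats()].
#' @return numeric value of E(P,Q).
#' @export
E_statistic <- function(stats) {
  with(stats, n - 2 * c - p - p_even / 2 + c2 + p2)
}

#' Export a breakpoint graph in DOT format
#'
#' Writes a Graphviz description with black and red edge colors, for visual
#' inspection of small graphs.
#'
#' @param bg a `bp_graph`.
#' @param path output file; when `NULL` the DOT text is returned.
#' @return the DOT text, invisibly when written to a file.
#' @export
bp_graph_dot <- function(bg, path = NULL) {
  esc <- function(v) paste0('"', v, '"')
  lines <- c("graph breakpoint {",
             paste0("  ", esc(bg$black$v1), " -- ", esc(bg$black$v2),
                    ' [color=black, label="', bg$black$id, '"];'),
             paste0("  ", esc(bg$red$v1), " -- ", esc(bg$red$v2),
                    ' [color=red, label="', bg$red$id, '"];'),
             "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
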