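# Shared fixtures: the worked-example genome pair and random-pair builders.

# Circular P = {+a -b +c -d}, linear Q = (+a +b +d +c): breakpoint graph is
# a single odd (QQ) path; d = 4, s = 5, E = 3.
fig_pair <- function() {
  gs <- parse_genomes(">P\n+a -b +c -d @\n>Q\n+a +b +d +c $\n")
  list(P = gs[[1]], Q = gs[[2]])
}

# Linear +a +b vs +b +a: one PP-path and one QQ-path of length 3 each;
# d = 2, s = 4, E = 0.
swap_pair <- function() {
  gs <- parse_genomes(">P\n+a +b $\n>Q\n+b +a $\n")
  list(P = gs[[1]], Q = gs[[2]])
}

# Circular transposition pair: one 6-cycle, d = 2, sorted by a weakly
# dependent DCJ pair.
transposition_pair <- function() {
  gs <- parse_genomes(">P\n+a +b +c @\n>Q\n+a +c +b @\n")
  list(P = gs[[1]], Q = gs[[2]])
}

random_pair <- function(n, seed, chroms_p = NULL, chroms_q = NULL) {
  chroms_p <- chroms_p %||% (1L + seed %% 3L)
  chroms_q <- chroms_q %||% (1L + (seed + 1L) %% 3L)
  list(P = random_genome(n, min(chroms_p, n), 0.5, seed = seed, name = "P"),
       Q = random_genome(n, min(chroms_q, n), 0.5, seed = seed + 10000L,
                         name = "Q"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable identity of a scenario step (removed edge ids are unique per step)
step_sig <- function(op) {
  paste(sort(vapply(op$removed, `[[`, 0, "id")), collapse = "_")
}

# dependency graph as a set of arcs between step identities (order-free)
dg_sig <- function(t) {
  dg <- build_dependency_graph(t)
  sigs <- vapply(t$steps, step_sig, "")
  sort(paste(sigs[dg$arcs$from], "->", sigs[dg$arcs$to]))
}

order_sig <- function(t) paste(vapply(t$steps, step_sig, ""), collapse = "|")
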