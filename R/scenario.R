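# DCJ operations on breakpoint graphs, shortest-scenario construction,
# exhaustive enumeration (test oracle) and the proper-scenario checks.

edge_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    list(id = df$id[i], v1 = df$v1[i], v2 = df$v2[i])
  })
}

new_dcj <- function(removed, created, form) {
  structure(list(removed = removed, created = created, form = form),
            class = "dcj_op")
}

fmt_vertex <- function(v) ifelse(is_telomere(v), "*", v)

#' @export
format.dcj_op <- function(x, ...) {
  f <- function(recs) paste(vapply(recs, function(e) {
    paste0("{", fmt_vertex(e$v1), ",", fmt_vertex(e$v2), "}")
  }, ""), collapse = " ")
  paste("REMOVE", f(x$removed), "CREATE", f(x$created))
}

#' @export
print.dcj_op <- function(x, ...) {
  cat(format(x), " [", x$form, "]\n", sep = "")
  invisible(x)
}

# classify a removed/created pair of record lists into the four DCJ forms
classify_form <- function(removed, created) {
  tel_rm <- sum(vapply(removed, function(e) is_telomere(e$v1) + is_telomere(e$v2), 0))
  tel_cr <- sum(vapply(created, function(e) is_telomere(e$v1) + is_telomere(e$v2), 0))
  if (length(removed) == 2L && length(created) == 1L) "fusion"
  else if (length(removed) == 1L && length(created) == 2L) "fission"
  else if (tel_rm > 0L || tel_cr > 0L) "end"
  else "internal"
}

#' Apply a DCJ operation to a breakpoint graph
#'
#' Removes the operation's black edges (by persistent id, with endpoint
#' verification) and installs the created black edges under fresh ids. Red
#' edges are never touched. Fissions introduce fresh telomere vertices;
#' fusions retire two.
#'
#' @param state a `bp_graph`.
#' @param op a DCJ operation (class `dcj_op`) whose `removed` ids exist in
#'   `state$black` and whose `created` ids are fresh.
#' @return the updated `bp_graph`.
#' @export
apply_dcj <- function(state, op) {
  stopifnot(inherits(state, "bp_graph"),
            inherits(op, "dcj_op") || inherits(op, "threebreak_op"))
  bl <- state$black
  rm_rows <- integer(0)
  for (e in op$removed) {
    i <- match(e$id, bl$id)
    if (is.na(i)) stop("removed edge id ", e$id, " not present in black edges")
    if (!setequal(c(bl$v1[i], bl$v2[i]), c(e$v1, e$v2))) {
      stop("endpoint mismatch for removed edge id ", e$id)
    }
    rm_rows <- c(rm_rows, i)
  }
  if (anyDuplicated(rm_rows)) stop("edge removed twice in one DCJ")
  reg <- function(recs) {
    v <- unlist(lapply(recs, function(e) c(e$v1, e$v2)), use.names = FALSE)
    sort(v[!is_telomere(v)])
  }
  if (!identical(reg(op$removed), reg(op$created))) {
    stop("created edges do not preserve the regular endpoints of removed edges")
  }
  cr_ids <- vapply(op$created, `[[`, 0, "id")
  if (any(cr_ids %in% state$used_ids) || anyDuplicated(cr_ids)) {
    stop("created edge ids must be fresh (never used before)")
  }
  # telomere vertices on created edges are either carried over from the
  # removed edges (end form) or brand new (fission)
  rm_vs <- unlist(lapply(op$removed, function(e) c(e$v1, e$v2)), use.names = FALSE)
  cur_vs <- c(bl$v1[-rm_rows], bl$v2[-rm_rows], state$red$v1, state$red$v2)
  for (e in op$created) {
    for (v in c(e$v1, e$v2)) {
      if (is_telomere(v) && !(v %in% rm_vs) && v %in% cur_vs) {
        stop("created telomere vertex ", v, " already exists")
      }
    }
  }
  bl <- bl[-rm_rows, , drop = FALSE]
  add <- data.frame(id = cr_ids,
                    v1 = vapply(op$created, `[[`, "", "v1"),
                    v2 = vapply(op$created, `[[`, "", "v2"),
                    stringsAsFactors = FALSE)
  state$black <- rbind(bl, add)
  rownames(state$black) <- NULL
  state$next_id <- max(state$next_id, cr_ids + 1L)
  state$used_ids <- c(state$used_ids, cr_ids)
  state
}

# ---- distance-reducing move generation (structural move types) ------------

# Plans are lightweight descriptions; realize_plan() mints fresh ids.
# kinds: "extract" (trivial-cycle extraction on a red edge; internal/end),
#        "fuse"    (close a PP-path; fusion),
#        "fission" (cut a QQ-path at a red telomeric end; fission).
sorting_moves <- function(bg, comps = NULL) {
  comps <- comps %||% bp_components(bg)
  bidx <- edge_index(bg$black)
  plans <- list()
  add <- function(p) plans[[length(plans) + 1L]] <<- p
  black_at <- function(v) bg$black[bidx[[v]], ]
  for (cm in comps) {
    if (cm$len == 2L) next
    red_ids <- cm$edge_ids[cm$colors == "red"]
    if (cm$type == "cycle") {
      for (rid in red_ids) {
        e <- bg$red[match(rid, bg$red$id), ]
        add(list(kind = "extract", u = e$v1, v = e$v2,
                 key = paste("extract", adj_key(e$v1, e$v2))))
      }
    } else if (cm$len %% 2L == 0L) {
      for (rid in red_ids) {
        e <- bg$red[match(rid, bg$red$id), ]
        if (is_telomere(e$v1) || is_telomere(e$v2)) next
        add(list(kind = "extract", u = e$v1, v = e$v2,
                 key = paste("extract", adj_key(e$v1, e$v2))))
      }
    } else if (cm$end_colors[1L] == "black") {
      # PP-path: fuse the two black telomeric end edges
      first_id <- cm$edge_ids[1L]
      last_id <- cm$edge_ids[cm$len]
      e1 <- bg$black[match(first_id, bg$black$id), ]
      e2 <- bg$black[match(last_id, bg$black$id), ]
      w1 <- if (is_telomere(e1$v1)) e1$v2 else e1$v1
      w2 <- if (is_telomere(e2$v1)) e2$v2 else e2$v1
      add(list(kind = "fuse", e1 = e1$id, e2 = e2$id, w1 = w1, w2 = w2,
               key = paste("fuse", adj_key(w1, w2))))
    } else {
      # QQ-path: fission next to either red telomeric end edge
      for (rid in c(cm$edge_ids[1L], cm$edge_ids[cm$len])) {
        e <- bg$red[match(rid, bg$red$id), ]
        w <- if (is_telomere(e$v1)) e$v2 else e$v1
        be <- black_at(w)
        add(list(kind = "fission", edge = be$id,
                 key = paste("fission", w)))
      }
    }
  }
  plans
}

realize_plan <- function(bg, plan) {
  bidx <- edge_index(bg$black)
  fresh <- function(k) bg$next_id + seq_len(k) - 1L
  if (plan$kind == "extract") {
    eu <- bg$black[bidx[[plan$u]], ]
    ev <- bg$black[bidx[[plan$v]], ]
    x <- if (eu$v1 == plan$u) eu$v2 else eu$v1
    y <- if (ev$v1 == plan$v) ev$v2 else ev$v1
    removed <- edge_records(rbind(eu, ev))
    ids <- fresh(2L)
    created <- list(list(id = ids[1L], v1 = plan$u, v2 = plan$v),
                    list(id = ids[2L], v1 = x, v2 = y))
    if (is_telomere(x) && is_telomere(y)) {
      created <- created[1L]  # both neighbors telomeric: this is a fusion
    }
  } else if (plan$kind == "fuse") {
    rows <- bg$black[match(c(plan$e1, plan$e2), bg$black$id), ]
    removed <- edge_records(rows)
    created <- list(list(id = fresh(1L), v1 = plan$w1, v2 = plan$w2))
  } else {
    row <- bg$black[match(plan$edge, bg$black$id), ]
    removed <- edge_records(row)
    ids <- fresh(2L)
    t1 <- paste0("*T", bg$next_tel)
    t2 <- paste0("*T", bg$next_tel + 1L)
    created <- list(list(id = ids[1L], v1 = row$v1, v2 = t1),
                    list(id = ids[2L], v1 = row$v2, v2 = t2))
  }
  new_dcj(removed, created, classify_form(removed, created))
}

apply_plan <- function(bg, plan) {
  op <- realize_plan(bg, plan)
  bg <- apply_dcj(bg, op)
  if (op$form == "fission") bg$next_tel <- bg$next_tel + 2L
  list(bg = bg, op = op)
}

new_scenario <- function(source, target, steps) {
  structure(list(source = source, target = target, steps = steps,
                 genes = gene_set(source), n = length(gene_set(source))),
            class = "dcj_scenario")
}

#' @export
print.dcj_scenario <- function(x, ...) {
  cat("DCJ scenario '", x$source$name, "' -> '", x$target$name, "': ",
      length(x$steps), " step(s)\n", sep = "")
  for (i in seq_along(x$steps)) {
    cat(sprintf("%3d  %s  [%s]\n", i, format(x$steps[[i]]), x$steps[[i]]$form))
  }
  invisible(x)
}

#' Length of a scenario
#' @param t a `dcj_scenario`.
#' @return integer number of steps.
#' @export
scenario_length <- function(t) length(t$steps)

#' Serialize a scenario to its plain-text grammar
#'
#' One step per line: `REMOVE {u,v} {x,y} CREATE {u,x} {y,v}`, with
#' telomere vertices printed as `*`.
#'
#' @param t a `dcj_scenario`.
#' @param path optional file; when `NULL` the text is returned.
#' @return character vector of lines (invisible when written).
#' @export
write_scenario <- function(t, path = NULL) {
  lines <- vapply(t$steps, format, "")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Replay a scenario on the breakpoint graph of its genome pair
#'
#' @param t a `dcj_scenario`.
#' @param upto replay only the first `upto` steps (default: all).
#' @return the resulting `bp_graph`.
#' @export
replay_scenario <- function(t, upto = length(t$steps)) {
  bg <- build_breakpoint_graph(t$source, t$target)
  for (i in seq_len(upto)) {
    bg <- apply_dcj(bg, t$steps[[i]])
    if (t$steps[[i]]$form == "fission") bg$next_tel <- bg$next_tel + 2L
  }
  bg
}

#' Does a scenario fully sort its source into its target?
#' @param t a `dcj_scenario`.
#' @return logical: `TRUE` when the replayed breakpoint graph has only
#'   trivial components.
#' @export
scenario_sorts <- function(t) {
  stats_distance(component_stats(replay_scenario(t))) == 0L
}

#' Construct a shortest DCJ scenario between two genomes
#'
#' Builds the breakpoint graph and repeatedly applies a distance-reducing
#' DCJ until all components are trivial. Only four structural move types
#' are used: splitting a non-trivial cycle, splitting a non-trivial even
#' path (both realized as trivial-cycle extraction on a red edge), closing
#' a PP-path by a fusion, and cutting a QQ-path by a fission next to a red
#' telomere. Consequently the scenario contains exactly `p_odd_P` fusions
#' and `p_odd_Q` fissions, and its length equals [dcj_distance()].
#'
#' @param P,Q genomes over the same gene set.
#' @param seed integer seed for `policy = "random"`; ignored otherwise.
#' @param policy `"deterministic"` processes the lexicographically smallest
#'   eligible move (by sorted endpoint labels of its red edge); `"random"`
#'   draws uniformly among all eligible distance-reducing moves.
#' @return a `dcj_scenario`.
#' @export
#' @examples
#' gs <- parse_genomes(">P\n+a -b +c -d @\n>Q\n+a +b +d +c $\n")
#' t <- sort_scenario(gs[[1]], gs[[2]])
#' scenario_length(t)  # 4
sort_scenario <- function(P, Q, seed = NULL,
                          policy = c("deterministic", "random")) {
  policy <- match.arg(policy)
  validate_pair(P, Q)
  bg <- build_breakpoint_graph(P, Q)
  with_seed(seed, {
    steps <- list()
    repeat {
      plans <- sorting_moves(bg)
      if (length(plans) == 0L) break
      pick <- if (policy == "deterministic") {
        plans[[order(vapply(plans, `[[`, "", "key"))[1L]]]
      } else {
        plans[[sample.int(length(plans), 1L)]]
      }
      res <- apply_plan(bg, pick)
      bg <- res$bg
      steps[[length(steps) + 1L]] <- res$op
    }
    new_scenario(P, Q, steps)
  })
}

# ---- exhaustive enumeration (oracle for small instances) ------------------

# All DCJ operations applicable to the black edges of `bg`, as op records
# with fresh ids; telomere-relabeling no-ops are excluded.
all_dcj_ops <- function(bg) {
  bl <- bg$black
  nb <- nrow(bl)
  ops <- list()
  fresh <- function(k) bg$next_id + seq_len(k) - 1L
  add <- function(removed, created) {
    ops[[length(ops) + 1L]] <<- new_dcj(removed, created,
                                        classify_form(removed, created))
  }
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)) {
      if (j <= i) next
      a <- bl$v1[i]; b <- bl$v2[i]; c_ <- bl$v1[j]; d <- bl$v2[j]
      removed <- edge_records(bl[c(i, j), ])
      for (pairing in list(list(c(a, c_), c(b, d)), list(c(a, d), c(b, c_)))) {
        keep <- Filter(function(pr) !(is_telomere(pr[1]) && is_telomere(pr[2])),
                       pairing)
        if (length(keep) == length(pairing)) {
          tel_per_pair <- vapply(keep, function(pr) {
            is_telomere(pr[1]) || is_telomere(pr[2])
          }, TRUE)
          if (sum(tel_per_pair) == 2L) next  # telomere swap: relabeling no-op
        }
        ids <- fresh(length(keep))
        created <- lapply(seq_along(keep), function(k) {
          list(id = ids[k], v1 = keep[[k]][1], v2 = keep[[k]][2])
        })
        add(removed, created)
      }
    }
    if (!is_telomere(bl$v1[i]) && !is_telomere(bl$v2[i])) {
      ids <- fresh(2L)
      t1 <- paste0("*T", bg$next_tel)
      t2 <- paste0("*T", bg$next_tel + 1L)
      add(edge_records(bl[i, , drop = FALSE]),
          list(list(id = ids[1L], v1 = bl$v1[i], v2 = t1),
               list(id = ids[2L], v1 = bl$v2[i], v2 = t2)))
    }
  }
  ops
}

apply_op_counting_tel <- function(bg, op) {
  bg2 <- apply_dcj(bg, op)
  if (op$form == "fission") bg2$next_tel <- bg2$next_tel + 2L
  bg2
}

#' Enumerate all shortest DCJ scenarios between two genomes
#'
#' Exhaustive depth-first search over distance-reducing DCJs (all forms, not
#' just the structural types used by [sort_scenario()]). Intended as a test
#' oracle for small instances (distance at most ~5).
#'
#' @param P,Q genomes over the same gene set.
#' @param cap stop after this many scenarios; the result then carries
#'   `attr(, "truncated") = TRUE`.
#' @return list of `dcj_scenario`, all of length `dcj_distance(P, Q)`.
#' @export
enumerate_shortest_scenarios <- function(P, Q, cap = 10000L) {
  validate_pair(P, Q)
  bg0 <- build_breakpoint_graph(P, Q)
  out <- list()
  truncated <- FALSE
  recurse <- function(bg, prefix, d) {
    if (truncated) return()
    if (d == 0L) {
      out[[length(out) + 1L]] <<- new_scenario(P, Q, prefix)
      if (length(out) >= cap) truncated <<- TRUE
      return()
    }
    for (op in all_dcj_ops(bg)) {
      bg2 <- apply_op_counting_tel(bg, op)
      if (stats_distance(component_stats(bg2)) == d - 1L) {
        recurse(bg2, c(prefix, list(op)), d - 1L)
        if (truncated) return()
      }
    }
  }
  recurse(bg0, list(), stats_distance(component_stats(bg0)))
  attr(out, "truncated") <- truncated
  out
}

# ---- proper-scenario conditions ------------------------------------------

#' Check the proper-scenario conditions on a DCJ scenario
#'
#' A scenario is proper when: (P1) no adjacency, once removed, is ever
#' recreated (telomeric adjacencies compare with a wildcard telomere); (P2)
#' no step removes both edges created by a single earlier step (strong
#' dependence, the operational face of "no two DCJs replaceable by one");
#' (P3) the number of fusions does not exceed the PP-path count and the
#' number of fissions does not exceed the QQ-path count of the genome pair.
#' Every shortest scenario is proper.
#'
#' @param t a `dcj_scenario`.
#' @return an object of class `proper_report`: list with `is_proper` and a
#'   data.frame `violations` (columns `condition`, `step_a`, `step_b`,
#'   `description`).
#' @export
check_proper <- function(t) {
  stopifnot(inherits(t, "dcj_scenario"))
  bg <- build_breakpoint_graph(t$source, t$target)
  s0 <- component_stats(bg)
  removed_keys <- new.env(parent = emptyenv())
  creator_of <- new.env(parent = emptyenv())  # edge id -> creating step
  viol <- list()
  bad <- function(cond, a, b, desc) {
    viol[[length(viol) + 1L]] <<- data.frame(
      condition = cond, step_a = a, step_b = b, description = desc,
      stringsAsFactors = FALSE)
  }
  fus <- 0L
  fis <- 0L
  for (i in seq_along(t$steps)) {
    op <- t$steps[[i]]
    rm_creators <- integer(0)
    for (e in op$removed) {
      cr <- creator_of[[as.character(e$id)]]
      if (!is.null(cr)) rm_creators <- c(rm_creators, cr)
      removed_keys[[adj_key(e$v1, e$v2)]] <-
        c(removed_keys[[adj_key(e$v1, e$v2)]] %||% integer(0), i)
    }
    if (length(rm_creators) == 2L && rm_creators[1L] == rm_creators[2L]) {
      bad("P2", rm_creators[1L], i,
          "step removes both edges created by one earlier step (strong dependence)")
    }
    for (e in op$created) {
      key <- adj_key(e$v1, e$v2)
      prev <- removed_keys[[key]]
      if (!is.null(prev)) {
        bad("P1", prev[1L], i,
            paste0("adjacency {", fmt_vertex(e$v1), ",", fmt_vertex(e$v2),
                   "} recreated after removal"))
      }
      creator_of[[as.character(e$id)]] <- i
    }
    if (op$form == "fusion") fus <- fus + 1L
    if (op$form == "fission") fis <- fis + 1L
    bg <- apply_op_counting_tel(bg, op)
  }
  if (fus > s0$p_odd_P) {
    bad("P3", NA_integer_, NA_integer_,
        sprintf("%d fusions exceed the PP-path count %d", fus, s0$p_odd_P))
  }
  if (fis > s0$p_odd_Q) {
    bad("P3", NA_integer_, NA_integer_,
        sprintf("%d fissions exceed the QQ-path count %d", fis, s0$p_odd_Q))
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(condition = character(0), step_a = integer(0),
               step_b = integer(0), description = character(0))
  structure(list(is_proper = nrow(violations) == 0L, violations = violations),
            class = "proper_report")
}

#' @export
print.proper_report <- function(x, ...) {
  if (x$is_proper) cat("Scenario is proper (P1-P3 hold)\n")
  else {
    cat("Scenario is NOT proper:\n")
    print(x$violations)
  }
  invisible(x)
}
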