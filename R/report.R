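#' Pairwise DCJ distances and implicit-transposition rate bounds
#'
#' For every unordered pair of genomes computes the DCJ distance and the
#' two genome-only lower bounds on the implicit-transposition rate: the
#' proper-scenario bound ([rate_bound_proper()]) and the shortest-scenario
#' bound ([rate_bound_shortest()]). With `circularize_also = TRUE` each
#' quantity is additionally computed after artificially circularizing every
#' chromosome ([circularize()]), reported in companion `*_circ` columns.
#'
#' All values are closed-form functions of the breakpoint graph and agree
#' bit-for-bit with direct calls of the underlying functions; `seed` is
#' accepted for interface stability but the report involves no sampling.
#'
#' @param genomes list of at least two `dcj_genome` over the same gene set.
#' @param circularize_also also report values for circularized genomes.
#' @param seed unused; reserved for future sampled columns.
#' @return a data.frame with one row per pair: `genome1`, `genome2`, `d`,
#'   `proper_bound`, `shortest_bound` (and `d_circ`, `proper_bound_circ`,
#'   `shortest_bound_circ` when requested). Values are full precision; see
#'   [format_pairwise_report()] for the two-decimal display used in
#'   published tables.
#' @export
#' @examples
#' gs <- parse_genomes(">P\n+a -b +c -d @\n>Q\n+a +b +d +c $\n")
#' pairwise_report(gs)
pairwise_report <- function(genomes, circularize_also = FALSE, seed = NULL) {
  if (length(genomes) < 2L) stop("need at least two genomes")
  for (i in seq_along(genomes)) {
    for (j in seq_along(genomes)) {
      if (j <= i) next
      tryCatch(validate_pair(genomes[[i]], genomes[[j]]),
               error = function(e) {
                 stop("pair (", genomes[[i]]$name, ", ", genomes[[j]]$name,
                      "): ", conditionMessage(e))
               })
    }
  }
  rows <- list()
  for (i in seq_along(genomes)) {
    for (j in seq_along(genomes)) {
      if (j <= i) next
      P <- genomes[[i]]
      Q <- genomes[[j]]
      row <- data.frame(
        genome1 = P$name, genome2 = Q$name,
        d = dcj_distance(P, Q),
        proper_bound = rate_bound_proper(P, Q),
        shortest_bound = rate_bound_shortest(P, Q),
        stringsAsFactors = FALSE)
      if (circularize_also) {
        Pc <- circularize(P)
        Qc <- circularize(Q)
        row$d_circ <- dcj_distance(Pc, Qc)
        row$proper_bound_circ <- rate_bound_proper(Pc, Qc)
        row$shortest_bound_circ <- rate_bound_shortest(Pc, Qc)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Format a pairwise report for display
#'
#' Rounds the bound columns to a fixed number of decimals (published tables
#' of this kind print two).
#'
#' @param report output of [pairwise_report()].
#' @param digits decimal places for the rate bounds.
#' @return a data.frame of character/integer columns ready for printing or
#'   TSV export.
#' @export
format_pairwise_report <- function(report, digits = 2L) {
  out <- report
  for (col in names(out)) {
    if (grepl("bound", col)) out[[col]] <- sprintf(paste0("%.", digits, "f"),
                                                   out[[col]])
  }
  out
}

#' Write a pairwise report as TSV
#'
#' @param report output of [pairwise_report()].
#' @param path output file.
#' @param digits `NULL` for full precision, otherwise decimal places.
#' @return the path, invisibly.
#' @export
write_pairwise_report <- function(report, path, digits = NULL) {
  if (!is.null(digits)) report <- format_pairwise_report(report, digits)
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
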