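# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; restore the
# caller's RNG afterwards. `seed = NULL` means "use the ambient RNG".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Telomere vertices are named "*P1", "*Q3", ... ; gene extremities "g:h"/"g:t".
is_telomere <- function(v) startsWith(v, "*")

# Canonical key of an adjacency: telomeres collapse to "*" so that an
# adjacency {x, inf} is the same gene-level adjacency whichever telomere
# vertex realizes it. "\t" cannot occur in gene labels (parser rejects it).
adj_key <- function(v1, v2) {
  a <- ifelse(is_telomere(v1), "*", v1)
  b <- ifelse(is_telomere(v2), "*", v2)
  ifelse(a <= b, paste(a, b, sep = "\t"), paste(b, a, sep = "\t"))
}
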