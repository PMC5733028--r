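#' Construct a genome from chromosomes
#'
#' A genome is a set of chromosomes over signed genes, each gene label
#' appearing exactly once across the whole genome. Chromosomes are either
#' linear or circular. Circular chromosomes are considered equal under
#' rotation and under full reversal with sign flip; linear chromosomes under
#' full reversal with sign flip.
#'
#' @param chromosomes a list of chromosomes, each created by [chromosome()].
#' @param name genome name (used in reports and GRIMM output).
#' @return an object of class `dcj_genome`.
#' @export
#' @examples
#' g <- genome(list(chromosome(c("a", "-b", "c"), circular = TRUE)), name = "P")
#' gene_set(g)
genome <- function(chromosomes, name = "genome") {
  stopifnot(is.list(chromosomes))
  for (ch in chromosomes) {
    if (!inherits(ch, "dcj_chromosome")) {
      stop("all chromosomes must be built with chromosome()")
    }
  }
  g <- structure(list(name = name, chromosomes = chromosomes),
                 class = "dcj_genome")
  validate_genome(g)
  g
}

#' Construct a chromosome from signed gene labels
#'
#' @param genes character vector of signed labels such as `"+a"`, `"-b"`,
#'   or `"a"` (an omitted sign defaults to `+`).
#' @param circular logical; `TRUE` for a circular chromosome.
#' @return an object of class `dcj_chromosome` with fields `genes`
#'   (bare labels), `signs` (+1/-1) and `circular`.
#' @export
chromosome <- function(genes, circular = FALSE) {
  stopifnot(is.character(genes), length(genes) >= 1L, is.logical(circular))
  signs <- ifelse(startsWith(genes, "-"), -1L, 1L)
  labels <- sub("^[+-]", "", genes)
  if (any(labels == "")) stop("empty gene label in chromosome")
  if (any(grepl("[\t $@#]", labels))) {
    stop("gene labels may not contain whitespace, '$', '@' or '#'")
  }
  structure(list(genes = labels, signs = signs, circular = isTRUE(circular)),
            class = "dcj_chromosome")
}

validate_genome <- function(g) {
  labs <- unlist(lapply(g$chromosomes, `[[`, "genes"), use.names = FALSE)
  if (anyDuplicated(labs)) {
    stop("duplicate gene(s) in genome '", g$name, "': ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  invisible(g)
}

#' Gene set of a genome
#'
#' @param g a `dcj_genome`.
#' @return character vector of bare gene labels (sorted).
#' @export
gene_set <- function(g) {
  sort(unlist(lapply(g$chromosomes, `[[`, "genes"), use.names = FALSE))
}

#' @export
print.dcj_genome <- function(x, ...) {
  cat("Genome '", x$name, "': ", length(x$chromosomes), " chromosome(s), ",
      length(gene_set(x)), " gene(s)\n", sep = "")
  for (ch in x$chromosomes) {
    cat(" ", format_chromosome(ch), "\n", sep = " ")
  }
  invisible(x)
}

format_chromosome <- function(ch) {
  body <- paste(ifelse(ch$signs > 0, "+", "-"), ch$genes, sep = "", collapse = " ")
  paste(body, if (ch$circular) "@" else "$")
}

#' Parse genomes from GRIMM-style text
#'
#' The dialect: a `>name` line opens a genome record; each following
#' non-empty line is one chromosome, a whitespace-separated list of signed
#' gene labels terminated by `$` (linear) or `@` (circular); a missing sign
#' defaults to `+`; lines starting with `#` are comments.
#'
#' @param text a single string, or a character vector of lines.
#' @return a list of `dcj_genome` objects, in file order.
#' @seealso [write_genomes()], [read_genomes()]
#' @export
#' @examples
#' gs <- parse_genomes(">P\n+a -b +c -d @\n>Q\n+a +b +d +c $\n")
#' gs[[1]]
parse_genomes <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  genomes <- list()
  cur_name <- NULL
  cur_chroms <- list()
  flush <- function() {
    if (is.null(cur_name)) return()
    genomes[[length(genomes) + 1L]] <<- genome(cur_chroms, name = cur_name)
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush()
      cur_name <- trimws(sub("^>", "", ln))
      cur_chroms <- list()
    } else {
      if (is.null(cur_name)) stop("chromosome line before any '>' header")
      toks <- strsplit(ln, "[[:space:]]+")[[1]]
      term <- toks[length(toks)]
      if (!term %in% c("$", "@")) {
        stop("chromosome line must end with '$' or '@', got: ", ln)
      }
      toks <- toks[-length(toks)]
      if (length(toks) == 0L) stop("empty chromosome in genome '", cur_name, "'")
      cur_chroms[[length(cur_chroms) + 1L]] <-
        chromosome(toks, circular = term == "@")
    }
  }
  flush()
  genomes
}

#' Serialize genomes to GRIMM-style text
#'
#' Re-parsing the output reproduces the genomes up to chromosome equivalence
#' (rotation for circular chromosomes, reversal with sign flip for both
#' topologies).
#'
#' @param genomes a list of `dcj_genome` objects (or a single genome).
#' @return a single string in the dialect accepted by [parse_genomes()].
#' @export
write_genomes <- function(genomes) {
  if (inherits(genomes, "dcj_genome")) genomes <- list(genomes)
  if (length(genomes) == 0L) return("")
  recs <- vapply(genomes, function(g) {
    paste0(">", g$name, "\n",
           paste(vapply(g$chromosomes, format_chromosome, ""), collapse = "\n"),
           "\n")
  }, "")
  paste(recs, collapse = "")
}

#' Read / write GRIMM-style genome files
#'
#' @param path file path.
#' @return `read_genomes()` returns a list of `dcj_genome`.
#' @export
read_genomes <- function(path) parse_genomes(readLines(path, warn = FALSE))

#' @param genomes list of genomes for `write_genomes_file()`.
#' @rdname read_genomes
#' @export
write_genomes_file <- function(genomes, path) {
  writeLines(sub("\n$", "", write_genomes(genomes)), path)
  invisible(path)
}

#' Circularize every linear chromosome of a genome
#'
#' Joins the two ends of each linear chromosome, preserving gene order;
#' circular chromosomes are unchanged. Useful for comparing against methods
#' restricted to circular chromosomes. Idempotent; the resulting genome has
#' no telomeres.
#'
#' @param g a `dcj_genome`.
#' @return a `dcj_genome` with all chromosomes circular.
#' @export
circularize <- function(g) {
  chroms <- lapply(g$chromosomes, function(ch) {
    ch$circular <- TRUE
    ch
  })
  genome(chroms, name = g$name)
}

#' Check that two genomes share the same gene set
#'
#' @param P,Q genomes.
#' @return the common gene count `n`, invisibly usable as a plain integer.
#'   Errors with the symmetric difference when the gene sets differ.
#' @export
validate_pair <- function(P, Q) {
  gp <- gene_set(P)
  gq <- gene_set(Q)
  if (!identical(gp, gq)) {
    diff <- c(setdiff(gp, gq), setdiff(gq, gp))
    stop("genomes '", P$name, "' and '", Q$name,
         "' differ in gene content: {", paste(diff, collapse = ", "), "}")
  }
  length(gp)
}

# --- canonical forms (equality only; never used for I/O ordering) ----------

signed_tokens <- function(ch) paste0(ifelse(ch$signs > 0, "+", "-"), ch$genes)

reverse_tokens <- function(tok) {
  flipped <- ifelse(startsWith(tok, "+"), sub("^\\+", "-", tok),
                    sub("^-", "+", tok))
  rev(flipped)
}

canonical_chromosome <- function(ch) {
  tok <- signed_tokens(ch)
  if (ch$circular) {
    cands <- character(0)
    for (seq in list(tok, reverse_tokens(tok))) {
      k <- length(seq)
      for (i in seq_len(k)) {
        rot <- seq[c(i:k, seq_len(i - 1L))]
        cands <- c(cands, paste(rot, collapse = " "))
      }
    }
    paste0("@", min(cands))
  } else {
    paste0("$", min(paste(tok, collapse = " "),
                    paste(reverse_tokens(tok), collapse = " ")))
  }
}

#' Genome equality up to chromosome equivalence
#'
#' Two genomes are equal when their multisets of canonical chromosomes agree
#' (rotation and reversal-with-sign-flip for circular chromosomes, reversal
#' with sign flip for linear ones). Names are ignored.
#'
#' @param a,b genomes.
#' @return logical.
#' @export
genomes_equal <- function(a, b) {
  ca <- sort(vapply(a$chromosomes, canonical_chromosome, ""))
  cb <- sort(vapply(b$chromosomes, canonical_chromosome, ""))
  identical(ca, cb)
}

# --- adjacency representation ---------------------------------------------

# Extremity names: tail "g:t", head "g:h". Reading a gene +g visits g:t then
# g:h; reading -g visits g:h then g:t. An adjacency joins the out-extremity
# of one gene to the in-extremity of the next. Telomere vertices are unique
# per chromosome end, named "*<tag><serial>".

extremities_in_order <- function(ch) {
  n <- length(ch$genes)
  out <- character(2L * n)
  for (i in seq_len(n)) {
    g <- ch$genes[i]
    if (ch$signs[i] > 0) {
      out[2L * i - 1L] <- paste0(g, ":t")
      out[2L * i] <- paste0(g, ":h")
    } else {
      out[2L * i - 1L] <- paste0(g, ":h")
      out[2L * i] <- paste0(g, ":t")
    }
  }
  out
}

# All adjacencies of a genome, telomeres as unique "*<tag><k>" vertices.
# Returns a data.frame(v1, v2).
genome_adjacencies <- function(g, tag = "P") {
  v1 <- character(0)
  v2 <- character(0)
  tel <- 0L
  for (ch in g$chromosomes) {
    ext <- extremities_in_order(ch)
    k <- length(ext)
    if (k > 2L) {
      ins <- ext[seq(3L, k, by = 2L)]   # in-extremity of genes 2..n
      outs <- ext[seq(2L, k - 1L, by = 2L)] # out-extremity of genes 1..n-1
      v1 <- c(v1, outs)
      v2 <- c(v2, ins)
    }
    if (ch$circular) {
      v1 <- c(v1, ext[k])
      v2 <- c(v2, ext[1L])
    } else {
      tel <- tel + 1L
      v1 <- c(v1, paste0("*", tag, tel))
      v2 <- c(v2, ext[1L])
      tel <- tel + 1L
      v1 <- c(v1, ext[k])
      v2 <- c(v2, paste0("*", tag, tel))
    }
  }
  data.frame(v1 = v1, v2 = v2, stringsAsFactors = FALSE)
}

# Rebuild a genome from an adjacency table over the given gene labels.
# Adjacencies reference extremities "g:t"/"g:h"; telomere vertices mark
# chromosome ends. Inverse of genome_adjacencies() up to chromosome
# equivalence.
genome_from_adjacencies <- function(adj, genes, name = "genome") {
  partner <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(adj))) {
    a <- adj$v1[i]
    b <- adj$v2[i]
    if (is_telomere(a) && is_telomere(b)) stop("adjacency between two telomeres")
    if (!is_telomere(a)) {
      if (!is.null(partner[[a]])) stop("extremity ", a, " in two adjacencies")
      partner[[a]] <- b
    }
    if (!is_telomere(b)) {
      if (!is.null(partner[[b]])) stop("extremity ", b, " in two adjacencies")
      partner[[b]] <- a
    }
  }
  other_end <- function(e) {
    gene <- sub(":[th]$", "", e)
    if (endsWith(e, ":t")) paste0(gene, ":h") else paste0(gene, ":t")
  }
  seen <- new.env(parent = emptyenv())
  chroms <- list()
  trace_from <- function(start, circular) {
    toks <- character(0)
    e <- start
    repeat {
      gene <- sub(":[th]$", "", e)
      sign <- if (endsWith(e, ":t")) "+" else "-"
      toks <- c(toks, paste0(sign, gene))
      seen[[gene]] <- TRUE
      nxt <- partner[[other_end(e)]]
      if (is.null(nxt)) stop("extremity ", other_end(e), " has no adjacency")
      if (is_telomere(nxt)) break
      if (circular && nxt == start) break
      e <- nxt
    }
    toks
  }
  # linear chromosomes first: start from each telomere-attached extremity
  for (i in seq_len(nrow(adj))) {
    for (cols in list(c(adj$v1[i], adj$v2[i]), c(adj$v2[i], adj$v1[i]))) {
      if (is_telomere(cols[1]) && !is_telomere(cols[2])) {
        gene <- sub(":[th]$", "", cols[2])
        if (!is.null(seen[[gene]])) next
        chroms[[length(chroms) + 1L]] <-
          chromosome(trace_from(cols[2], circular = FALSE), circular = FALSE)
      }
    }
  }
  # remaining genes lie on circular chromosomes
  for (g in genes) {
    if (is.null(seen[[g]])) {
      chroms[[length(chroms) + 1L]] <-
        chromosome(trace_from(paste0(g, ":t"), circular = TRUE), circular = TRUE)
    }
  }
  genome(chroms, name = name)
}
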