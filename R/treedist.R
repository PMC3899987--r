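#' Edit cost model for structure forests
#'
#' Interior PAIR nodes stand for base pairs (two nucleotides) and UNPAIRED
#' leaves for single nucleotides, so insertion/deletion costs default to 2
#' and 1 respectively.  Substituting a node for one of the same kind is
#' free; substituting PAIR for UNPAIRED (or vice versa) costs the
#' nucleotide-count difference, 1, which is also cheaper than the
#' delete-plus-insert alternative.  Set `sub_pair_unpaired = Inf` (or any
#' value above `indel_pair + indel_unpaired`) is rejected: a substitution
#' must never cost more than deleting one node and inserting the other.
#'
#' @param indel_pair Insertion/deletion cost of a PAIR node (default 2).
#' @param indel_unpaired Insertion/deletion cost of an UNPAIRED leaf
#'   (default 1).
#' @param sub_pair_unpaired Cost of relabeling PAIR as UNPAIRED or vice
#'   versa (default 1).
#' @return An object of class `cost_model`.
#' @examples
#' cost_model()
#' cost_model(sub_pair_unpaired = 3)  # equivalent to substitution disabled
#' @export
cost_model <- function(indel_pair = 2, indel_unpaired = 1,
                       sub_pair_unpaired = 1) {
  for (v in list(indel_pair, indel_unpaired, sub_pair_unpaired))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("all costs must be single non-negative numbers", call. = FALSE)
  if (sub_pair_unpaired > indel_pair + indel_unpaired)
    stop("sub_pair_unpaired must not exceed indel_pair + indel_unpaired",
         call. = FALSE)
  structure(list(indel_pair = as.numeric(indel_pair),
                 indel_unpaired = as.numeric(indel_unpaired),
                 sub_pair_unpaired = as.numeric(sub_pair_unpaired)),
            class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat(sprintf("<cost_model> indel pair %g, indel unpaired %g, sub pair<->unpaired %g\n",
              x$indel_pair, x$indel_unpaired, x$sub_pair_unpaired))
  invisible(x)
}

# del_cost vector indexed by type code + 1 (0 unpaired, 1 pair, 2 virtual
# root) and the 3x3 substitution matrix.  The virtual root is free to
# indel and to match against itself; matching it against a real node is
# blocked with a prohibitive cost so that attaching virtual roots leaves
# the forest edit distance unchanged.
.cost_tables <- function(cost) {
  stopifnot(inherits(cost, "cost_model"))
  del <- c(cost$indel_unpaired, cost$indel_pair, 0)
  sub <- matrix(0, 3, 3)
  sub[1, 2] <- sub[2, 1] <- cost$sub_pair_unpaired
  sub[1, 3] <- sub[3, 1] <- sub[2, 3] <- sub[3, 2] <- 1e9
  list(del = del, sub = sub)
}

#' Tree edit distance between two structure forests
#'
#' Minimum total cost of node insertions, deletions and substitutions
#' transforming one ordered forest into the other, computed with the
#' keyroot / leftmost-leaf dynamic program of Zhang and Shasha.
#' Multi-rooted forests are handled by attaching a shared virtual root of
#' zero cost, so the value is the canonical forest edit distance.  Under
#' the default cost model all distances are integers and the function is a
#' metric on forests (unlike tree alignment costs, which violate the
#' triangle inequality).
#'
#' @param f1,f2 `rna_forest` objects (see [parse_dotbracket()]).
#' @param cost A [cost_model()].
#' @return A single non-negative number.
#' @examples
#' tree_edit_distance(parse_dotbracket("((..))"), parse_dotbracket("(..)"))
#' @export
tree_edit_distance <- function(f1, f2, cost = cost_model()) {
  stopifnot(inherits(f1, "rna_forest"), inherits(f2, "rna_forest"))
  tab <- .cost_tables(cost)
  p1 <- forest_postorder(f1)
  p2 <- forest_postorder(f2)
  zs_tree_edit(p1$type, p1$lml, p1$keyroots,
               p2$type, p2$lml, p2$keyroots,
               tab$del, tab$sub)
}

#' Exact forest edit distance by memoized textbook recursion (oracle)
#'
#' Direct implementation of the three-way edit recursion on dot-bracket
#' substrings (delete rightmost root of one forest, insert rightmost root
#' of the other, or match the two rightmost roots), memoized on string
#' pairs and without the keyroot optimization.  It shares only the cost
#' semantics with [tree_edit_distance()] and serves as an independent
#' testing oracle; it refuses forests above `max_nodes` nodes.
#'
#' @inheritParams tree_edit_distance
#' @param max_nodes Refusal threshold on the node count of either forest.
#' @return A single non-negative number.
#' @export
brute_force_distance <- function(f1, f2, cost = cost_model(),
                                 max_nodes = 14L) {
  stopifnot(inherits(f1, "rna_forest"), inherits(f2, "rna_forest"))
  s1 <- to_dotbracket(f1)
  s2 <- to_dotbracket(f2)
  nodes <- function(s) nchar(gsub(")", "", s, fixed = TRUE))
  if (nodes(s1) > max_nodes || nodes(s2) > max_nodes)
    stop(sprintf("brute_force_distance refuses forests above %d nodes",
                 max_nodes), call. = FALSE)
  cp <- cost$indel_pair; cu <- cost$indel_unpaired
  cs <- cost$sub_pair_unpaired

  # split a forest string into (prefix forest, rightmost-root kind,
  # rightmost root's child forest)
  rsplit <- function(s) {
    n <- nchar(s)
    last <- substr(s, n, n)
    if (last == ".")
      return(list(prefix = substr(s, 1L, n - 1L), pair = FALSE, inner = ""))
    depth <- 0L
    for (i in n:1) {
      ch <- substr(s, i, i)
      if (ch == ")") depth <- depth + 1L
      else if (ch == "(") {
        depth <- depth - 1L
        if (depth == 0L)
          return(list(prefix = substr(s, 1L, i - 1L), pair = TRUE,
                      inner = substr(s, i + 1L, n - 1L)))
      }
    }
    stop("unbalanced forest string", call. = FALSE)
  }
  wt <- function(s) {
    npair <- nchar(gsub("[).]", "", s))
    nleaf <- nchar(gsub("[()]", "", s))
    cp * npair + cu * nleaf
  }
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(a, b) {
    if (a == "") return(wt(b))
    if (b == "") return(wt(a))
    key <- paste(a, b, sep = "|")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    ra <- rsplit(a); rb <- rsplit(b)
    da <- if (ra$pair) cp else cu
    db <- if (rb$pair) cp else cu
    best <- min(
      da + rec(paste0(ra$prefix, ra$inner), b),
      db + rec(a, paste0(rb$prefix, rb$inner)),
      (if (ra$pair == rb$pair) 0 else cs) +
        rec(ra$prefix, rb$prefix) + rec(ra$inner, rb$inner))
    memo[[key]] <- best
    best
  }
  rec(s1, s2)
}

#' All-vs-all tree edit distance matrix
#'
#' Computes the `n(n-1)/2` upper-triangle distances between consensus
#' structures and mirrors them into a symmetric matrix with zero diagonal.
#' Row/column order follows the input order of the families.
#'
#' @param structures A data frame with columns `accession` and `structure`
#'   (dot-bracket strings), e.g. from [read_stockholm()], or a named
#'   character vector of dot-bracket strings.
#' @param cost A [cost_model()].
#' @param progress_every Emit a progress message every this many pairs
#'   (0, the default, disables progress output).
#' @return A symmetric numeric matrix with the accessions as dimnames and
#'   an attribute `n_comparisons` recording how many pairwise distances
#'   were computed.
#' @examples
#' m <- distance_matrix(c(a = "(..)", b = "(..)", c = ""))
#' m
#' @export
distance_matrix <- function(structures, cost = cost_model(),
                            progress_every = 0L) {
  if (is.data.frame(structures)) {
    acc <- as.character(structures$accession)
    db <- as.character(structures$structure)
  } else if (is.character(structures)) {
    acc <- names(structures)
    db <- unname(structures)
  } else stop("`structures` must be a data frame or named character vector",
              call. = FALSE)
  n <- length(db)
  if (n < 2L) stop("need at least 2 structures", call. = FALSE)
  if (is.null(acc) || anyNA(acc) || any(acc == ""))
    stop("every structure needs an accession", call. = FALSE)
  dup <- acc[duplicated(acc)]
  if (length(dup))
    stop(sprintf("duplicate accession(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)

  tab <- .cost_tables(cost)
  post <- lapply(db, function(s) forest_postorder(parse_dotbracket(s)))
  m <- matrix(0, n, n, dimnames = list(acc, acc))
  done <- 0L
  total <- n * (n - 1L) / 2L
  for (i in seq_len(n - 1L)) {
    pi_ <- post[[i]]
    for (j in (i + 1L):n) {
      pj <- post[[j]]
      m[i, j] <- m[j, i] <- zs_tree_edit(
        pi_$type, pi_$lml, pi_$keyroots,
        pj$type, pj$lml, pj$keyroots, tab$del, tab$sub)
      done <- done + 1L
      if (progress_every > 0L && done %% progress_every == 0L)
        message(sprintf("distance_matrix: %d / %d pairs", done, total))
    }
  }
  attr(m, "n_comparisons") <- done
  m
}

#' Write / read a square PHYLIP distance matrix
#'
#' The strict dialect pads or truncates names to 10 characters; the
#' relaxed dialect writes full names followed by whitespace.  Values are
#' space-separated with six decimals, one row per family.
#'
#' @param m Symmetric numeric matrix with dimnames.
#' @param path Output (or input) file path.
#' @param relaxed Use the relaxed long-name dialect (default `TRUE`).
#' @return `write_phylip_matrix()` returns `path` invisibly;
#'   `read_phylip_matrix()` returns a symmetric matrix with dimnames.
#' @export
write_phylip_matrix <- function(m, path, relaxed = TRUE) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  n <- nrow(m)
  nm <- rownames(m)
  if (!relaxed) nm <- formatC(substr(nm, 1L, 10L), width = 10L, flag = "-")
  rows <- vapply(seq_len(n), function(i)
    paste0(nm[i], if (relaxed) "\t" else "",
           paste(sprintf("%.6f", m[i, ]), collapse = " ")),
    character(1))
  writeLines(c(sprintf("%5d", n), rows), path)
  invisible(path)
}

#' @rdname write_phylip_matrix
#' @export
read_phylip_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty distance matrix file", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L)
    stop("first line must be the matrix dimension", call. = FALSE)
  body <- lines[-1]
  if (length(body) != n)
    stop(sprintf("header says %d rows but file has %d", n, length(body)),
         call. = FALSE)
  nm <- character(n)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(body[i]), "[ \t]+")[[1]]
    if (length(fields) != n + 1L)
      stop(sprintf("row %d has %d values, expected %d", i,
                   length(fields) - 1L, n), call. = FALSE)
    nm[i] <- fields[1]
    m[i, ] <- as.numeric(fields[-1])
  }
  if (anyNA(m)) stop("non-numeric distance entries", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-6)
    stop("matrix is not symmetric", call. = FALSE)
  dimnames(m) <- list(nm, nm)
  m
}
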