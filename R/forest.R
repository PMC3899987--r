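#' Ordered-forest representation of an RNA secondary structure
#'
#' A dot-bracket string has a natural reading as an ordered forest: every
#' matched pair of parentheses is an interior PAIR node whose children are
#' the forest of the enclosed substring, and every dot is an UNPAIRED leaf.
#' Sibling order follows string order and is significant everywhere; the
#' forest carries no nucleotide labels because only structures are compared.
#'
#' @param db A single dot-bracket string over the alphabet `(`, `)`, `.`.
#'   The empty string yields an empty forest.
#' @return An object of class `rna_forest`: a list with element `roots`,
#'   an ordered list of nodes.  Each node is a list with elements `pair`
#'   (logical) and `children` (list, empty for UNPAIRED leaves).
#' @examples
#' f <- parse_dotbracket("((..))")
#' forest_weight(f)
#' to_dotbracket(f)
#' @seealso [to_dotbracket()], [forest_weight()], [tree_edit_distance()]
#' @export
parse_dotbracket <- function(db) {
  if (!is.character(db) || length(db) != 1L || is.na(db))
    stop("`db` must be a single dot-bracket string", call. = FALSE)
  n <- nchar(db)
  if (n == 0L)
    return(structure(list(roots = list()), class = "rna_forest"))
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("(", ")", "."))
  if (length(bad))
    stop(sprintf("invalid character '%s' at position %d (expected one of '(', ')', '.')",
                 chars[bad[1]], bad[1]), call. = FALSE)
  # stack of sibling lists; the bottom entry collects the root sequence
  stack <- list(list())
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch == ".") {
      top <- length(stack)
      stack[[top]][[length(stack[[top]]) + 1L]] <- .leaf_node
    } else if (ch == "(") {
      stack[[length(stack) + 1L]] <- list()
    } else {
      if (length(stack) == 1L)
        stop(sprintf("unbalanced ')' at position %d", i), call. = FALSE)
      kids <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      top <- length(stack)
      stack[[top]][[length(stack[[top]]) + 1L]] <-
        list(pair = TRUE, children = kids)
    }
  }
  if (length(stack) != 1L)
    stop(sprintf("unbalanced at end: %d unclosed '('", length(stack) - 1L),
         call. = FALSE)
  structure(list(roots = stack[[1]]), class = "rna_forest")
}

.leaf_node <- list(pair = FALSE, children = list())

#' Serialize an ordered forest back to dot-bracket notation
#'
#' Inverse of [parse_dotbracket()]: `to_dotbracket(parse_dotbracket(s))`
#' is `s` for every valid dot-bracket string.
#'
#' @param f An `rna_forest`.
#' @return A dot-bracket string (possibly empty).
#' @export
to_dotbracket <- function(f) {
  stopifnot(inherits(f, "rna_forest"))
  ser <- function(nodes) {
    if (!length(nodes)) return("")
    paste(vapply(nodes, function(nd) {
      if (nd$pair) paste0("(", ser(nd$children), ")") else "."
    }, character(1)), collapse = "")
  }
  ser(f$roots)
}

#' Count PAIR and UNPAIRED nodes of a forest
#'
#' @param f An `rna_forest`.
#' @return Named integer vector with elements `pair` and `unpaired`.
#' @export
forest_node_counts <- function(f) {
  stopifnot(inherits(f, "rna_forest"))
  np <- 0L; nu <- 0L
  walk <- function(nodes) {
    for (nd in nodes) {
      if (nd$pair) {
        np <<- np + 1L
        walk(nd$children)
      } else nu <<- nu + 1L
    }
  }
  walk(f$roots)
  c(pair = np, unpaired = nu)
}

#' Nucleotide weight of a forest
#'
#' Interior PAIR nodes represent base pairs (two nucleotides) and UNPAIRED
#' leaves single nucleotides, so the weight is `2 * #pairs + #unpaired`.
#' Under the default edit costs this equals the cost of deleting (or
#' inserting) the entire forest.
#'
#' @param f An `rna_forest`.
#' @return Non-negative integer.
#' @export
forest_weight <- function(f) {
  cnt <- forest_node_counts(f)
  unname(2L * cnt[["pair"]] + cnt[["unpaired"]])
}

#' @export
print.rna_forest <- function(x, ...) {
  db <- to_dotbracket(x)
  cnt <- forest_node_counts(x)
  cat(sprintf("<rna_forest> %d pair node(s), %d unpaired leaf/leaves\n",
              cnt[["pair"]], cnt[["unpaired"]]))
  cat(db, "\n")
  invisible(x)
}

#' Indented text dump of a forest (debug aid)
#'
#' @param f An `rna_forest`.
#' @return Character vector, one line per node, invisibly; printed to the
#'   console as a side effect.
#' @export
forest_dump <- function(f) {
  stopifnot(inherits(f, "rna_forest"))
  out <- character(0)
  walk <- function(nodes, depth) {
    for (nd in nodes) {
      out[[length(out) + 1L]] <<- paste0(
        strrep("  ", depth), if (nd$pair) "PAIR" else "UNPAIRED")
      if (nd$pair) walk(nd$children, depth + 1L)
    }
  }
  walk(f$roots, 0L)
  cat(out, sep = "\n")
  invisible(out)
}

# Postorder arrays used by the tree-edit dynamic program: node types
# (0 = unpaired, 1 = pair, 2 = virtual root), leftmost-leaf indices and
# LR keyroots.  A virtual root of type 2 is appended as the last postorder
# node so multi-rooted forests become trees; its indel/substitution cost
# is zero, which leaves the forest edit distance unchanged.
forest_postorder <- function(f) {
  stopifnot(inherits(f, "rna_forest"))
  type <- integer(0)
  lml <- integer(0)
  walk <- function(nodes) {
    for (nd in nodes) {
      if (nd$pair) {
        first <- length(type) + 1L
        walk(nd$children)
        id <- length(type) + 1L
        type[[id]] <<- 1L
        lml[[id]] <<- if (id > first) lml[[first]] else id
      } else {
        id <- length(type) + 1L
        type[[id]] <<- 0L
        lml[[id]] <<- id
      }
    }
  }
  walk(f$roots)
  vr <- length(type) + 1L
  type[[vr]] <- 2L
  lml[[vr]] <- if (vr > 1L) lml[[1L]] else vr
  keyroots <- which(!duplicated(lml, fromLast = TRUE))
  list(type = type, lml = lml, keyroots = keyroots)
}
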