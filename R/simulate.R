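#' Default structural class templates
#'
#' Three dot-bracket templates mirroring the complexity gradient seen
#' across real RNA families: a single stem-loop as in microRNA
#' precursors, a two-hairpin arrangement as in box H/ACA snoRNAs, and a
#' multiloop-rich fold reminiscent of larger structured RNAs.
#'
#' @return Named character vector of balanced dot-bracket strings.
#' @export
default_templates <- function() {
  c(hairpin   = "((((((....))))))",
    twohairpin = ".((((((...))))))...((((((...)))))).",
    multiloop = "(((..(((...)))..(((...)))..(((...)))..)))")
}

# sample() without its scalar-x surprise
.sample_from <- function(x, k) x[sample.int(length(x), k)]

# ---- forest surgery helpers (structure-space mutation) ----------------

# list of all node paths; a path is the vector of child indices from the
# top level down (the top-level root list acts as one sibling list)
.forest_paths <- function(roots) {
  out <- list()
  walk <- function(nodes, prefix) {
    for (i in seq_along(nodes)) {
      p <- c(prefix, i)
      out[[length(out) + 1L]] <<- p
      if (nodes[[i]]$pair) walk(nodes[[i]]$children, p)
    }
  }
  walk(roots, integer(0))
  out
}

.get_siblings <- function(roots, path) {
  # sibling list addressed by a (possibly empty) path of pair nodes
  cur <- roots
  for (i in path) cur <- cur[[i]]$children
  cur
}

.set_siblings <- function(roots, path, value) {
  if (!length(path)) return(value)
  head <- path[1]
  roots[[head]]$children <-
    .set_siblings(roots[[head]]$children, path[-1], value)
  roots
}

# paths of all sibling lists: the top level plus every pair node
.sibling_list_paths <- function(roots) {
  pair_paths <- Filter(function(p) {
    cur <- roots
    for (i in p[-length(p)]) cur <- cur[[i]]$children
    cur[[p[length(p)]]]$pair
  }, .forest_paths(roots))
  c(list(integer(0)), pair_paths)
}

#' Randomly perturb a secondary structure
#'
#' Applies edits directly in structure space: each node of the forest is,
#' with probability `rate`, subject to one of three elementary operations
#' chosen uniformly — delete the node (its children are promoted to the
#' parent), insert a new unpaired leaf at a random position, or wrap a
#' random contiguous run of siblings in a new pair node.  The number of
#' edits is drawn as `Binomial(#nodes, rate)` and the edits are applied
#' sequentially to the evolving structure.  Uses the R random number
#' generator; seed with [set.seed()] for reproducibility.
#'
#' @param db Balanced dot-bracket string.
#' @param rate Per-node edit probability in `[0, 1]`.
#' @return A balanced dot-bracket string (possibly empty).
#' @export
mutate_structure <- function(db, rate) {
  stopifnot(is.numeric(rate), rate >= 0, rate <= 1)
  f <- parse_dotbracket(db)
  n0 <- sum(forest_node_counts(f))
  if (rate == 0 || n0 == 0L) return(db)
  k <- stats::rbinom(1L, n0, rate)
  roots <- f$roots
  for (e in seq_len(k)) {
    n_nodes <- length(.forest_paths(roots))
    ops <- c("delete", "insert", "wrap")
    if (n_nodes == 0L) ops <- c("insert", "wrap")
    op <- sample(ops, 1L)
    if (op == "delete") {
      p <- .forest_paths(roots)[[sample.int(n_nodes, 1L)]]
      sibs <- .get_siblings(roots, p[-length(p)])
      i <- p[length(p)]
      repl <- sibs[[i]]$children        # empty for a leaf
      sibs <- append(sibs[-i], repl, after = i - 1L)
      roots <- .set_siblings(roots, p[-length(p)], sibs)
    } else if (op == "insert") {
      slots <- .sibling_list_paths(roots)
      sp <- slots[[sample.int(length(slots), 1L)]]
      sibs <- .get_siblings(roots, sp)
      at <- sample.int(length(sibs) + 1L, 1L) - 1L
      sibs <- append(sibs, list(.leaf_node), after = at)
      roots <- .set_siblings(roots, sp, sibs)
    } else {
      slots <- .sibling_list_paths(roots)
      sp <- slots[[sample.int(length(slots), 1L)]]
      sibs <- .get_siblings(roots, sp)
      if (length(sibs)) {
        i <- sample.int(length(sibs), 1L)
        j <- i + sample.int(length(sibs) - i + 1L, 1L) - 1L
        wrapped <- list(pair = TRUE, children = sibs[i:j])
        sibs <- append(sibs[-(i:j)], list(wrapped), after = i - 1L)
      } else {
        sibs <- list(list(pair = TRUE, children = list()))
      }
      roots <- .set_siblings(roots, sp, sibs)
    }
  }
  to_dotbracket(structure(list(roots = roots), class = "rna_forest"))
}

#' Simulation parameters for Rfam-like synthetic datasets
#'
#' @param n_classes Number of planted structural classes (uses the first
#'   `n_classes` templates).
#' @param families_per_class Families generated per class.
#' @param templates Named character vector of balanced dot-bracket class
#'   templates; defaults to [default_templates()].
#' @param mutation_rate Per-node structure edit probability applied to
#'   each family's copy of its class template.
#' @param n_tight_clans Number of planted within-class clans.
#' @param n_dispersed_clans Number of planted clans spanning two or more
#'   classes.
#' @param clan_size Members per planted clan (at least 2).
#' @param seed Integer seed driving all randomness of the simulation.
#' @return A list of validated parameters, class `sim_params`.
#' @export
sim_params <- function(n_classes = 3L, families_per_class = 20L,
                       templates = default_templates(),
                       mutation_rate = 0.03,
                       n_tight_clans = 2L, n_dispersed_clans = 2L,
                       clan_size = 4L, seed = 1L) {
  stopifnot(n_classes >= 1L, n_classes <= length(templates),
            families_per_class >= 1L,
            mutation_rate >= 0, mutation_rate <= 1,
            n_tight_clans >= 0L, n_dispersed_clans >= 0L,
            clan_size >= 2L)
  for (tm in templates) parse_dotbracket(tm)  # validates balance
  structure(list(n_classes = as.integer(n_classes),
                 families_per_class = as.integer(families_per_class),
                 templates = templates[seq_len(n_classes)],
                 mutation_rate = mutation_rate,
                 n_tight_clans = as.integer(n_tight_clans),
                 n_dispersed_clans = as.integer(n_dispersed_clans),
                 clan_size = as.integer(clan_size),
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Generate a synthetic Rfam-like dataset
#'
#' Families are independent structural mutations of their class template
#' (accessions `SYN00001`, `SYN00002`, ...).  Planted *tight* clans
#' sample members from a single class; planted *dispersed* clans sample
#' across at least two classes.  Every family belongs to exactly one
#' class and at most one clan.  The whole dataset is reproducible from
#' the seed in the parameters.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `synthetic_dataset` with elements
#'   `families` (data frame in [read_stockholm()] layout plus a `class`
#'   column), `clans` (named list, tight clans `CLT...`, dispersed clans
#'   `CLD...`) and `classes` (named character vector accession -> class).
#' @export
simulate_families <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  cls_names <- names(params$templates)
  if (is.null(cls_names))
    cls_names <- paste0("class", seq_len(params$n_classes))
  total <- params$n_classes * params$families_per_class
  acc <- sprintf("SYN%05d", seq_len(total))
  klass <- rep(cls_names, each = params$families_per_class)
  structure_str <- character(total)
  idx <- 0L
  for (ci in seq_len(params$n_classes)) {
    for (fi in seq_len(params$families_per_class)) {
      idx <- idx + 1L
      structure_str[idx] <- mutate_structure(params$templates[[ci]],
                                             params$mutation_rate)
    }
  }
  fam <- data.frame(
    accession = acc,
    id = sprintf("%s-%02d", klass,
                 sequence(rep(params$families_per_class, params$n_classes))),
    description = sprintf("class:%s synthetic consensus structure", klass),
    ss_cons_raw = structure_str,
    structure = structure_str,
    class = klass,
    stringsAsFactors = FALSE)

  # plant clans on disjoint family sets
  need <- (params$n_tight_clans + params$n_dispersed_clans) * params$clan_size
  if (need > total)
    stop("clan sizes exceed the number of available families", call. = FALSE)
  if (params$n_dispersed_clans > 0L && params$n_classes < 2L)
    stop("dispersed clans need at least 2 classes", call. = FALSE)
  avail <- split(seq_len(total), klass)
  clans <- list()
  for (tcl in seq_len(params$n_tight_clans)) {
    # pick the class with the most unassigned families
    sizes <- lengths(avail)
    cls <- names(sizes)[which.max(sizes)]
    if (sizes[[cls]] < params$clan_size)
      stop("not enough unassigned families in one class for a tight clan",
           call. = FALSE)
    pick <- sort(.sample_from(avail[[cls]], params$clan_size))
    avail[[cls]] <- setdiff(avail[[cls]], pick)
    clans[[sprintf("CLT%04d", tcl)]] <- acc[pick]
  }
  for (dcl in seq_len(params$n_dispersed_clans)) {
    pool_classes <- names(avail)[lengths(avail) > 0L]
    if (length(pool_classes) < 2L)
      stop("not enough classes with unassigned families for a dispersed clan",
           call. = FALSE)
    # guarantee >= 2 classes, then fill uniformly from the remaining pool
    first_two <- .sample_from(pool_classes, 2L)
    pick <- vapply(first_two, function(cl) .sample_from(avail[[cl]], 1L),
                   integer(1))
    for (cl in first_two) avail[[cl]] <- setdiff(avail[[cl]], pick)
    pool <- unlist(avail, use.names = FALSE)
    if (length(pool) < params$clan_size - 2L)
      stop("clan sizes exceed the number of available families",
           call. = FALSE)
    extra <- sort(.sample_from(pool, params$clan_size - 2L))
    for (cl in names(avail)) avail[[cl]] <- setdiff(avail[[cl]], extra)
    pick <- sort(c(pick, extra))
    clans[[sprintf("CLD%04d", dcl)]] <- acc[pick]
  }
  classes <- stats::setNames(klass, acc)
  structure(list(families = fam, clans = clans, classes = classes,
                 params = params),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d families in %d classes, %d clans (seed %d)\n",
              nrow(x$families), length(unique(x$families$class)),
              length(x$clans), x$params$seed))
  invisible(x)
}

#' Write a synthetic dataset as Stockholm + clan TSV
#'
#' Emits `families.sto` (one minimal Stockholm record per family with a
#' single gapless placeholder sequence row, so the file is structurally
#' valid Stockholm 1.0) and `clans.tsv` (two-column group/family table).
#' `read_stockholm()` on the written file recovers all structures
#' exactly.
#'
#' @param ds A `synthetic_dataset` from [simulate_families()].
#' @param dir Output directory (created if missing).
#' @return Named character vector with the paths `stockholm` and `clans`,
#'   invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sto <- file.path(dir, "families.sto")
  con <- file(sto, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ds$families))) {
    r <- ds$families[i, ]
    len <- nchar(r$structure)
    writeLines(c(
      "# STOCKHOLM 1.0",
      paste0("#=GF AC ", r$accession),
      paste0("#=GF ID ", r$id),
      paste0("#=GF DE ", r$description),
      if (len > 0)
        c(sprintf("%s/1-%d %s", r$accession, len, strrep("A", len)),
          paste0("#=GC SS_cons ", r$structure))
      else paste0("#=GC SS_cons ", r$structure),
      "//"), con)
  }
  clan_path <- file.path(dir, "clans.tsv")
  rows <- unlist(lapply(names(ds$clans), function(g)
    paste(g, ds$clans[[g]], sep = "\t")))
  writeLines(c("# group\tfamily", rows), clan_path)
  invisible(c(stockholm = sto, clans = clan_path))
}
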