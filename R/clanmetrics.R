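#' Clan / class concordance scores for a dendrogram
#'
#' Given an externally defined group of families G (an Rfam clan, an RNA
#' class, ...) and a dendrogram T over all families, three scores measure
#' how well the clustering recovers the group:
#'
#' * **alpha** — the maximal Jaccard index
#'   `max over clusters C of |G intersect C| / |G union C|`,
#'   a compromise between coverage and contamination; 1 exactly when the
#'   group's leaf set equals some subtree's leaf set.
#' * **beta** — `|G| / |C_min|`, where `C_min` is the smallest cluster
#'   that entirely contains G (the leaf set below the lowest common
#'   ancestor of G).  A dispersion measure, sensitive to single outliers.
#' * **gamma** — a height-based dispersion measure,
#'   `h_in(G) / h(C_min)` with `h_in(G)` the largest height of a node
#'   whose leaf set lies entirely inside G.  Unlike beta it does not
#'   punish groups of very similar families: by convention gamma is 1 for
#'   singletons and when `h(C_min) = 0`.
#'
#' All three equal 1 when G appears as a cluster of the dendrogram.
#' Group members missing from the dendrogram are dropped with a warning;
#' a group with no member left is an error.
#'
#' @param t An `rna_dendrogram` (see [agglomerate()]).
#' @param g Character vector of member accessions.
#' @return `max_jaccard_alpha()`, `beta_dispersion()` and
#'   `gamma_dispersion()` each return a single number.
#' @examples
#' m <- matrix(c(0, 2, 6, 2, 0, 8, 6, 8, 0), 3, 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' t <- agglomerate(m, "single")          # ((a,b)@2, c)@6
#' max_jaccard_alpha(t, c("a", "c"))      # 2/3
#' beta_dispersion(t, c("a", "c"))        # 2/3
#' gamma_dispersion(t, c("a", "c"))       # 0
#' @name clan_scores
NULL

# shared per-group evaluation over the cluster list of all_clusters()
.score_group <- function(clusters, labels, g, group = "<group>") {
  g <- unique(as.character(g))
  missing <- setdiff(g, labels)
  if (length(missing)) {
    warning(sprintf("%s: dropping %d member(s) absent from the dendrogram: %s",
                    group, length(missing), paste(missing, collapse = ", ")),
            call. = FALSE)
    g <- setdiff(g, missing)
  }
  if (!length(g))
    stop(sprintf("%s: no group member is a leaf of the dendrogram", group),
         call. = FALSE)
  ng <- length(g)
  best_j <- 0; best_size <- NA_integer_
  cmin_size <- NA_integer_; cmin_h <- NA_real_
  h_in <- 0
  for (cl in clusters) {
    ninter <- sum(cl$members %in% g)
    nc <- length(cl$members)
    j <- ninter / (ng + nc - ninter)
    if (j > best_j + 1e-12 ||
        (abs(j - best_j) <= 1e-12 && !is.na(best_size) && nc < best_size)) {
      best_j <- j; best_size <- nc
    }
    if (ninter == ng && (is.na(cmin_size) || nc < cmin_size)) {
      cmin_size <- nc; cmin_h <- cl$height
    }
    if (ninter == nc && cl$height > h_in) h_in <- cl$height
  }
  gamma <- if (ng == 1L || cmin_h == 0) 1 else h_in / cmin_h
  list(size = ng, alpha = best_j, beta = ng / cmin_size, gamma = gamma,
       best_cluster_size = best_size, enclosing_cluster_size = cmin_size)
}

#' @rdname clan_scores
#' @export
max_jaccard_alpha <- function(t, g) {
  stopifnot(inherits(t, "rna_dendrogram"))
  .score_group(all_clusters(t), t$labels, g)$alpha
}

#' @rdname clan_scores
#' @export
beta_dispersion <- function(t, g) {
  stopifnot(inherits(t, "rna_dendrogram"))
  .score_group(all_clusters(t), t$labels, g)$beta
}

#' @rdname clan_scores
#' @export
gamma_dispersion <- function(t, g) {
  stopifnot(inherits(t, "rna_dendrogram"))
  .score_group(all_clusters(t), t$labels, g)$gamma
}

#' Score every group of a clan map against a dendrogram
#'
#' One row per group with the three concordance scores (see
#' [clan_scores]).  Rows are ordered by descending beta, ties by
#' descending alpha, then by group accession, giving a deterministic
#' rank-plot ordering from the tightest to the most dispersed group.
#'
#' @param t An `rna_dendrogram`.
#' @param clans A clan map as returned by [read_clan_map()]: named list of
#'   member-accession vectors.
#' @return Data frame with columns `group`, `size`, `alpha`, `beta`,
#'   `gamma`, `best_cluster_size`, `enclosing_cluster_size`.
#' @export
clan_report <- function(t, clans) {
  stopifnot(inherits(t, "rna_dendrogram"), is.list(clans),
            !is.null(names(clans)))
  clusters <- all_clusters(t)
  rows <- lapply(names(clans), function(gname) {
    sc <- .score_group(clusters, t$labels, clans[[gname]], gname)
    data.frame(group = gname, size = sc$size, alpha = sc$alpha,
               beta = sc$beta, gamma = sc$gamma,
               best_cluster_size = sc$best_cluster_size,
               enclosing_cluster_size = sc$enclosing_cluster_size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$beta, -out$alpha, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a clan report as TSV
#'
#' @param report Data frame from [clan_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clan_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
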