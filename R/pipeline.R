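#' Run the full clustering pipeline on one dataset
#'
#' Chains the stages end to end: read Stockholm, normalize structures,
#' all-vs-all tree edit distances, agglomerative clustering, optional
#' clan scoring and optional SVG rendering.  Every intermediate artifact
#' is written as a plain file (TSV / PHYLIP / Newick / SVG) so any stage
#' can be re-run or inspected on its own, and a JSON run manifest records
#' inputs, parameters and timing.
#'
#' @param stockholm Path to a multi-record Stockholm file.
#' @param outdir Output directory (created if missing).
#' @param clans Optional path to a clan membership TSV.
#' @param method Clustering method: `"upgma"`, `"single"` or
#'   `"complete"`.
#' @param cost A [cost_model()].
#' @param rules Optional [highlight_rules()] for the rendering stage.
#' @param progress_every Progress interval for the distance stage.
#' @return Named list of output paths plus the in-memory results
#'   (`families`, `matrix`, `dendrogram`, `scores`), invisibly.
#' @export
run_pipeline <- function(stockholm, outdir, clans = NULL,
                         method = "upgma", cost = cost_model(),
                         rules = NULL, progress_every = 0L) {
  t0 <- Sys.time()
  for (p in c(stockholm, clans))
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("input file not found: %s", p), call. = FALSE)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)

  fam <- read_stockholm(stockholm)
  paths <- list(structures = file.path(outdir, "structures.tsv"))
  write_structures_tsv(fam, paths$structures)

  m <- distance_matrix(fam, cost, progress_every = progress_every)
  paths$matrix <- file.path(outdir, "distances.phylip")
  write_phylip_matrix(m, paths$matrix)

  dend <- agglomerate(m, method)
  paths$newick <- file.path(outdir, paste0("dendrogram_", method, ".nwk"))
  writeLines(to_newick(dend), paths$newick)

  scores <- NULL
  if (!is.null(clans)) {
    cm <- read_clan_map(clans)
    scores <- clan_report(dend, cm)
    paths$scores <- file.path(outdir, "clan_scores.tsv")
    write_clan_report(scores, paths$scores)
  }
  paths$svg <- file.path(outdir, "dendrogram.svg")
  render_dendrogram(dend, fam, rules, file = paths$svg)

  manifest <- list(
    inputs = list(stockholm = stockholm, clans = clans),
    parameters = list(method = method,
                      cost = unclass(cost)),
    n_families = nrow(fam),
    n_comparisons = attr(m, "n_comparisons"),
    outputs = paths,
    package_version = as.character(utils::packageVersion("forestclust")),
    wall_time_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  paths$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(c(paths, list(families = fam, matrix = m, dendrogram = dend,
                          scores = scores)))
}
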