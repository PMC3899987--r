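#' Leaf highlighting rules
#'
#' Each rule colors the leaves whose chosen metadata field matches a
#' regular expression.  Rules are applied in order and the first match
#' wins.
#'
#' @param pattern Character vector of regular expressions.
#' @param field One of `"accession"`, `"id"`, `"description"` per rule
#'   (recycled).
#' @param color Hex colors `#RRGGBB` (recycled).
#' @param label Legend text per rule (defaults to the pattern).
#' @return Data frame of class `highlight_rules`.
#' @export
highlight_rules <- function(pattern, field = "id", color = "#cc0000",
                            label = pattern) {
  n <- length(pattern)
  field <- rep_len(field, n); color <- rep_len(color, n)
  label <- rep_len(label, n)
  if (!all(field %in% c("accession", "id", "description")))
    stop("field must be accession, id or description", call. = FALSE)
  if (!all(grepl("^#[0-9A-Fa-f]{6}$", color)))
    stop("colors must be hex #RRGGBB strings", call. = FALSE)
  for (p in pattern) {
    ok <- tryCatch({ grepl(p, "x"); TRUE }, error = function(e) FALSE,
                   warning = function(w) FALSE)
    if (!ok) stop(sprintf("invalid regular expression: %s", p),
                  call. = FALSE)
  }
  structure(data.frame(pattern = pattern, field = field, color = color,
                       label = label, stringsAsFactors = FALSE),
            class = c("highlight_rules", "data.frame"))
}

#' Read highlight rules from a TSV file
#'
#' Columns: pattern, field, color, label (header optional; `#` comments
#' allowed).
#'
#' @param path Path to the rules TSV.
#' @return A [highlight_rules()] object.
#' @export
read_highlight_rules <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) && grepl("^pattern\\t", lines[1])) lines <- lines[-1]
  if (!length(lines)) return(highlight_rules(character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 4L)
  if (length(bad))
    stop(sprintf("rules line %d: expected 4 tab-separated fields", bad[1]),
         call. = FALSE)
  m <- do.call(rbind, fields)
  highlight_rules(m[, 1], m[, 2], m[, 3], m[, 4])
}

# first matching rule index per accession (NA when none matches)
.match_rules <- function(meta, rules) {
  hit <- rep(NA_integer_, nrow(meta))
  if (is.null(rules) || nrow(rules) == 0L) return(hit)
  for (r in seq_len(nrow(rules))) {
    vals <- meta[[rules$field[r]]]
    vals[is.na(vals)] <- ""
    m <- grepl(rules$pattern[r], vals) & is.na(hit)
    hit[m] <- r
  }
  hit
}

#' Per-rule match counts over family metadata
#'
#' Applies first-match-wins precedence and reports how many families each
#' rule colors plus how many are matched by no rule; the counts sum to
#' the number of families.
#'
#' @param meta Data frame with columns `accession`, `id`, `description`.
#' @param rules A [highlight_rules()] object (or `NULL`).
#' @return Data frame with columns `label` and `count`; the final row is
#'   labelled `<unmatched>`.
#' @export
match_report <- function(meta, rules = NULL) {
  hit <- .match_rules(meta, rules)
  nr <- if (is.null(rules)) 0L else nrow(rules)
  counts <- if (nr) tabulate(hit, nbins = nr) else integer(0)
  data.frame(
    label = c(if (nr) rules$label else character(0), "<unmatched>"),
    count = c(counts, sum(is.na(hit))),
    stringsAsFactors = FALSE)
}

.svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a dendrogram as a standalone SVG document
#'
#' Linear (rectangular) layout: leaves are evenly spaced down the right
#' edge in dendrogram order and the horizontal position of every internal
#' node is proportional to its height, the root lying leftmost.  Leaf
#' glyphs and labels are colored by the first matching highlight rule; a
#' legend lists the rules.  Branches longer than `height_cap` (if set)
#' are drawn at the cap with a double tick mark indicating shortening.
#'
#' @param t An `rna_dendrogram`.
#' @param meta Data frame with columns `accession`, `id`, `description`
#'   (e.g. from [read_stockholm()]); leaves without metadata are drawn
#'   unhighlighted with a warning.
#' @param rules A [highlight_rules()] object, or `NULL` for no
#'   highlighting.
#' @param file Output path; `NULL` returns the SVG text only.
#' @param width,row_height Page width and per-leaf row height in pixels.
#' @param height_cap Optional cap on displayed node heights.
#' @return The SVG document as a single string, invisibly when written to
#'   `file`.
#' @export
render_dendrogram <- function(t, meta = NULL, rules = NULL, file = NULL,
                              width = 800, row_height = 16,
                              height_cap = NULL) {
  stopifnot(inherits(t, "rna_dendrogram"))
  if (!is.null(rules) && !inherits(rules, "highlight_rules"))
    stop("`rules` must come from highlight_rules()", call. = FALSE)
  n <- length(t$labels)
  ord <- leaf_order(t)
  if (is.null(meta)) {
    meta <- data.frame(accession = t$labels, id = NA_character_,
                       description = NA_character_,
                       stringsAsFactors = FALSE)
  } else {
    missing <- setdiff(t$labels, meta$accession)
    if (length(missing)) {
      warning(sprintf("no metadata for %d leaf/leaves; drawn unhighlighted",
                      length(missing)), call. = FALSE)
      meta <- rbind(meta[, c("accession", "id", "description")],
                    data.frame(accession = missing, id = NA_character_,
                               description = NA_character_,
                               stringsAsFactors = FALSE))
    }
  }
  meta <- meta[match(t$labels, meta$accession), , drop = FALSE]
  hit <- .match_rules(meta, rules)
  leaf_color <- ifelse(is.na(hit), "#333333", if (is.null(rules)) ""
                       else rules$color[hit])

  hroot <- max(t$height, 1e-12)
  hmax <- if (is.null(height_cap)) hroot else min(height_cap, hroot)
  margin_l <- 20; margin_r <- 220; margin_t <- 20
  legend_h <- if (!is.null(rules) && nrow(rules)) 18 * nrow(rules) + 10 else 0
  plot_w <- width - margin_l - margin_r
  xpos <- function(h) margin_l + plot_w * (1 - pmin(h, hmax) / hmax)
  ypos <- stats::setNames(margin_t + legend_h +
                            row_height * (seq_len(n) - 0.5), ord)
  total_h <- margin_t + legend_h + row_height * n + 20

  el <- character(0)
  add <- function(...) el[[length(el) + 1L]] <<- paste0(...)

  # node coordinates bottom-up
  nx <- numeric(n - 1L); ny <- numeric(n - 1L)
  capped <- logical(n - 1L)
  coord <- function(k)
    if (k < 0L) c(xpos(0), ypos[[t$labels[-k]]]) else c(nx[k], ny[k])
  for (s in seq_len(n - 1L)) {
    a <- coord(t$merge[s, 1]); b <- coord(t$merge[s, 2])
    h <- t$height[s]
    capped[s] <- h > hmax + 1e-12
    nx[s] <- xpos(h)
    ny[s] <- (a[2] + b[2]) / 2
    for (child in list(a, b)) {
      add(sprintf(
        '<polyline fill="none" stroke="#555555" stroke-width="1" points="%.2f,%.2f %.2f,%.2f %.2f,%.2f"/>',
        child[1], child[2], nx[s], child[2], nx[s], ny[s]))
    }
    if (capped[s])  # double tick marking a shortened branch
      add(sprintf(
        '<path class="capped" stroke="#000000" stroke-width="1" d="M %.2f %.2f l -3 6 M %.2f %.2f l -3 6"/>',
        nx[s] + 6, ny[s] - 3, nx[s] + 10, ny[s] - 3))
  }
  for (i in seq_len(n)) {
    lab <- t$labels[i]
    col <- leaf_color[i]
    y <- ypos[[lab]]
    add(sprintf('<circle class="leaf" cx="%.2f" cy="%.2f" r="3" fill="%s"/>',
                xpos(0), y, col))
    add(sprintf(
      '<text x="%.2f" y="%.2f" font-size="10" font-family="monospace" fill="%s">%s</text>',
      xpos(0) + 8, y + 3, col, .svg_escape(lab)))
  }
  if (!is.null(rules) && nrow(rules)) {
    for (r in seq_len(nrow(rules))) {
      y <- margin_t + 18 * (r - 1) + 8
      add(sprintf('<rect x="%d" y="%.2f" width="10" height="10" fill="%s"/>',
                  margin_l, y - 8, rules$color[r]))
      add(sprintf(
        '<text x="%d" y="%.2f" font-size="11" font-family="sans-serif">%s</text>',
        margin_l + 16, y, .svg_escape(rules$label[r])))
    }
  }
  svg <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">\n',
            width, ceiling(total_h), width, ceiling(total_h)),
    '<rect width="100%" height="100%" fill="#ffffff"/>\n',
    paste(el, collapse = "\n"),
    "\n</svg>\n")
  if (!is.null(file)) {
    writeLines(svg, file, sep = "")
    return(invisible(svg))
  }
  svg
}
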