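#' Normalize a WUSS consensus structure to plain dot-bracket
#'
#' Rfam `SS_cons` lines use WUSS notation: four bracket families
#' `<>`, `[]`, `{}`, `()` for nested base pairs, the characters
#' `_ - , : . ~` for unpaired positions, and upper/lower-case letter pairs
#' for pseudoknots.  All bracket families map to `(` / `)`, every unpaired
#' symbol maps to `.`, and pseudoknot letters become `.` as well (crossing
#' pairs cannot be represented in an ordered tree).  Nesting is validated
#' with a type-aware stack, so improperly interleaved bracket families
#' such as `<[>]` are rejected even though their merged projection would
#' balance.
#'
#' @param ss A single non-empty WUSS string.
#' @return A dot-bracket string of the same length.
#' @examples
#' normalize_wuss("<<<__>>>")
#' normalize_wuss("::AA..aa")
#' @export
normalize_wuss <- function(ss) {
  if (!is.character(ss) || length(ss) != 1L || is.na(ss) || !nchar(ss))
    stop("`ss` must be a single non-empty string", call. = FALSE)
  chars <- strsplit(ss, "", fixed = TRUE)[[1]]
  openers <- c("<" = ">", "[" = "]", "{" = "}", "(" = ")")
  closers <- names(openers)
  names(closers) <- openers
  unpaired <- c("_", "-", ",", ":", ".", "~")
  out <- character(length(chars))
  stack <- character(0)
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch %in% names(openers)) {
      stack <- c(stack, ch)
      out[i] <- "("
    } else if (ch %in% names(closers)) {
      if (!length(stack))
        stop(sprintf("unbalanced '%s' at position %d", ch, i), call. = FALSE)
      top <- stack[length(stack)]
      if (openers[[top]] != ch)
        stop(sprintf("mismatched bracket '%s' at position %d (open '%s')",
                     ch, i, top), call. = FALSE)
      stack <- stack[-length(stack)]
      out[i] <- ")"
    } else if (ch %in% unpaired || grepl("^[A-Za-z]$", ch)) {
      out[i] <- "."
    } else {
      stop(sprintf("unknown WUSS character '%s' at position %d", ch, i),
           call. = FALSE)
    }
  }
  if (length(stack))
    stop(sprintf("unbalanced at end: %d unclosed bracket(s)", length(stack)),
         call. = FALSE)
  paste(out, collapse = "")
}

#' Read families from a multi-record Stockholm file
#'
#' Parses the Rfam seed dialect of Stockholm 1.0: records are delimited by
#' `//`; `#=GF AC`, `#=GF ID` and `#=GF DE` carry the accession, short
#' name and description; the `#=GC SS_cons` consensus structure may be
#' split across interleaved blocks, whose pieces are concatenated in
#' order.  Records lacking an `SS_cons` line are skipped with a message.
#' Per-residue (`#=GR`) and other annotations are ignored.
#'
#' @param path Path to a Stockholm file, or a character vector of lines
#'   when `text = TRUE`.
#' @param text Treat `path` as the file content rather than a path.
#' @return A data frame with one row per retained family and columns
#'   `accession`, `id`, `description`, `ss_cons_raw` (WUSS as read) and
#'   `structure` (normalized dot-bracket).
#' @export
read_stockholm <- function(path, text = FALSE) {
  lines <- if (text) path else readLines(path, warn = FALSE)
  # drop a leading format header; records may repeat it
  recs <- list()
  cur <- character(0)
  open_content <- FALSE
  for (ln in lines) {
    tl <- trimws(ln, which = "right")
    if (trimws(tl) == "//") {
      recs[[length(recs) + 1L]] <- cur
      cur <- character(0)
      open_content <- FALSE
    } else {
      cur <- c(cur, tl)
      if (nzchar(trimws(tl)) && !grepl("^# STOCKHOLM", tl))
        open_content <- TRUE
    }
  }
  if (open_content)
    stop(sprintf("record %d lacks its '//' terminator", length(recs) + 1L),
         call. = FALSE)

  parse_rec <- function(rl, idx) {
    gf <- function(tag) {
      hits <- grep(sprintf("^#=GF\\s+%s\\s+", tag), rl, value = TRUE)
      vals <- unique(trimws(sub(sprintf("^#=GF\\s+%s\\s+", tag), "", hits)))
      if (length(vals) > 1L && tag == "AC")
        stop(sprintf("record %d has conflicting #=GF AC lines", idx),
             call. = FALSE)
      if (!length(vals)) NA_character_ else paste(vals, collapse = " ")
    }
    ss_hits <- grep("^#=GC\\s+SS_cons\\s", rl, value = TRUE)
    ss <- if (length(ss_hits))
      paste(trimws(sub("^#=GC\\s+SS_cons\\s+", "", ss_hits)), collapse = "")
    else NA_character_
    list(accession = gf("AC"), id = gf("ID"), description = gf("DE"),
         ss_cons_raw = ss)
  }
  parsed <- lapply(seq_along(recs), function(i) parse_rec(recs[[i]], i))
  parsed <- Filter(function(p) !all(is.na(unlist(p))), parsed)

  keep <- vapply(parsed, function(p) !is.na(p$ss_cons_raw), logical(1))
  for (p in parsed[!keep])
    message(sprintf("skipping record %s: no #=GC SS_cons line",
                    if (is.na(p$accession)) "<no accession>" else p$accession))
  parsed <- parsed[keep]
  out <- data.frame(
    accession = vapply(parsed, `[[`, character(1), "accession"),
    id = vapply(parsed, `[[`, character(1), "id"),
    description = vapply(parsed, `[[`, character(1), "description"),
    ss_cons_raw = vapply(parsed, `[[`, character(1), "ss_cons_raw"),
    stringsAsFactors = FALSE)
  out$structure <- vapply(out$ss_cons_raw, normalize_wuss, character(1),
                          USE.NAMES = FALSE)
  out
}

#' Read a clan (group) membership table
#'
#' Two tab-separated columns per line: group accession, family accession.
#' Lines starting with `#` and blank lines are ignored.  A family listed
#' under more than one group keeps its last assignment, with a warning.
#'
#' @param path Path to the TSV file, or the content itself when
#'   `text = TRUE`.
#' @param text Treat `path` as content.
#' @return A named list mapping each group accession to the character
#'   vector of its member family accessions (a `ClanMap`).
#' @export
read_clan_map <- function(path, text = FALSE) {
  lines <- if (text) path else readLines(path, warn = FALSE)
  assign_group <- character(0)  # family -> group
  order_seen <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2L)
      stop(sprintf("line %d: expected 2 tab-separated fields, got %d",
                   i, length(fields)), call. = FALSE)
    grp <- trimws(fields[1]); fam <- trimws(fields[2])
    if (fam %in% names(assign_group) && assign_group[[fam]] != grp)
      warning(sprintf("family %s reassigned from %s to %s (last wins)",
                      fam, assign_group[[fam]], grp), call. = FALSE)
    assign_group[[fam]] <- grp
    if (!grp %in% order_seen) order_seen <- c(order_seen, grp)
  }
  out <- lapply(order_seen, function(g)
    names(assign_group)[assign_group == g])
  names(out) <- order_seen
  out[lengths(out) > 0L]
}

#' Write / read the accession-to-structure table
#'
#' Plain two-column TSV (`accession`, dot-bracket `structure`) used to
#' hand normalized structures between pipeline stages.
#'
#' @param families Data frame with `accession` and `structure` columns.
#' @param path Output (input) path.
#' @return `write_structures_tsv()` returns `path` invisibly;
#'   `read_structures_tsv()` returns a data frame.
#' @export
write_structures_tsv <- function(families, path) {
  stopifnot(all(c("accession", "structure") %in% names(families)))
  utils::write.table(families[, c("accession", "structure")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_structures_tsv
#' @export
read_structures_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!all(c("accession", "structure") %in% names(df)))
    stop("structures TSV needs 'accession' and 'structure' columns",
         call. = FALSE)
  df$structure[is.na(df$structure)] <- ""
  df
}
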