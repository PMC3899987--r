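.render_fixture <- function() {
  m <- matrix(c(0, 2, 6, 2, 0, 8, 6, 8, 0), 3, 3,
              dimnames = list(c("RF1", "RF2", "RF3"), c("RF1", "RF2", "RF3")))
  t <- agglomerate(m, "upgma")
  meta <- data.frame(accession = c("RF1", "RF2", "RF3"),
                     id = c("mir-101", "mir-102", "SNORD42"),
                     description = c("microRNA", "microRNA", "snoRNA"),
                     stringsAsFactors = FALSE)
  list(t = t, meta = meta)
}

test_that("rule validation rejects bad regexes, colors and fields", {
  expect_error(highlight_rules("([", "id", "#ff0000"), "invalid regular")
  expect_error(highlight_rules("^mir-", "id", "red"), "hex")
  expect_error(highlight_rules("^mir-", "name"), "field must be")
  r <- highlight_rules(c("^mir-", "SNOR"), c("id", "id"),
                       c("#cc0000", "#00cc00"), c("miRNA", "snoRNA"))
  expect_s3_class(r, "highlight_rules")
  expect_equal(nrow(r), 2L)
})

test_that("match_report applies first-match precedence and counts add up", {
  fx <- .render_fixture()
  rules <- highlight_rules(c("^mir-", "micro"), c("id", "description"),
                           c("#cc0000", "#0000cc"), c("a", "b"))
  rep <- match_report(fx$meta, rules)
  expect_equal(rep$count[rep$label == "a"], 2L)   # rule 1 claims both mirs
  expect_equal(rep$count[rep$label == "b"], 0L)
  expect_equal(rep$count[rep$label == "<unmatched>"], 1L)
  expect_equal(sum(rep$count), nrow(fx$meta))

  rep0 <- match_report(fx$meta, NULL)
  expect_equal(rep0$count, 3L)

  all_rule <- highlight_rules(".", "accession", "#123456", "all")
  repa <- match_report(fx$meta, all_rule)
  expect_equal(repa$count, c(3L, 0L))
})

test_that("the SVG is well-formed, one glyph per leaf, highlighted as ruled", {
  skip_if_not_installed("xml2")
  fx <- .render_fixture()
  rules <- highlight_rules("^SNOR", "id", "#00aa00", "snoRNA")
  svg <- render_dendrogram(fx$t, fx$meta, rules)
  doc <- xml2::read_xml(svg)   # errors if not well-formed XML
  ns <- xml2::xml_ns(doc)
  circles <- xml2::xml_find_all(doc, ".//d1:circle[@class='leaf']", ns)
  expect_length(circles, 3L)
  greens <- Filter(function(x) xml2::xml_attr(x, "fill") == "#00aa00",
                   circles)
  expect_length(greens, 1L)
  legend <- xml2::xml_find_all(doc, ".//d1:rect[@fill='#00aa00']", ns)
  expect_length(legend, 1L)
})

test_that("x coordinates decrease with node height and the cap draws a tick", {
  skip_if_not_installed("xml2")
  fx <- .render_fixture()
  svg <- render_dendrogram(fx$t, fx$meta, NULL)
  doc <- xml2::read_xml(svg)
  ns <- xml2::xml_ns(doc)
  polys <- xml2::xml_find_all(doc, ".//d1:polyline", ns)
  xs <- vapply(polys, function(p) {
    pts <- strsplit(xml2::xml_attr(p, "points"), "[ ,]")[[1]]
    min(as.numeric(pts[c(1, 3, 5)]))
  }, numeric(1))
  # the root (height 7) must sit left of the first merge (height 2)
  expect_lt(min(xs), max(xs))

  svg2 <- render_dendrogram(fx$t, fx$meta, NULL, height_cap = 3)
  doc2 <- xml2::read_xml(svg2)
  ticks <- xml2::xml_find_all(doc2, ".//d1:path[@class='capped']",
                              xml2::xml_ns(doc2))
  expect_length(ticks, 1L)
})

test_that("missing metadata only downgrades highlighting, with a warning", {
  fx <- .render_fixture()
  expect_warning(
    svg <- render_dendrogram(fx$t, fx$meta[1:2, ],
                             highlight_rules(".", "id", "#cc0000", "any")),
    "no metadata for 1")
  expect_match(svg, "#333333")
})

test_that("rules read back from TSV equal their in-memory construction", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pattern\tfield\tcolor\tlabel",
               "# comment",
               "^mir-\tid\t#cc0000\tmiRNA",
               "snoRNA\tdescription\t#00cc00\tsnoRNA"), p)
  r <- read_highlight_rules(p)
  expect_equal(nrow(r), 2L)
  expect_identical(r$pattern, c("^mir-", "snoRNA"))
  writeLines("too\tfew", p)
  expect_error(read_highlight_rules(p), "expected 4")
})
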