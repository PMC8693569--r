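mds_fixture <- function(seed = 31) {
  sim <- simulate_counts(n_genes = 300, groups = c("b", "lp", "ml"),
                         samples_per_group = 3, n_de = 60, seed = seed)
  list(expr = sim$expr, mds = run_mds(sim$expr))
}

test_that("MDS widget exposes every retained dimension on both axes", {
  fx <- mds_fixture()
  doc <- build_mds_widget(fx$mds, fx$expr$samples)
  k <- ncol(fx$mds$coordinates)
  expect_equal(k, 8)
  ctl <- setNames(doc$controls, vapply(doc$controls, `[[`, "", "id"))
  expect_length(ctl$x_dim$options, 8)
  expect_length(ctl$y_dim$options, 8)
  pairs <- choose(length(ctl$x_dim$options), 2)
  expect_equal(pairs, 28)
  # variance-explained series embedded alongside, one save control per panel
  expect_equal(length(doc$data$variance$proportion), length(fx$mds$var_explained))
  expect_true(all(c("save_mds_plot", "save_variance_plot") %in% names(ctl)))
  expect_identical(as.character(ctl$save_mds_plot$options), c("png", "svg"))
})

test_that("MDS widget defaults mirror group colour/shape and library-size size", {
  fx <- mds_fixture()
  doc <- build_mds_widget(fx$mds, fx$expr$samples, colour_by = "group",
                          shape_by = "group", size_by = "library_size")
  expect_identical(doc$encodings$main$colour$field, "group")
  expect_identical(doc$encodings$main$shape$field, "group")
  expect_identical(doc$encodings$main$size$field, "library_size")
  expect_true("library_size" %in% names(doc$data$samples))
  expect_equal(as.numeric(doc$data$samples$library_size),
               unname(library_sizes(fx$expr)))
})

test_that("continuous covariates may colour and size but never shape", {
  fx <- mds_fixture()
  st <- fx$expr$samples
  st$rin <- seq(6, 8, length.out = nrow(st))
  doc <- build_mds_widget(fx$mds, st, colour_by = "rin", size_by = "rin")
  ctl <- setNames(doc$controls, vapply(doc$controls, `[[`, "", "id"))
  expect_true("rin" %in% as.character(ctl$colour_by$options))
  expect_true("rin" %in% as.character(ctl$size_by$options))
  expect_false("rin" %in% as.character(ctl$shape_by$options))
  expect_error(build_mds_widget(fx$mds, st, shape_by = "rin"), "discretize")
  # continuous colour default switches the scheme list to ramps
  expect_true(doc$encodings$main$colour$scheme %in% deview:::CONTINUOUS_SCHEMES)
})

test_that("shape categories beyond the glyph guarantee are rejected", {
  fx <- mds_fixture()
  st <- fx$expr$samples
  st$many <- paste0("cat", seq_len(nrow(st)))  # 9 categories
  expect_error(build_mds_widget(fx$mds, st, shape_by = "many"), "glyph")
})

test_that("summary widgets map axes by kind", {
  expr <- toy_expr(8, 4)
  de <- de_result(rownames(expr$counts), logfc = rnorm(8),
                  p_value = c(0.01, runif(7)),
                  ave_expr = rowMeans(log_cpm(expr)))
  ma <- build_summary_widget("ma", de, expr, group_col = "group")
  expect_equal(as.numeric(ma$data$summary$x), de$ave_expr)
  expect_equal(as.numeric(ma$data$summary$y), de$logfc)
  vol <- build_summary_widget("volcano", de, expr, group_col = "group")
  expect_equal(as.numeric(vol$data$summary$x), de$logfc)
  expect_equal(as.numeric(vol$data$summary$y), neglog10_p(de$p_value))
  # p = 0.01 gene sits at y = 2
  expect_equal(as.numeric(vol$data$summary$y)[1], 2)
  xy <- build_summary_widget("xy", de, expr, group_col = "group",
                             x = seq_len(8), y = 8:1,
                             x_label = "score_a", y_label = "score_b")
  expect_equal(as.numeric(xy$data$summary$x), 1:8)
  expect_identical(xy$encodings$summary$x$label, "score_a")
})

test_that("xy vectors must have one value per gene", {
  expr <- toy_expr(8, 4)
  de <- toy_de(expr)
  expect_error(
    build_summary_widget("xy", de, expr, group_col = "group",
                         x = 1:7, y = 1:8),
    "length\\(x\\) = 7.*n_genes = 8")
  expect_error(build_summary_widget("xy", de, expr, group_col = "group"),
               "requires both x and y")
})

test_that("unknown grouping column errors list the available columns", {
  expr <- toy_expr(4, 4)
  de <- toy_de(expr)
  expect_error(build_summary_widget("ma", de, expr, group_col = "treatment"),
               "sample_id, group")
})

test_that("summary tables carry full cardinality and status legend", {
  sim <- simulate_counts(n_genes = 1000, n_de = 100, seed = 5)
  de <- fixture_de_test(sim$expr)
  doc <- build_summary_widget("ma", de, sim$expr, group_col = "group")
  expect_length(doc$data$table$gene_id, 1000)
  expect_length(doc$data$expression$value, 1000 * n_samples(sim$expr))
  expect_true(all(as.numeric(doc$data$summary$status) %in% c(-1, 0, 1)))
  expect_equal(as.numeric(doc$encodings$summary$colour$domain), c(-1, 0, 1))
  # expression x labels carry the 45-degree anticlockwise rotation
  expect_equal(doc$encodings$expression$x$label_rotation, -45)
})

test_that("ma and volcano embed identical expression payloads", {
  expr <- toy_expr(10, 4)
  de <- toy_de(expr)
  ma <- build_summary_widget("ma", de, expr, group_col = "group")
  vol <- build_summary_widget("volcano", de, expr, group_col = "group")
  expect_identical(
    jsonlite::toJSON(ma$data$expression, digits = NA),
    jsonlite::toJSON(vol$data$expression, digits = NA))
})

test_that("max_y_axis fixes the expression y-domain upper bound literally", {
  expr <- toy_expr(5, 4)
  de <- toy_de(expr)
  doc <- build_summary_widget("ma", de, expr, group_col = "group",
                              max_y_axis = 10)
  expect_equal(doc$encodings$expression$y$domain$max, 10)
  expect_lte(doc$encodings$expression$y$domain$min, 0)
  auto <- build_summary_widget("ma", de, expr, group_col = "group")
  expect_identical(auto$encodings$expression$y$domain, "auto")
})

test_that("explicit status and sample colours flow into the document", {
  expr <- toy_expr(5, 4)
  de <- toy_de(expr)
  forced <- c(1, 1, -1, 0, 0)
  doc <- build_summary_widget("ma", de, expr, group_col = "group",
                              status = forced,
                              sample_colours = c("#111111", "#222222",
                                                 "#333333", "#444444"))
  expect_equal(as.numeric(doc$data$summary$status), forced)
  expect_true(doc$encodings$expression$colour$literal)
  expect_identical(unique(doc$data$expression$colour[1:4]),
                   c("#111111", "#222222", "#333333", "#444444"))
  expect_error(
    build_summary_widget("ma", de, expr, group_col = "group",
                         sample_colours = "#111111"),
    "one per sample")
})

test_that("widget documents validate and reject broken encodings or controls", {
  expr <- toy_expr(4, 4)
  de <- toy_de(expr)
  doc <- build_summary_widget("ma", de, expr, group_col = "group")
  expect_silent(validate_widget(doc))
  broken <- doc
  broken$encodings$summary$x$field <- "nope"
  expect_error(validate_widget(broken), "absent from table")
  broken2 <- doc
  broken2$controls[[1]]$options <- I(character(0))
  expect_error(validate_widget(broken2), "empty option list")
  broken3 <- doc
  broken3$kind <- "pie"
  expect_error(validate_widget(broken3), "unknown widget kind")
})

test_that("serialize-parse-serialize is byte-identical on random documents", {
  for (seed in 1:25) {
    doc <- random_widget_doc(seed)
    json <- serialize_widget(doc)
    back <- parse_widget(json)
    expect_identical(serialize_widget(back), json, label = paste("seed", seed))
  }
  fx <- mds_fixture()
  doc <- build_mds_widget(fx$mds, fx$expr$samples)
  json <- serialize_widget(doc)
  expect_identical(serialize_widget(parse_widget(json)), json)
})
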