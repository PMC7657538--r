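ztable_from_wide <- function(df) {
  long <- rbind(
    data.frame(source = df$source, target = df$target,
               metric = "complementarity", value = NA_real_, bin = 0L,
               z = df$z_complementarity, flag = "none"),
    data.frame(source = df$source, target = df$target,
               metric = "competition", value = NA_real_, bin = 0L,
               z = df$z_competition, flag = "none"))
  class(long) <- c("ztable", "data.frame")
  long
}

test_that("edges require high complementarity AND low competition, strictly", {
  wide <- data.frame(source = c("a", "a", "b", "b"),
                     target = c("b", "c", "a", "c"),
                     z_complementarity = c(3.0, 3.0, 2.698, 5.0),
                     z_competition = c(-1.5, -0.5, -2.0, -1.0))
  g <- build_graph(ztable_from_wide(wide))
  # a->b passes; a->c fails competition; b->a fails strict complementarity;
  # b->c fails strict competition
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$from, "a")
  expect_equal(g$edges$to, "b")
  expect_setequal(g$nodes, c("a", "b"))
})

test_that("edge set equals a brute-force row filter on synthetic tables", {
  withr::local_seed(33)
  ids <- sprintf("s%02d", 1:8)
  pairs <- expand.grid(source = ids, target = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ][1:50, ]
  pairs$z_complementarity <- rnorm(50, sd = 2)
  pairs$z_competition <- rnorm(50, sd = 2)
  g <- build_graph(ztable_from_wide(pairs))
  manual <- pairs[pairs$z_complementarity > 2.698 &
                    pairs$z_competition < -1.0, ]
  expect_equal(nrow(g$edges), nrow(manual))
  expect_setequal(paste(g$edges$from, g$edges$to),
                  paste(manual$source, manual$target))
})

test_that("a pair missing one metric is a validation error", {
  long <- ztable_from_wide(data.frame(source = "a", target = "b",
                                      z_complementarity = 3,
                                      z_competition = -2))
  expect_error(build_graph(long[long$metric == "complementarity", ]),
               "a->b")
})

test_that("infomap export writes zero-based links and a faithful mapping", {
  g <- structure(list(nodes = c("spA", "spB"),
                      edges = data.frame(from = "spA", to = "spB",
                                         z_complementarity = 3,
                                         z_competition = -2)),
                 class = "interaction_graph")
  links <- withr::local_tempfile()
  paths <- export_infomap(g, links)
  expect_equal(readLines(links), "0 1")
  map <- read.table(paths["mapping"], sep = "\t", header = TRUE)
  expect_equal(map$model_id, c("spA", "spB"))

  empty <- structure(list(nodes = character(0),
                          edges = data.frame()),
                     class = "interaction_graph")
  expect_error(export_infomap(empty, links), "empty")
})

test_that("export/parse round trip preserves node identity and edges", {
  withr::local_seed(43)
  ids <- sprintf("sp%02d", 1:6)
  edges <- unique(data.frame(from = sample(ids, 10, replace = TRUE),
                             to = sample(ids, 10, replace = TRUE)))
  edges <- edges[edges$from != edges$to, ]
  g <- structure(list(nodes = sort(unique(c(edges$from, edges$to))),
                      edges = edges), class = "interaction_graph")
  links <- withr::local_tempfile()
  paths <- export_infomap(g, links)
  expect_equal(length(readLines(links)), nrow(edges))
  lk <- read.table(links)
  expect_lte(max(lk), length(g$nodes) - 1L)
  map <- read.table(paths["mapping"], sep = "\t", header = TRUE)
  back <- data.frame(from = map$model_id[lk$V1 + 1L],
                     to = map$model_id[lk$V2 + 1L])
  expect_setequal(paste(back$from, back$to), paste(edges$from, edges$to))
})

test_that("infomap module output parses into model-id module paths", {
  map_path <- withr::local_tempfile()
  write.table(data.frame(node_id = 0:5,
                         model_id = sprintf("sp%02d", 1:6)),
              map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  tree_path <- withr::local_tempfile()
  writeLines(c("# Infomap output",
               sprintf('1:%d 0.1 "%d" %d', 1:3, 0:2, 0:2),
               sprintf('2:%d 0.1 "%d" %d', 1:3, 3:5, 3:5)),
             tree_path)
  mods <- parse_infomap_modules(tree_path, map_path)
  expect_length(mods, 6L)
  expect_equal(unname(mods["sp01"]), "1:1")
  top <- sub(":.*$", "", mods)
  expect_equal(sort(as.integer(table(top))), c(3L, 3L))

  empty_tree <- withr::local_tempfile()
  writeLines("# nothing", empty_tree)
  expect_length(parse_infomap_modules(empty_tree, map_path), 0L)

  bad_tree <- withr::local_tempfile()
  writeLines('1:1 0.5 "9" 9', bad_tree)
  expect_error(parse_infomap_modules(bad_tree, map_path), "9")
})

test_that("within-genus proportions match a brute-force group-by", {
  tax <- c(sp1 = "Alpha", sp2 = "Alpha", sp3 = "Alpha", sp4 = "Beta",
           sp5 = "Gamma", sp6 = "Gamma")
  pairs <- expand.grid(source = names(tax), target = names(tax),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  withr::local_seed(53)
  pairs$significant <- runif(nrow(pairs)) < 0.3
  got <- within_genus_proportions(pairs, tax)
  # Beta has one member: excluded
  expect_setequal(got$genus, c("Alpha", "Gamma"))
  expect_equal(got$n_pairs[got$genus == "Alpha"], 6L)
  same <- pairs[tax[pairs$source] == tax[pairs$target], ]
  for (g in got$genus) {
    manual <- sum(same$significant[tax[same$source] == g])
    expect_equal(got$n_significant[got$genus == g], manual)
    expect_equal(got$proportion[got$genus == g],
                 manual / got$n_pairs[got$genus == g])
  }
  expect_error(within_genus_proportions(pairs, tax[-1]), "sp1")
})

test_that("a 3-member genus with one significant pair scores 1/6", {
  tax <- c(a = "G", b = "G", c = "G")
  pairs <- expand.grid(source = names(tax), target = names(tax),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs$significant <- pairs$source == "a" & pairs$target == "b"
  got <- within_genus_proportions(pairs, tax)
  expect_equal(got$n_pairs, 6L)
  expect_equal(got$n_significant, 1L)
  expect_equal(got$proportion, 1 / 6)
})
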