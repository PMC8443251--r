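# constructed regulator/target expression: each target copies one regulator
copyLinkExpr <- function(n_cells, n_reg = 10, seed = 1) {
  set.seed(seed)
  regs <- matrix(rnorm(n_cells * n_reg), n_cells, n_reg,
                 dimnames = list(NULL, sprintf("R%02d", seq_len(n_reg))))
  targets <- regs + matrix(rnorm(n_cells * n_reg, sd = 0.1), n_cells, n_reg)
  colnames(targets) <- sprintf("T%02d", seq_len(n_reg))
  t(cbind(regs, targets))
}

test_that("a copied regulator ranks first for its target", {
  expr <- copyLinkExpr(150, n_reg = 10, seed = 50)
  links <- inferLinks(expr, regulators = sprintf("R%02d", 1:10),
                      targets = sprintf("T%02d", 1:10),
                      n_trees = 300, seed = 1)
  expect_true(all(links$importance >= 0))
  expect_true(all(is.finite(links$importance)))
  expect_false(any(links$regulator == links$target))
  first_per_target <- vapply(sprintf("T%02d", 1:10), function(tg) {
    sub <- links[links$target == tg, ]
    sub$regulator[1]
  }, character(1))
  n_correct <- sum(first_per_target == sub("T", "R", names(first_per_target)))
  expect_gte(n_correct, 9L)
})

test_that("independent targets score below copied links", {
  expr <- copyLinkExpr(150, n_reg = 6, seed = 51)
  set.seed(52)
  expr <- rbind(expr, Tnull = rnorm(150))
  links <- inferLinks(expr, regulators = sprintf("R%02d", 1:6),
                      targets = c("T01", "Tnull"), n_trees = 300, seed = 3)
  copy_imp <- links$importance[links$target == "T01" &
                                 links$regulator == "R01"]
  null_max <- max(links$importance[links$target == "Tnull"])
  expect_gt(copy_imp, null_max)
})

test_that("inference is seed-reproducible and skips constant targets", {
  expr <- copyLinkExpr(80, n_reg = 4, seed = 53)
  l1 <- inferLinks(expr, n_trees = 100, seed = 7)
  l2 <- inferLinks(expr, n_trees = 100, seed = 7)
  expect_identical(l1, l2)
  expr2 <- rbind(expr, Tconst = rep(1, 80))
  expect_warning(inferLinks(expr2, targets = "Tconst", n_trees = 50, seed = 1),
                 "zero variance")
})

test_that("marker networks keep the strongest marker-adjacent links", {
  set.seed(54)
  genes <- sprintf("g%03d", 1:40)
  links <- expand.grid(regulator = genes[1:20], target = genes[21:40],
                       stringsAsFactors = FALSE)
  links$importance <- runif(nrow(links))
  links <- links[order(-links$importance), ]
  markers <- genes[c(1:10, 21:30)]
  net <- buildMarkerNetwork(links, markers, top_links = 200)
  qualifying <- links[links$regulator %in% markers |
                        links$target %in% markers, ]
  expect_gt(nrow(qualifying), 200)
  expect_equal(nrow(net$edges), 200L)
  ## sort/filter oracle: the largest qualifying importances win
  expect_equal(net$edges$importance,
               sort(qualifying$importance, decreasing = TRUE)[1:200])
  expect_true(all(net$edges$regulator %in% markers |
                    net$edges$target %in% markers))
  ## ties at the boundary resolve lexicographically by (regulator, target)
  tied <- data.frame(regulator = c("a", "b", "c"), target = c("m", "m", "m"),
                     importance = 1)
  nt <- buildMarkerNetwork(tied, "m", top_links = 2)
  expect_equal(nt$edges$regulator, c("a", "b"))
  expect_warning(buildMarkerNetwork(links[0, ], markers, 10), "empty")
  expect_warning(buildMarkerNetwork(tied, "m", 10), "qualifying")
})

test_that("gene-centric expansion builds the two-ring neighborhood", {
  ## star around "hub" plus second-ring stars, hand-built oracle
  links <- data.frame(
    regulator = c("hub", "hub", "hub", "s1", "s2", "far1"),
    target    = c("s1", "s2", "s3", "s1b", "s2b", "far2"),
    importance = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
  net <- geneCentricNetwork(links, "hub", top_k = 20) |>
    suppressWarnings()
  expect_setequal(net$nodes, c("hub", "s1", "s2", "s3", "s1b", "s2b"))
  expect_equal(nrow(net$edges), 5L)   # far1->far2 excluded
  ## top_k = 0 leaves the gene alone
  solo <- geneCentricNetwork(links, "hub", top_k = 0)
  expect_identical(solo$nodes, "hub")
  ## fewer partners than requested warns
  expect_warning(geneCentricNetwork(links, "s3", top_k = 20), "partners")
  expect_error(geneCentricNetwork(links, "absent"), "absent")
})

test_that("clustering coefficient matches closed forms and hand enumeration", {
  tri <- igraph::make_ring(3)
  expect_equal(networkMetrics(tri)$clustering_coefficient, 1.0)
  star <- igraph::make_star(5, mode = "undirected")
  expect_equal(networkMetrics(star)$clustering_coefficient, 0.0)
  k4 <- igraph::make_full_graph(4)
  expect_equal(networkMetrics(k4)$clustering_coefficient, 1.0)
  ## 4-cycle A-B-C-D with chord A-C: local = (2/3, 1, 2/3, 1), mean 5/6
  chord <- igraph::graph_from_edgelist(
    rbind(c("A", "B"), c("B", "C"), c("C", "D"), c("D", "A"), c("A", "C")),
    directed = FALSE)
  expect_equal(networkMetrics(chord)$clustering_coefficient, 5 / 6,
               tolerance = 1e-12)
  comp <- networkMetrics(igraph::make_ring(3) +
                           igraph::make_full_graph(5))
  expect_equal(comp$component_sizes, c(5L, 3L))
  empty <- suppressWarnings(networkMetrics(igraph::make_empty_graph(0)))
  expect_equal(empty$clustering_coefficient, 0)
  ## direction and duplicate edges are ignored for metrics
  dir_g <- igraph::graph_from_edgelist(
    rbind(c("x", "y"), c("y", "x"), c("y", "z"), c("z", "x")), directed = TRUE)
  expect_equal(networkMetrics(dir_g)$clustering_coefficient, 1.0)
})

test_that("networks export to edge-list TSV and GraphML", {
  links <- data.frame(regulator = c("a", "a", "b"), target = c("b", "c", "c"),
                      importance = c(0.3, 0.2, 0.1))
  net <- buildMarkerNetwork(links, c("a", "b"), top_links = 3)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  exportNetwork(net, f1, "tsv")
  back <- read.delim(f1)
  expect_equal(nrow(back), 3L)
  expect_equal(sort(names(back)), c("importance", "regulator", "target"))
  f2 <- withr::local_tempfile(fileext = ".graphml")
  exportNetwork(net, f2, "graphml")
  g2 <- igraph::read_graph(f2, format = "graphml")
  expect_equal(igraph::ecount(g2), 3)
})

test_that("completing a triangle never lowers the common neighbour's coefficient", {
  g0 <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("a", "c")),
                                    directed = FALSE)
  l0 <- igraph::transitivity(g0, type = "local", isolates = "zero")
  g1 <- igraph::add_edges(g0, c("b", "c"))
  l1 <- igraph::transitivity(g1, type = "local", isolates = "zero")
  expect_gte(l1[1], l0[1])
})
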