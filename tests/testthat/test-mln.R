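taxa4 <- c("A", "B", "C", "D")

test_that("lateral edges come from sibling origin pairs and add up", {
  tr <- t4()
  net1 <- build_mln(tr, infer_scenarios(tr, make_pap(list(c1 = "1010"), taxa4), "BOR1"))
  expect_equal(nrow(net1$edges), 1L)
  expect_setequal(tr$labels[c(net1$edges$node_a, net1$edges$node_b)], c("A", "C"))
  expect_equal(net1$edges$weight, 1L)

  net2 <- build_mln(tr, infer_scenarios(
    tr, make_pap(list(c1 = "1010", c2 = "1010"), taxa4), "BOR1"
  ))
  expect_equal(net2$edges$weight, 2L)
  expect_setequal(net2$edges$characters[[1]], c("c1", "c2"))

  net0 <- build_mln(tr, infer_scenarios(tr, make_pap(list(c1 = "1100"), taxa4), "BOR1"))
  expect_equal(nrow(net0$edges), 0L)
  expect_true(all(net0$lateral == 0L))
})

test_that("summed lateral weight equals total inferred borrowings", {
  set.seed(47)
  tr <- random_reference_tree(12, seed = 47)
  sim <- simulate_pap(tr, 80, q = 0.1, lambda = 1, seed = 48)
  for (m in c("BOR1", "BOR3", "BOR15")) {
    sc <- infer_scenarios(tr, sim$pap, m)
    net <- build_mln(tr, sc)
    expect_equal(sum(net$edges$weight), sum(sc$n_borrowings))
    expect_true(all(net$lateral == t(net$lateral)))
    expect_true(all(diag(net$lateral) == 0L))
  }
})

test_that("connectivity counts distinct lateral neighbours only", {
  tr <- t4()
  net <- build_mln(tr, infer_scenarios(tr, make_pap(list(c1 = "1010"), taxa4), "BOR1"))
  ds <- degree_stats(net)
  conn <- setNames(ds$connectivity$connectivity, ds$connectivity$label)
  expect_equal(unname(conn["A"]), 1L)
  expect_equal(unname(conn["C"]), 1L)
  expect_equal(sum(conn), 2L)
  expect_equal(ds$median, 0)
  expect_equal(ds$max, 1L)

  empty <- build_mln(tr, infer_scenarios(tr, make_pap(list(c1 = "1111"), taxa4), "LO"))
  expect_true(all(degree_stats(empty)$connectivity$connectivity == 0L))
})

test_that("graph statistics are computed on the unweighted union graph", {
  tr <- t4()
  empty <- build_mln(tr, infer_scenarios(tr, make_pap(list(c1 = "1111"), taxa4), "LO"))
  gs <- graph_stats(empty)
  expect_equal(gs$clustering_coefficient, 0) # trees are triangle-free

  # lateral edge A-B closes a triangle with the cherry parent
  net <- build_mln(tr, infer_scenarios(tr, make_pap(list(c1 = "1010"), taxa4), "BOR1"))
  # A-C joins two leaves across the root: still triangle-free
  expect_equal(graph_stats(net)$clustering_coefficient, 0)

  # enumerate by hand: triangle graph
  tri <- igraph::make_full_graph(3)
  expect_equal(igraph::transitivity(tri, type = "localaverage"), 1)

  # direct enumeration of mean shortest path on the bare 7-node tree
  g <- igraph::graph_from_edgelist(
    cbind(tr$parent[tr$parent != 0], which(tr$parent != 0)), directed = FALSE
  )
  d <- igraph::distances(g)
  expect_equal(gs$mean_shortest_path, mean(d[upper.tri(d)]))
})

test_that("a sibling lateral edge between cherry leaves creates a triangle", {
  # force sibling origins by hand: A and B under their parent
  tr <- t4()
  sc <- infer_scenarios(tr, make_pap(list(c1 = "1010"), taxa4), "BOR1")
  sc$origins[[1]] <- c(node_by_label(tr, "A"), node_by_label(tr, "B"))
  sc$sibling_pairs[[1]] <- matrix(c(node_by_label(tr, "A"), node_by_label(tr, "B")), 1)
  net <- build_mln(tr, sc)
  gs <- graph_stats(net)
  expect_gt(gs$clustering_coefficient, 0)
  # brute-force check: triangle A-B-parent among 7 nodes, degree-weighted mean
  g <- mlnet:::mln_igraph(net)
  local <- igraph::transitivity(g, type = "local")
  local[is.na(local)] <- 0
  expect_equal(gs$clustering_coefficient, mean(local))
})

test_that("edge weight histogram conserves the distinct edge count", {
  tr <- t8()
  pap <- make_pap(list(
    c1 = "10101111", c2 = "10101111", c3 = "10101111", c4 = "10111111"
  ), taxa(tr))
  net <- build_mln(tr, infer_scenarios(tr, pap, "BOR1"))
  h <- edge_weight_histogram(net)
  expect_equal(sum(h$n_edges), nrow(net$edges))
  empty <- build_mln(tr, infer_scenarios(tr, make_pap(list(x = "11111111"), taxa(tr)), "SO"))
  expect_equal(nrow(edge_weight_histogram(empty)), 0L)
})

test_that("edges classify by endpoint kind and counts sum to the total", {
  set.seed(53)
  tr <- random_reference_tree(16, seed = 53)
  sim <- simulate_pap(tr, 100, q = 0.1, lambda = 1.5, seed = 54)
  net <- build_mln(tr, infer_scenarios(tr, sim$pap, "BOR3"))
  cl <- classify_edges(net)
  expect_equal(
    cl$external_external + cl$external_internal + cl$internal_internal,
    cl$total
  )
  expect_equal(cl$total, nrow(net$edges))

  tr4 <- t4()
  n1 <- build_mln(tr4, infer_scenarios(tr4, make_pap(list(c1 = "1010"), taxa4), "BOR1"))
  expect_equal(classify_edges(n1)$external_external, 1L)
})

test_that("recent borrowing fractions are percentages of leaf inventories", {
  tr <- t4()
  pap <- make_pap(list(c1 = "1010", c2 = "1100", c3 = "1111"), taxa4)
  net <- build_mln(tr, infer_scenarios(tr, pap, "BOR1"))
  rb <- recent_borrowing_fraction(net)
  expect_true(all(rb$pct >= 0 & rb$pct <= 100, na.rm = TRUE))
  # A carries c1 (lateral) out of inventory {c1, c2, c3}
  a <- rb[rb$taxon == "A", ]
  expect_equal(a$n_lateral_characters, 1L)
  expect_equal(a$pct, 100 * 1 / 3)
  expect_equal(rb[rb$taxon == "B", ]$pct, 0)
})

test_that("leaves that directly received more borrowings get larger fractions", {
  set.seed(59)
  cors <- vapply(1:20, function(s) {
    tr <- random_reference_tree(16, seed = s)
    sim <- simulate_pap(tr, 150, q = 0.05, lambda = 1, seed = s + 500)
    net <- build_mln(tr, infer_scenarios(tr, sim$pap, "BOR3"))
    rb <- recent_borrowing_fraction(net)
    # recent borrowings: events whose recipient is the leaf itself
    hits <- tabulate(
      Filter(function(b) b <= tr$n_leaf, unlist(sim$truth$borrowings)),
      nbins = tr$n_leaf
    )
    suppressWarnings(stats::cor(rb$pct, hits, method = "spearman"))
  }, numeric(1))
  expect_gt(mean(cors, na.rm = TRUE), 0)
})

test_that("group edge analysis separates within- from between-group borrowing", {
  tr <- t4()
  groups <- tibble::tibble(taxon = taxa4, group = c("g1", "g1", "g2", "g2"))

  # lateral edge inside the AB cherry only
  sc <- infer_scenarios(tr, make_pap(list(c1 = "1010"), taxa4), "BOR1")
  sc$sibling_pairs[[1]] <- matrix(c(node_by_label(tr, "A"), node_by_label(tr, "B")), 1)
  net <- build_mln(tr, sc)
  ga <- group_edge_analysis(net, groups)
  g1 <- ga[ga$group == "g1", ]
  expect_equal(g1$freq_external, 0)
  expect_gt(g1$freq_internal, 0)

  # direct KS computation on given weight samples
  ks <- ks_one_sided(c(2, 2, 3), c(1, 1))
  expect_gt(ks$statistic, 0.9)

  # no lateral edges: zero frequencies, KS missing
  empty <- build_mln(tr, infer_scenarios(tr, make_pap(list(c1 = "1111"), taxa4), "LO"))
  ga0 <- group_edge_analysis(empty, groups)
  expect_true(all(ga0$freq_internal == 0))
  expect_true(all(is.na(ga0$ks_p)))

  expect_error(
    group_edge_analysis(net, tibble::tibble(taxon = "A", group = "g1")),
    "every leaf"
  )
})

test_that("simulated between-clade borrowing concentrates external edge weight", {
  set.seed(61)
  tr <- t8()
  groups <- tibble::tibble(taxon = taxa(tr),
                           group = rep(c("left", "right"), each = 4))
  # characters born in the left clade and copied into the right clade
  left <- mrca(tr, c("A", "B", "C", "D"))
  right <- mrca(tr, c("E", "F", "G", "H"))
  pap <- make_pap(list(c1 = "11101110", c2 = "11011101", c3 = "10111011"), taxa(tr))
  net <- build_mln(tr, infer_scenarios(tr, pap, "BOR1"))
  ga <- group_edge_analysis(net, groups)
  expect_true(all(ga$freq_internal == 0))
  expect_true(all(ga$freq_external > 0))
})

test_that("known borrowings classify as external, internal or not detected", {
  tr <- t4()
  pap <- make_pap(list(c1 = "1010", c2 = "1100", c3 = "1110"), taxa4)
  sc <- infer_scenarios(tr, pap, "BOR1")

  val <- validate_known_borrowings(sc, tibble::tibble(character = "c1", taxon = "C"))
  expect_equal(val$class, "external")

  # c3 under BOR1: origins are the AB cherry and leaf C... the C origin is a leaf,
  # so D reinserted into c3's sibling CD clade tests the internal case instead:
  sc$origins[[3]] <- c(mrca(tr, c("A", "B")), mrca(tr, c("C", "D")))
  val2 <- validate_known_borrowings(sc, tibble::tibble(character = "c3", taxon = "D"))
  expect_equal(val2$class, "internal")

  val3 <- validate_known_borrowings(sc, tibble::tibble(character = "c2", taxon = "C"))
  expect_equal(val3$class, "not_detected")

  expect_error(
    validate_known_borrowings(sc, tibble::tibble(character = "nope", taxon = "A")),
    "unknown character"
  )
  smry <- attr(
    validate_known_borrowings(sc, tibble::tibble(
      character = c("c1", "c2"), taxon = c("C", "C")
    )), "summary"
  )
  expect_equal(smry$detection_pct, 50)
})
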