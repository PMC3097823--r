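test_that("loss-only inference places losses at maximal absent clades", {
  tr <- t4()
  expect_length(infer_lo(tr, row4("1111"))$losses, 0)
  sc <- infer_lo(tr, row4("1100"))
  expect_equal(sc$origins, tr$root)
  expect_equal(sc$losses, mrca(tr, c("C", "D")))
  sc2 <- infer_lo(tr, row4("1010"))
  expect_setequal(tr$labels[sc2$losses], c("B", "D"))
})

test_that("single-origin inference starts at the MRCA of presences", {
  tr <- t4()
  sc <- infer_so(tr, row4("1100"))
  expect_equal(sc$origins, mrca(tr, c("A", "B")))
  expect_length(sc$losses, 0)
  sc2 <- infer_so(tr, row4("1000"))
  expect_equal(sc2$origins, node_by_label(tr, "A"))
  expect_length(sc2$losses, 0)
  sc3 <- infer_so(tr, row4("1110"))
  expect_equal(sc3$origins, tr$root)
  expect_equal(tr$labels[sc3$losses], "D")
})

test_that("BOR models collapse to single origin when the clade is complete", {
  tr <- t4()
  sc <- infer_bork(tr, row4("1100"), "BOR1")
  expect_equal(sc$origins, mrca(tr, c("A", "B")))
  expect_equal(nrow(sc$sibling_pairs), 0)
})

test_that("BOR1 splits a patchy pattern into per-clade MRCAs", {
  tr <- t4()
  sc <- infer_bork(tr, row4("1010"), "BOR1")
  expect_setequal(tr$labels[sc$origins], c("A", "C"))
  expect_length(sc$losses, 0)
  expect_equal(nrow(sc$sibling_pairs), 1)
  expect_setequal(tr$labels[sc$sibling_pairs[1, ]], c("A", "C"))
})

test_that("BOR3 resolves the fully alternating 8-leaf pattern with 4 origins", {
  tr <- t8()
  sc <- infer_bork(tr, row8("10101010"), "BOR3")
  expect_setequal(tr$labels[sc$origins], c("A", "C", "E", "G"))
  expect_length(sc$losses, 0)
  expect_equal(nrow(sc$sibling_pairs), 3)
  pres <- replay_scenario(tr, sc$origins, sc$losses)
  expect_equal(as.integer(pres[1:8]), unname(row8("10101010")[taxa(tr)]))
})

test_that("the origin budget is respected and splits are atomic", {
  tr <- t8()
  sc <- infer_bork(tr, row8("10101010"), "BOR1")
  expect_equal(length(sc$origins), 2L)
  pres <- replay_scenario(tr, sc$origins, sc$losses)
  expect_equal(as.integer(pres[1:8]), unname(row8("10101010")[taxa(tr)]))
  for (m in c("BOR1", "BOR3", "BOR7", "BOR15")) {
    s <- infer_bork(tr, row8("10101010"), m)
    expect_lte(length(s$origins), model_spec(m)$max_origins)
  }
})

test_that("origin subtrees are pairwise disjoint and cover all presences", {
  set.seed(13)
  for (tr in tree_pool(6, 6:8, seed = 13)) {
    row <- random_row(tr)
    for (m in c("BOR1", "BOR3", "BOR7")) {
      sc <- infer_bork(tr, row, m)
      leafsets <- lapply(sc$origins, function(o) tr$leaf_desc[[o]])
      all_leaves <- unlist(leafsets)
      expect_equal(anyDuplicated(all_leaves), 0)
      expect_true(all(which(row[taxa(tr)] == 1L) %in% all_leaves))
    }
  }
})

test_that("every scenario replays to its PAP row bit for bit", {
  set.seed(17)
  pool <- tree_pool(8, 5:9, seed = 17)
  models <- c("LO", "SO", "BOR1", "BOR3", "BOR7", "BOR15")
  for (i in 1:200) {
    tr <- pool[[sample(length(pool), 1)]]
    row <- random_row(tr)
    m <- sample(models, 1)
    sc <- switch(m,
      LO = infer_lo(tr, row),
      SO = infer_so(tr, row),
      infer_bork(tr, row, m)
    )
    pres <- replay_scenario(tr, sc$origins, sc$losses)
    expect_identical(pres[seq_len(tr$n_leaf)], as.logical(row[taxa(tr)]))
  }
})

test_that("losses shrink and origins grow monotonically with the allowance", {
  set.seed(19)
  for (tr in tree_pool(5, 6:9, seed = 19)) {
    for (rep in 1:10) {
      row <- random_row(tr)
      scens <- list(
        infer_lo(tr, row), infer_so(tr, row),
        infer_bork(tr, row, "BOR1"), infer_bork(tr, row, "BOR3"),
        infer_bork(tr, row, "BOR7"), infer_bork(tr, row, "BOR15")
      )
      losses <- vapply(scens, function(s) length(s$losses), numeric(1))
      origins <- vapply(scens, function(s) length(s$origins), numeric(1))
      expect_true(all(diff(losses) <= 0))
      expect_true(all(diff(origins) >= 0))
      # with enough allowance the pattern is explained without any loss
      expect_equal(losses[6], 0)
    }
  }
})

test_that("ancestral inventories replay presence correctly", {
  tr <- t4()
  taxa4 <- c("A", "B", "C", "D")

  # all-present characters under LO: every node carries all of them
  pap <- make_pap(list(c1 = "1111", c2 = "1111", c3 = "1111"), taxa4)
  inv <- ancestral_inventory(tr, infer_scenarios(tr, pap, "LO"))
  expect_true(all(inv$size == 3L))

  # single 1010 row under BOR1: only the two origin leaves carry it
  pap2 <- make_pap(list(c1 = "1010"), taxa4)
  inv2 <- ancestral_inventory(tr, infer_scenarios(tr, pap2, "BOR1"))
  expect_equal(unname(inv2$size[node_by_label(tr, "A")]), 1L)
  expect_equal(unname(inv2$size[node_by_label(tr, "C")]), 1L)
  expect_true(all(inv2$ancestral == 0L))

  # 1100 under SO: present at the cherry and its two leaves, not the root
  pap3 <- make_pap(list(c1 = "1100"), taxa4)
  inv3 <- ancestral_inventory(tr, infer_scenarios(tr, pap3, "SO"))
  x <- mrca(tr, c("A", "B"))
  expect_equal(unname(inv3$size[x]), 1L)
  expect_equal(unname(inv3$size[node_by_label(tr, "A")]), 1L)
  expect_equal(unname(inv3$size[tr$root]), 0L)

  # leaf inventories always equal PAP column sums
  set.seed(23)
  tr8 <- t8()
  pap8 <- do.call(rbind, lapply(1:20, function(i) random_row(tr8)))
  rownames(pap8) <- paste0("c", 1:20)
  for (m in c("LO", "SO", "BOR3")) {
    inv8 <- ancestral_inventory(tr8, infer_scenarios(tr8, pap8, m))
    expect_equal(unname(inv8$contemporary), unname(colSums(pap8[, taxa(tr8)])))
  }
})

test_that("origin-count inventories count origins placed at each node", {
  tr <- t4()
  pap <- make_pap(list(c1 = "1010", c2 = "1100"), c("A", "B", "C", "D"))
  sc <- infer_scenarios(tr, pap, "BOR1")
  inv <- ancestral_inventory(tr, sc, mode = "origin_count")
  expect_equal(sum(inv$size), 3L) # two origins for c1, one for c2
  expect_equal(unname(inv$size[mrca(tr, c("A", "B"))]), 1L)
})

test_that("event counts summarize losses, borrowings and origin histogram", {
  tr <- t4()
  pap <- make_pap(list(c1 = "1111", c2 = "1010"), c("A", "B", "C", "D"))
  ev <- event_counts(infer_scenarios(tr, pap, "BOR1"))
  expect_equal(ev$mean_borrowings, 0.5)
  expect_equal(ev$origin_histogram$n_characters, c(1L, 1L))
  ev_lo <- event_counts(infer_scenarios(tr, pap, "LO"))
  expect_equal(ev_lo$mean_borrowings, 0)
  expect_equal(ev_lo$origin_histogram$n_origins, 1L)
})

test_that("under LO the root inventory equals the number of characters", {
  set.seed(29)
  tr <- t8()
  pap <- do.call(rbind, lapply(1:15, function(i) random_row(tr)))
  rownames(pap) <- paste0("c", 1:15)
  inv <- ancestral_inventory(tr, infer_scenarios(tr, pap, "LO"))
  expect_equal(unname(inv$size[tr$root]), 15L)
})

test_that("model selection accepts the first model with p above alpha", {
  tr <- random_reference_tree(16, seed = 31)
  sim <- simulate_pap(tr, 120, q = 0.05, lambda = 0, seed = 32)
  sel <- select_model(tr, sim$pap)
  expect_s3_class(sel, "mln_model_selection")
  expect_equal(nrow(sel$table), 6L)
  expect_true(all(sel$table$p_value >= 0 & sel$table$p_value <= 1))
  first_ok <- which(sel$table$p_value > sel$alpha)[1]
  expect_equal(sel$accepted_model, sel$table$model[first_ok])
  expect_identical(attr(sel$scenarios, "model"), sel$accepted_model)
})

test_that("model selection errors on degenerate trees", {
  tiny <- read_newick(textConnection("(A,B);"))
  pap <- make_pap(list(c1 = "11"), c("A", "B"))
  expect_error(select_model(tiny, pap), "internal nodes")
})
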