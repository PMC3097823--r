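# Shared fixtures and independent oracles for the test suite.

t4 <- function() read_newick(textConnection("((A,B),(C,D));"))
t8 <- function() read_newick(textConnection("(((A,B),(C,D)),((E,F),(G,H)));"))

# named binary row over given taxa, e.g. row4("1010")
named_row <- function(bits, taxa) {
  stats::setNames(as.integer(strsplit(bits, "")[[1]]), taxa)
}
row4 <- function(bits) named_row(bits, c("A", "B", "C", "D"))
row8 <- function(bits) named_row(bits, c("A", "B", "C", "D", "E", "F", "G", "H"))

# PAP matrix from a named list of bit strings
make_pap <- function(rows, taxa) {
  m <- do.call(rbind, lapply(rows, function(b) named_row(b, taxa)))
  rownames(m) <- names(rows)
  m
}

# node index by label
node_by_label <- function(tree, label) match(label, tree$labels)

# random non-zero presence row over the tree's leaves
random_row <- function(tree) {
  repeat {
    r <- stats::rbinom(tree$n_leaf, 1L, 0.5)
    if (any(r == 1L)) break
  }
  stats::setNames(as.integer(r), taxa(tree))
}

# Brute-force minimum number of losses that, together with the given
# origins, replays to the target row. Enumerates loss sets by size.
oracle_min_losses <- function(tree, origins, row) {
  target <- as.logical(named_row_to_leaf_order(tree, row))
  nodes <- seq_len(tree$n_node)
  for (k in 0:6) {
    sets <- if (k == 0) list(integer(0)) else utils::combn(nodes, k, simplify = FALSE)
    for (ls in sets) {
      pres <- replay_scenario(tree, origins, ls)
      if (identical(pres[seq_len(tree$n_leaf)], target)) {
        return(k)
      }
    }
  }
  stop("oracle: no loss set of size <= 6 found")
}

named_row_to_leaf_order <- function(tree, row) {
  if (is.null(names(row))) row else row[taxa(tree)]
}

# Independent BOR1 oracle built directly on the ape tree: preliminary
# origin at the MRCA of present tips; if its clade has an absent tip,
# one origin at the MRCA of present tips within each child clade.
oracle_bor1 <- function(tree, row) {
  phy <- tree$phylo
  row <- named_row_to_leaf_order(tree, row)
  present <- which(row == 1L)
  tips_under <- function(node) {
    if (node <= length(phy$tip.label)) node else {
      match(ape::extract.clade(phy, node)$tip.label, phy$tip.label)
    }
  }
  mrca_of <- function(tips) if (length(tips) == 1L) tips else ape::getMRCA(phy, tips)
  m <- mrca_of(present)
  clade <- tips_under(m)
  if (all(row[clade] == 1L)) {
    return(list(origins = m))
  }
  kids <- phy$edge[phy$edge[, 1] == m, 2]
  origins <- vapply(kids, function(k) {
    p <- intersect(tips_under(k), present)
    mrca_of(p)
  }, numeric(1))
  list(origins = sort(as.integer(origins)), preliminary = m)
}

# Deterministic seeded trees for property tests
tree_pool <- function(n_trees, n_leaves, seed) {
  set.seed(seed)
  lapply(seq_len(n_trees), function(i) {
    as_reference_tree(ape::rtree(sample(n_leaves, 1L)))
  })
}
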