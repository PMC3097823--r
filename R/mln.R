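#' Build the minimal lateral network
#'
#' The MLN is the reference tree (vertical component) augmented with the
#' lateral edges implied by an accepted borrowing model: every split
#' performed during BOR-k inference produced a pair of sibling origins, and
#' each such pair contributes one lateral edge between the two origin
#' nodes, weighted by the number of characters sharing it. Lateral edges
#' can join any two tree nodes, contemporary (external) or ancestral
#' (internal). The summed lateral weight always equals the total number of
#' inferred borrowings, `sum(n_origins - 1)`.
#'
#' @param tree A [reference_tree][as_reference_tree].
#' @param scenarios A `gl_scenarios` object from [infer_scenarios].
#' @param inventory Optional [ancestral_inventory] profile; computed from
#'   the scenarios when omitted.
#' @return A `lateral_network`: list with `tree`, `inventory` (named sizes
#'   over all nodes), `lateral` (symmetric node x node weight matrix),
#'   `edges` (tibble: `node_a`, `node_b`, `weight`, `characters` list) and
#'   `model`.
#' @examples
#' tr <- read_newick(textConnection("((A,B),(C,D));"))
#' pap <- matrix(c(1L, 0L, 1L, 0L), 1, dimnames = list("cog1", c("A", "B", "C", "D")))
#' net <- build_mln(tr, infer_scenarios(tr, pap, "BOR1"))
#' net$edges
#' @export
build_mln <- function(tree, scenarios, inventory = NULL) {
  tree <- as_reference_tree(tree)
  if (is.null(inventory)) inventory <- ancestral_inventory(tree, scenarios)
  n <- tree$n_node
  L <- matrix(0L, n, n, dimnames = list(tree$labels, tree$labels))
  chars <- list()
  for (i in seq_len(nrow(scenarios))) {
    sp <- scenarios$sibling_pairs[[i]]
    if (is.null(sp) || nrow(sp) == 0) next
    for (r in seq_len(nrow(sp))) {
      a <- min(sp[r, ])
      b <- max(sp[r, ])
      L[a, b] <- L[a, b] + 1L
      L[b, a] <- L[a, b]
      key <- paste0(a, ":", b)
      chars[[key]] <- c(chars[[key]], scenarios$character[i])
    }
  }
  if (length(chars) > 0) {
    ab <- do.call(rbind, strsplit(names(chars), ":", fixed = TRUE))
    edges <- tibble(
      node_a = as.integer(ab[, 1L]),
      node_b = as.integer(ab[, 2L]),
      weight = vapply(chars, length, integer(1), USE.NAMES = FALSE),
      characters = unname(chars)
    )
    edges <- dplyr::arrange(edges, .data$node_a, .data$node_b)
  } else {
    edges <- tibble(
      node_a = integer(0), node_b = integer(0),
      weight = integer(0), characters = list()
    )
  }
  structure(
    list(
      tree = tree, inventory = inventory$size, lateral = L,
      edges = edges, model = attr(scenarios, "model")
    ),
    class = "lateral_network"
  )
}

#' @export
print.lateral_network <- function(x, ...) {
  cat(sprintf(
    "<lateral_network: %d nodes (%d external), %d lateral edges, total weight %d, model %s>\n",
    x$tree$n_node, x$tree$n_leaf, nrow(x$edges), sum(x$edges$weight),
    x$model %||% "?"
  ))
  invisible(x)
}

#' Lateral connectivity per node
#'
#' Connectivity is the number of distinct lateral neighbours of a node
#' (edge weights ignored; tree branches not counted).
#'
#' @param net A `lateral_network` from [build_mln].
#' @return A list with `connectivity` (tibble: `node`, `label`, `kind`,
#'   `connectivity`) and summary fields `min`, `max`, `median` over all
#'   nodes.
#' @export
degree_stats <- function(net) {
  n <- net$tree$n_node
  conn <- integer(n)
  if (nrow(net$edges) > 0) {
    tab <- tabulate(c(net$edges$node_a, net$edges$node_b), nbins = n)
    conn <- as.integer(tab)
  }
  tb <- tibble(
    node = seq_len(n),
    label = net$tree$labels,
    kind = ifelse(net$tree$is_leaf, "external", "internal"),
    connectivity = conn
  )
  list(
    connectivity = tb,
    min = min(conn), max = max(conn), median = median(conn)
  )
}

#' Global statistics of the MLN graph
#'
#' Computed on the undirected, unweighted union of the tree's branches and
#' the distinct lateral edges over all nodes: the mean local clustering
#' coefficient (nodes of degree < 2 contribute 0) and the mean shortest
#' path over all reachable unordered node pairs.
#'
#' @param net A `lateral_network`.
#' @return A one-row tibble: `clustering_coefficient`,
#'   `mean_shortest_path`, `n_nodes`, `n_vertical_edges`,
#'   `n_lateral_edges`.
#' @export
graph_stats <- function(net) {
  g <- mln_igraph(net)
  cc <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  tibble(
    clustering_coefficient = cc,
    mean_shortest_path = igraph::mean_distance(g, directed = FALSE, unconnected = TRUE),
    n_nodes = net$tree$n_node,
    n_vertical_edges = net$tree$n_node - 1L,
    n_lateral_edges = nrow(net$edges)
  )
}

#' igraph view of the union MLN graph (unweighted, simple)
#' @noRd
mln_igraph <- function(net) {
  tree <- net$tree
  nonroot <- which(tree$parent != 0L)
  el <- rbind(
    cbind(tree$parent[nonroot], nonroot),
    cbind(net$edges$node_a, net$edges$node_b)
  )
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, tree$n_node - igraph::vcount(g)))
  igraph::simplify(g)
}

#' Histogram of lateral edge weights
#'
#' @param net A `lateral_network`.
#' @return A tibble with `weight` and `n_edges`; totals equal the number
#'   of distinct lateral edges.
#' @export
edge_weight_histogram <- function(net) {
  if (nrow(net$edges) == 0) {
    return(tibble(weight = integer(0), n_edges = integer(0)))
  }
  dplyr::count(net$edges, weight = .data$weight, name = "n_edges")
}

#' Classify lateral edges by endpoint kinds
#'
#' @param net A `lateral_network`.
#' @return A one-row tibble: `external_external`, `external_internal`,
#'   `internal_internal`, `total`.
#' @export
classify_edges <- function(net) {
  is_leaf <- net$tree$is_leaf
  a <- is_leaf[net$edges$node_a]
  b <- is_leaf[net$edges$node_b]
  tibble(
    external_external = sum(a & b),
    external_internal = sum(xor(a, b)),
    internal_internal = sum(!a & !b),
    total = nrow(net$edges)
  )
}

#' Fraction of each taxon's inventory involved in recent borrowing
#'
#' Lateral edges incident to an external (leaf) node represent
#' comparatively recent borrowing. For each leaf the percentage is
#' `100 * (distinct characters on incident lateral edges) / inventory`.
#'
#' @param net A `lateral_network`.
#' @return A tibble with `taxon`, `n_lateral_characters`, `inventory`,
#'   `pct` (NA when inventory is 0); the mean and SD of `pct` over leaves
#'   are attached as attributes `mean_pct` and `sd_pct`.
#' @export
recent_borrowing_fraction <- function(net) {
  tree <- net$tree
  leaves <- seq_len(tree$n_leaf)
  nchars <- vapply(leaves, function(l) {
    hit <- net$edges$node_a == l | net$edges$node_b == l
    length(unique(unlist(net$edges$characters[hit])))
  }, integer(1))
  inv <- as.integer(net$inventory[leaves])
  pct <- ifelse(inv > 0, 100 * nchars / inv, NA_real_)
  out <- tibble(
    taxon = tree$labels[leaves],
    n_lateral_characters = nchars,
    inventory = inv,
    pct = pct
  )
  attr(out, "mean_pct") <- mean(pct, na.rm = TRUE)
  attr(out, "sd_pct") <- sd(pct, na.rm = TRUE)
  out
}

#' Lateral edge frequencies within and between taxon groups
#'
#' Each leaf belongs to one group (e.g. a main branch of the family); an
#' internal node belongs to a group only when all its descendant leaves
#' do. For every group, a lateral edge is *internal* when both endpoints
#' belong to the group and *external* when exactly one does. Frequencies
#' are normalized as internal edges per node inside the group and external
#' edges per node outside the group. A one-sided two-sample
#' Kolmogorov-Smirnov test compares the internal and external edge-weight
#' samples (H0: internal weights stochastically <= external weights).
#'
#' @param net A `lateral_network`.
#' @param groups Data frame with columns `taxon` and `group` covering all
#'   leaves.
#' @return A tibble with one row per group: `group`, `n_taxa`, `n_nodes`,
#'   `freq_internal`, `freq_external`, `median_weight_internal`,
#'   `median_weight_external`, `ks_p`.
#' @export
group_edge_analysis <- function(net, groups) {
  tree <- net$tree
  groups <- tibble::as_tibble(groups)
  if (!all(c("taxon", "group") %in% names(groups))) {
    abort("`groups` needs columns taxon and group")
  }
  gl <- groups$group[match(tree$labels[seq_len(tree$n_leaf)], groups$taxon)]
  if (anyNA(gl)) {
    abort("every leaf must be assigned to a group")
  }
  node_group <- rep(NA_character_, tree$n_node)
  node_group[seq_len(tree$n_leaf)] <- as.character(gl)
  for (v in tree$postorder) {
    if (!tree$is_leaf[v]) {
      g1 <- node_group[tree$kid1[v]]
      g2 <- node_group[tree$kid2[v]]
      if (!is.na(g1) && !is.na(g2) && g1 == g2) node_group[v] <- g1
    }
  }
  ga <- node_group[net$edges$node_a]
  gb <- node_group[net$edges$node_b]
  out <- lapply(unique(as.character(gl)), function(g) {
    in_g <- !is.na(node_group) & node_group == g
    n_in <- sum(in_g)
    if (n_in == 0) {
      warn(paste0("group with no nodes skipped: ", g))
      return(NULL)
    }
    ea <- !is.na(ga) & ga == g
    eb <- !is.na(gb) & gb == g
    internal <- ea & eb
    external <- xor(ea, eb)
    wi <- net$edges$weight[internal]
    we <- net$edges$weight[external]
    ks_p <- if (length(wi) > 0 && length(we) > 0) ks_one_sided(wi, we)$p_value else NA_real_
    tibble(
      group = g,
      n_taxa = sum(gl == g),
      n_nodes = n_in,
      freq_internal = sum(internal) / n_in,
      freq_external = sum(external) / (tree$n_node - n_in),
      median_weight_internal = if (length(wi)) median(wi) else NA_real_,
      median_weight_external = if (length(we)) median(we) else NA_real_,
      ks_p = ks_p
    )
  })
  dplyr::bind_rows(out)
}

#' Classify known borrowings against inferred scenarios
#'
#' For each known (character, taxon) borrowing: if the character's
#' scenario has a single origin, no borrowing event was inferred at all
#' and the item is `not_detected`. Otherwise the item is classified by
#' the origin node that contains the borrowing taxon: `external` when the
#' taxon itself is an origin node (the borrowing language was inferred as
#' a separate origin), `internal` when it descends from an internal
#' origin (the borrowing was absorbed into an ancestral origin). Which of
#' the origins carries the "primary" label is a discovery-order
#' convention and plays no role here.
#'
#' @param scenarios A `gl_scenarios` object.
#' @param known Data frame with columns `character` and `taxon`.
#' @return A tibble with `character`, `taxon`, `class`; counts and the
#'   detection rate (percent classified external or internal) are attached
#'   as attribute `summary`.
#' @export
validate_known_borrowings <- function(scenarios, known) {
  tree <- attr(scenarios, "tree")
  known <- tibble::as_tibble(known)
  if (!all(c("character", "taxon") %in% names(known))) {
    abort("`known` needs columns character and taxon")
  }
  ci <- match(known$character, scenarios$character)
  if (anyNA(ci)) {
    abort(paste0("unknown character(s): ",
                 paste(unique(known$character[is.na(ci)]), collapse = ", ")))
  }
  li <- leaf_index(tree, as.character(known$taxon))
  cls <- vapply(seq_len(nrow(known)), function(r) {
    org <- scenarios$origins[[ci[r]]]
    if (length(org) < 2L) return("not_detected")
    leaf <- li[r]
    if (leaf %in% org) return("external")
    for (o in org[!tree$is_leaf[org]]) {
      if (leaf %in% tree$leaf_desc[[o]]) return("internal")
    }
    "not_detected"
  }, character(1))
  out <- tibble(character = known$character, taxon = known$taxon, class = cls)
  n <- nrow(out)
  smry <- tibble(
    n_known = n,
    n_external = sum(cls == "external"),
    n_internal = sum(cls == "internal"),
    n_not_detected = sum(cls == "not_detected"),
    detection_pct = 100 * sum(cls != "not_detected") / n
  )
  attr(out, "summary") <- smry
  out
}
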