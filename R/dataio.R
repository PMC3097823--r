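#' Read a rooted reference tree from a Newick file
#'
#' Parses a Newick string with [ape::read.tree], validates it (rooted,
#' unique non-empty leaf labels, >= 2 leaves) and resolves any polytomies
#' deterministically (see [as_reference_tree]). Branch lengths, if present,
#' are ignored by all downstream algorithms.
#'
#' @param path Path to a Newick file, or a connection.
#' @return A [reference_tree][as_reference_tree].
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(trimws(txt))) abort("empty Newick input")
  phy <- tryCatch(
    suppressWarnings(ape::read.tree(text = txt)),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)))
  )
  if (is.null(phy)) abort("Newick parse error: no tree found in input")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  as_reference_tree(phy)
}

#' Read / write a presence-absence pattern (PAP) matrix
#'
#' The PAP matrix is the binary characters-by-taxa matrix at the heart of
#' the method: one row per character (cognate set / gene family), one column
#' per taxon, entry 1 when the character is present in the taxon. The file
#' format is TSV (or CSV when the path ends in `.csv`): header row of taxon
#' names, first column the character id, remaining cells 0/1. All-zero rows
#' are rejected: a character must be present somewhere to be observable.
#'
#' @param path File path (`.csv` is read/written as comma-separated,
#'   anything else as tab-separated).
#' @return `read_pap_matrix()` returns an integer matrix with character ids
#'   as row names and taxa as column names. `write_pap_matrix()` returns
#'   `path`, invisibly.
#' @export
read_pap_matrix <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
  df <- reader(path, col_types = readr::cols(), progress = FALSE)
  if (ncol(df) < 2) abort("PAP file needs a character-id column plus >= 1 taxon column")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  bad <- which(!(m %in% c(0, 1) & !is.na(m)))
  if (length(bad) > 0) {
    i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    abort(sprintf("non-binary value at (%s, %s)", ids[i], colnames(m)[j]))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  validate_pap(m)
}

#' @rdname read_pap_matrix
#' @param pap A PAP matrix as returned by [read_pap_matrix] or
#'   [cognate_table_to_pap].
#' @export
write_pap_matrix <- function(pap, path) {
  pap <- validate_pap(pap)
  df <- tibble::as_tibble(pap, rownames = "character")
  writer <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::write_csv else readr::write_tsv
  writer(df, path, progress = FALSE)
  invisible(path)
}

#' Validate a binary PAP matrix
#' @noRd
validate_pap <- function(pap) {
  if (!is.matrix(pap)) abort("PAP must be a matrix")
  if (is.null(rownames(pap)) || is.null(colnames(pap))) {
    abort("PAP must carry character row names and taxon column names")
  }
  if (!all(pap %in% c(0L, 1L))) abort("PAP values must be exactly 0 or 1")
  storage.mode(pap) <- "integer"
  zero <- rownames(pap)[rowSums(pap) == 0L]
  if (length(zero) > 0) {
    abort(paste0("all-zero PAP row(s): ", paste(zero, collapse = ", ")))
  }
  if (anyDuplicated(rownames(pap))) abort("duplicate character ids")
  pap
}

#' Convert a long-format cognate/family table to a PAP matrix
#'
#' Each record states that a taxon has at least one word (or gene) in a
#' given cognate class of a given concept (gene family). Every distinct
#' (concept, class) pair becomes one binary character whose entry for a
#' taxon is 1 when the taxon has >= 1 record in that class. Known-loan
#' flags are carried along as an annotation (`attr(pap, "loans")`) and
#' never alter the presence values themselves.
#'
#' @param table A data frame with columns `concept`, `taxon`,
#'   `cognate_class`, and optionally a logical `loan` column flagging known
#'   borrowings.
#' @param taxa Optional character vector fixing the taxon set (and column
#'   order); defaults to the sorted taxa observed in the table.
#' @return An integer PAP matrix (characters x taxa); character ids are
#'   `"<concept>:<class>"`.
#' @examples
#' tab <- tibble::tibble(
#'   concept = "tooth",
#'   taxon = c("English", "German", "Italian", "French"),
#'   cognate_class = c("c1", "c1", "c2", "c2")
#' )
#' cognate_table_to_pap(tab)
#' @export
cognate_table_to_pap <- function(table, taxa = NULL) {
  table <- tibble::as_tibble(table)
  need <- c("concept", "taxon", "cognate_class")
  if (!all(need %in% names(table))) {
    abort(paste0("cognate table needs columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(table) == 0) abort("cognate table is empty")
  if (any(!nzchar(as.character(table$cognate_class)))) {
    abort("cognate class labels must be non-empty")
  }
  table$character <- paste(table$concept, table$cognate_class, sep = ":")
  if (is.null(taxa)) taxa <- sort(unique(as.character(table$taxon)))
  chars <- unique(table$character)
  m <- matrix(0L, nrow = length(chars), ncol = length(taxa),
              dimnames = list(chars, taxa))
  ti <- match(as.character(table$taxon), taxa)
  if (anyNA(ti)) abort("cognate table contains taxa outside `taxa`")
  m[cbind(match(table$character, chars), ti)] <- 1L
  m <- validate_pap(m)
  if ("loan" %in% names(table)) {
    loans <- dplyr::distinct(
      dplyr::filter(table, .data$loan),
      character = .data$character, taxon = as.character(.data$taxon)
    )
    attr(m, "loans") <- loans
  }
  m
}

#' Read a long-format cognate table from TSV/CSV
#'
#' @inheritParams read_pap_matrix
#' @return A tibble with columns `concept`, `taxon`, `cognate_class` and,
#'   when present in the file, `loan` (logical).
#' @export
read_cognate_table <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
  df <- reader(path, col_types = readr::cols(), progress = FALSE)
  need <- c("concept", "taxon", "cognate_class")
  if (!all(need %in% names(df))) {
    abort(paste0("cognate table needs columns: ", paste(need, collapse = ", ")))
  }
  if ("loan" %in% names(df)) df$loan <- as.logical(df$loan)
  df
}

#' Write a per-character gain-loss scenario report
#'
#' One row per character: number of origins (the first is the primary
#' origin, the rest are borrowed origins), the origin and loss node
#' identifiers, and the implied number of borrowings (`n_origins - 1`).
#'
#' @param scenarios A `gl_scenarios` object from [infer_scenarios].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scenario_report <- function(scenarios, path) {
  readr::write_tsv(tidy(scenarios), path, progress = FALSE)
  invisible(path)
}

#' Export a lateral network to GraphML or a weighted edge list
#'
#' The export contains every tree node (external = contemporary leaf,
#' internal = ancestral HTU) with its inventory size, the tree's branches
#' as edges of kind `"vertical"`, and the lateral edges of kind
#' `"lateral"` weighted by the number of laterally shared characters.
#'
#' @param net A `lateral_network` from [build_mln].
#' @param path Output file path.
#' @param format `"edgelist"` (TSV: from, to, weight, kind) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml")) {
  if (!format[1L] %in% c("edgelist", "graphml")) {
    abort(paste0("unsupported network format: ", format[1L]))
  }
  format <- match.arg(format)
  ex <- network_export(net)
  if (format == "edgelist") {
    readr::write_tsv(ex$edges, path, progress = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(ex$edges, directed = FALSE, vertices = ex$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Tabular view of a lateral network (nodes + edges)
#'
#' @param net A `lateral_network` from [build_mln].
#' @return A list with a `nodes` tibble (id, kind, inventory) and an
#'   `edges` tibble (from, to, weight, kind); lateral edges are stored
#'   once per unordered pair.
#' @export
network_export <- function(net) {
  tree <- net$tree
  nodes <- tibble(
    id = tree$labels,
    kind = ifelse(tree$is_leaf, "external", "internal"),
    inventory = as.integer(net$inventory)
  )
  vert <- tibble(
    from = tree$labels[tree$parent[tree$parent != 0L]],
    to = tree$labels[which(tree$parent != 0L)],
    weight = 1L,
    kind = "vertical"
  )
  lat <- net$edges
  if (nrow(lat) > 0) {
    lat <- tibble(
      from = tree$labels[lat$node_a],
      to = tree$labels[lat$node_b],
      weight = lat$weight,
      kind = "lateral"
    )
  } else {
    lat <- vert[0, ]
  }
  list(nodes = nodes, edges = dplyr::bind_rows(vert, lat))
}

#' Read a network edge list written by [write_network]
#'
#' @param path Edge-list TSV path.
#' @return A tibble with columns from, to, weight, kind.
#' @export
read_network_edgelist <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}
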