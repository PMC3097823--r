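#' Run the full borrowing-detection pipeline
#'
#' Wires the stages end to end: read inputs, summarize patterns, select
#' the borrowing-allowance model (or use a forced one), infer scenarios,
#' assemble the minimal lateral network, and write every report to
#' `<out_prefix>.*`. The run is deterministic given the inputs and
#' parameters.
#'
#' Files written (TSV unless noted): `model_selection.tsv` (per-model
#' Wilcoxon p, IQR fraction, event means), `scenarios.tsv` (per-character
#' origins/losses/borrowings), `network.tsv` or `network.graphml` (node +
#' edge export), `mln_stats.tsv` (graph statistics and edge
#' classification), `pap_summary.tsv`, and, when the annotations are
#' given, `communities.tsv`, `groups.tsv` and `validation.tsv`.
#'
#' @param tree A `reference_tree`, or a path to a Newick file.
#' @param pap A PAP matrix, or a path to a PAP TSV/CSV; alternatively
#'   `cognates` may name a long-format cognate table to convert.
#' @param out_prefix Output path prefix (e.g. `"results/run1"`).
#' @param cognates Optional cognate table (data frame or path); converted
#'   with [cognate_table_to_pap] when `pap` is `NULL`.
#' @param model `"auto"` (default: uniformitarian selection via
#'   [select_model]) or a model name to force.
#' @param alpha Significance level for model selection.
#' @param groups Optional taxon-to-group table (data frame or path) for
#'   [group_edge_analysis].
#' @param known_borrowings Optional (character, taxon) table (data frame
#'   or path) for [validate_known_borrowings].
#' @param communities If `TRUE`, also run shared-character community
#'   detection and write the partition.
#' @param format Network export format, `"edgelist"` or `"graphml"`.
#' @return Invisibly, a list with `selection` (or `NULL` when forced),
#'   `scenarios`, `inventory`, `network`, `stats`, `pap_summary`, and the
#'   optional `communities`, `groups`, `validation` tables.
#' @export
run_pipeline <- function(tree, pap = NULL, out_prefix,
                         cognates = NULL,
                         model = "auto", alpha = 0.05,
                         groups = NULL, known_borrowings = NULL,
                         communities = FALSE,
                         format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)))
    })
  }
  as_table <- function(x) if (is.character(x)) read_cognate_table(x) else tibble::as_tibble(x)

  tree <- stage("tree", if (is.character(tree)) read_newick(tree) else as_reference_tree(tree))
  pap <- stage("characters", {
    if (is.null(pap)) {
      if (is.null(cognates)) abort("either `pap` or `cognates` is required")
      cognate_table_to_pap(as_table(cognates), taxa = taxa(tree))
    } else if (is.character(pap)) {
      read_pap_matrix(pap)
    } else {
      validate_pap(pap)
    }
  })
  dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
  out <- function(suffix) paste0(out_prefix, ".", suffix)

  ps <- pap_summary(pap)
  cong <- congruence(tree, pap)
  ps$n_congruent <- sum(cong)
  ps$n_incongruent <- sum(!cong)
  readr::write_tsv(ps, out("pap_summary.tsv"), progress = FALSE)

  selection <- NULL
  if (identical(model, "auto")) {
    selection <- stage("select_model", select_model(tree, pap, alpha = alpha))
    scenarios <- selection$scenarios
    inventory <- selection$inventory
    readr::write_tsv(tidy(selection), out("model_selection.tsv"), progress = FALSE)
    message(sprintf("accepted model: %s%s", selection$accepted_model,
                    if (selection$none_accepted) " (none accepted)" else ""))
  } else {
    scenarios <- stage("infer", infer_scenarios(tree, pap, model))
    inventory <- ancestral_inventory(tree, scenarios)
  }
  write_scenario_report(scenarios, out("scenarios.tsv"))

  net <- stage("mln", build_mln(tree, scenarios, inventory))
  write_network(net, out(if (format == "graphml") "network.graphml" else "network.tsv"),
                format = format)
  stats_tb <- dplyr::bind_cols(graph_stats(net), classify_edges(net))
  deg <- degree_stats(net)
  stats_tb$connectivity_min <- deg$min
  stats_tb$connectivity_max <- deg$max
  stats_tb$connectivity_median <- deg$median
  rb <- recent_borrowing_fraction(net)
  stats_tb$recent_borrowing_mean_pct <- attr(rb, "mean_pct")
  stats_tb$recent_borrowing_sd_pct <- attr(rb, "sd_pct")
  readr::write_tsv(stats_tb, out("mln_stats.tsv"), progress = FALSE)

  comm <- NULL
  if (isTRUE(communities)) {
    comm <- stage("communities", leading_eigenvector_communities(shared_matrix(pap)))
    readr::write_tsv(tidy(comm), out("communities.tsv"), progress = FALSE)
  }
  grp <- NULL
  if (!is.null(groups)) {
    grp <- stage("groups", group_edge_analysis(net, as_table(groups)))
    readr::write_tsv(grp, out("groups.tsv"), progress = FALSE)
  }
  val <- NULL
  if (!is.null(known_borrowings)) {
    val <- stage("validate", validate_known_borrowings(scenarios, as_table(known_borrowings)))
    readr::write_tsv(val, out("validation.tsv"), progress = FALSE)
  }

  invisible(list(
    selection = selection, scenarios = scenarios, inventory = inventory,
    network = net, stats = stats_tb, pap_summary = ps,
    communities = comm, groups = grp, validation = val
  ))
}
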