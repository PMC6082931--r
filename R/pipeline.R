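#' End-to-end analysis pipeline and format conversion
#'
#' [run_pipeline()] chains the full workflow — validate the model, run the
#' wild-type scenario, the knockout/knockin panel, the wild-type comparison,
#' the loop analysis and the candidate ranking — and writes every artifact
#' plus a JSON run manifest (input checksums, parameters, package version) to
#' an output directory. [convert_model()] translates between model formats.
#' Both back the command-line wrapper in `inst/cli/hillcube-cli.R`.
#'
#' @name pipeline
NULL

read_model_any <- function(path) {
  if (!file.exists(path)) stop("model not found: ", path)
  first <- readLines(path, n = 5, warn = FALSE)
  if (any(grepl("<sbml", first, fixed = TRUE))) {
    read_sbml_qual(path)
  } else {
    parse_rules(paste(readLines(path, warn = FALSE), collapse = "\n"))
  }
}

#' Run the full analysis pipeline
#'
#' @param model_path path to a model in rule text or SBML-qual.
#' @param output_dir directory for the artifacts (created if needed).
#' @param params_path optional kinetic-parameter JSON
#'   (see [read_parameters_json()]); defaults used otherwise.
#' @param scenario_path optional scenario JSON (see [read_scenario_json()]);
#'   by default every input is set to 1 ("all signals on") with `t_end = 200`.
#' @param panel optional list of [perturbation()]; defaults to
#'   [default_pid_panel()] filtered to the model's nodes, falling back to a
#'   knockout of every regulated node when no panel entry matches.
#' @param threshold dysregulation threshold for [compare_to_wildtype()].
#' @param max_loop_length cap for [enumerate_cycles()].
#' @param candidate_threshold loop-participation threshold for
#'   [rank_candidates()].
#' @param seed integer seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return Invisibly, a list with the in-memory results and the artifact
#'   paths (`attractor_matrix.tsv`, `dysregulation.tsv`, `loop_stats.tsv`,
#'   `candidates.tsv`, `manifest.json`).
#' @export
run_pipeline <- function(model_path, output_dir, params_path = NULL,
                         scenario_path = NULL, panel = NULL, threshold = 0.1,
                         max_loop_length = 26, candidate_threshold = 0.1,
                         seed = 1) {
  network <- read_model_any(model_path)
  problems <- validate_network(network)
  if (length(problems)) stop("invalid model: ", paste(problems, collapse = "; "))
  params <- if (is.null(params_path)) kinetic_parameters()
            else read_parameters_json(params_path)
  scn <- if (is.null(scenario_path)) {
    scenario("all_inputs_on",
             input_values = stats::setNames(rep(1, length(network$inputs)),
                                            network$inputs),
             t_end = 200)
  } else read_scenario_json(scenario_path)
  if (is.null(panel)) {
    panel <- suppressWarnings(default_pid_panel(network))
    if (!length(panel)) {
      panel <- lapply(names(network$rules), function(nd)
        perturbation(paste0(nd, "-KO"), nd, 0))
    }
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  matrix <- run_pid_panel(network, params, scn, panel)
  report <- compare_to_wildtype(matrix, threshold = threshold)
  ig <- to_interaction_graph(network)
  loops <- enumerate_cycles(ig, max_length = max_loop_length)
  stats <- loop_stats(loops, ig$nodes)
  known <- unique(vapply(panel, `[[`, character(1), "node"))
  candidates <- rank_candidates(stats, known_pids = known,
                                threshold = candidate_threshold)

  paths <- list(
    attractor_matrix = file.path(output_dir, "attractor_matrix.tsv"),
    dysregulation = file.path(output_dir, "dysregulation.tsv"),
    loop_stats = file.path(output_dir, "loop_stats.tsv"),
    candidates = file.path(output_dir, "candidates.tsv"),
    manifest = file.path(output_dir, "manifest.json")
  )
  write_attractor_matrix_tsv(matrix, paths$attractor_matrix)
  utils::write.table(report, paths$dysregulation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  part <- sort(stats$participation, decreasing = TRUE)
  part_df <- data.frame(node = names(part), participation = unname(part))
  utils::write.table(part_df, paths$loop_stats, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(candidates, paths$candidates, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    model = unname(tools::md5sum(model_path)),
    params = if (is.null(params_path)) "defaults"
             else unname(tools::md5sum(params_path)),
    scenario = scn$name,
    seed = seed,
    package_version = as.character(utils::packageVersion("hillcube")),
    loop_count = stats$count,
    panel_size = length(panel),
    outputs = lapply(paths[c("attractor_matrix", "dysregulation",
                             "loop_stats", "candidates")],
                     function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(network = network, matrix = matrix, report = report,
                 loops = loops, stats = stats, candidates = candidates,
                 paths = paths))
}

#' Convert a model between formats
#'
#' @param model_path path to a model in rule text or SBML-qual.
#' @param format one of `"rules"`, `"sbml"`, `"sif"`, `"graphml"`, `"tsv"`
#'   (the last three export the interaction graph).
#' @param out output file path (for `"tsv"`, the basename stem: writes
#'   `<out>_nodes.tsv` and `<out>_edges.tsv`).
#' @return Invisibly, the written path(s).
#' @export
convert_model <- function(model_path, format, out) {
  supported <- c("rules", "sbml", "sif", "graphml", "tsv")
  if (!format %in% supported) {
    stop("unsupported format '", format, "'; supported: ",
         paste(supported, collapse = ", "))
  }
  network <- read_model_any(model_path)
  switch(format,
    rules = { write_rules(network, out); invisible(out) },
    sbml = write_sbml_qual(network, out),
    sif = write_sif(to_interaction_graph(network), out),
    graphml = write_graphml(to_interaction_graph(network), out),
    tsv = write_graph_tables(to_interaction_graph(network),
                             paste0(out, "_nodes.tsv"),
                             paste0(out, "_edges.tsv"))
  )
}
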