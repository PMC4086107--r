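# Pipeline driver: the three-step workflow (data processing -> network
# construction -> network analysis) from a single config, plus session
# save/restore. Every decision taken during a run (cutoffs, dropped rows,
# size warnings) is recorded in a run log.

SESSION_VERSION <- 1L

pipeline_defaults <- list(
  species = "custom", mapping = NULL, data_kind = "intensity",
  force_log = FALSE, factor = NULL, group_a = NULL, group_b = NULL,
  p_cutoff = 0.05, fc_cutoff = 1, use_adjusted = TRUE,
  order = "first", trim = FALSE, exclude = NULL,
  walk_steps = 4L, weight_baseline = 1,
  gmt = NULL, universe = "collection", enrich_selection = "top_module",
  seed = NULL)

#' Run the full analysis pipeline
#'
#' Executes the three-step workflow from a config (YAML file or named list):
#' load the interactome; parse, normalize and analyze the expression data
#' (or read a gene list); select seeds; build the subnetwork at the chosen
#' order with optional trimming and exclusions; analyze the continent
#' (largest component): topology table, ranked Walktrap modules and, when a
#' GMT collection is given, hypergeometric enrichment of the configured
#' selection. All result tables, a GraphML export, a session file and a run
#' log are written to the output directory.
#'
#' Config keys: `ppi` (edge list, required), `expression` or `gene_list`
#' (one required), `out_dir` (required unless passed as argument),
#' `mapping`, `data_kind`, `force_log`, `factor`, `group_a`, `group_b`,
#' `p_cutoff`, `fc_cutoff`, `use_adjusted`, `order` (`zero`/`first`/
#' `expand`), `trim`, `exclude`, `walk_steps`, `weight_baseline`, `gmt`,
#' `universe`, `enrich_selection` (`top_module`/`seeds`/`network`), `seed`.
#'
#' @param config Path to a YAML config or a named list.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a result bundle: list with `db`, `de`, `seeds`,
#'   `network`, `continent`, `components`, `topology`, `partition`,
#'   `enrichment`, `files` (named output paths) and `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(pipeline_defaults, config)
  for (key in c("ppi")) {
    if (is.null(cfg[[key]])) stop("config missing required key: '", key, "'", call. = FALSE)
  }
  if (is.null(cfg$expression) && is.null(cfg$gene_list)) {
    stop("config missing required key: 'expression' (or 'gene_list')", call. = FALSE)
  }
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("config missing required key: 'out_dir'", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  stage <- function(name, expr) {
    tryCatch(withCallingHandlers(
      expr,
      message = function(m) {
        note("[", name, "] ", sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      },
      warning = function(w) {
        note("[", name, "] warning: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
      error = function(e) stop(sprintf("stage '%s' failed: %s", name,
                                       conditionMessage(e)), call. = FALSE))
  }
  files <- list()
  out <- function(name) file.path(out_dir, name)

  db <- stage("load", load_interactions(cfg$ppi, cfg$mapping, cfg$species))
  note("[load] ", length(db$proteins), " proteins, ", nrow(db$interactions),
       " interactions")

  de <- NULL
  if (!is.null(cfg$expression)) {
    seeds <- stage("differential expression", {
      ds <- parse_expression(cfg$expression, data_kind = cfg$data_kind)
      ds <- collapse_probes(ds, db)
      ds <- normalize_expression(ds, force_log = cfg$force_log)
      fct <- if (is.null(cfg$factor)) names(ds$factors)[1L] else cfg$factor
      labels <- unique(get_factor(ds, fct))
      ga <- if (is.null(cfg$group_a)) labels[1L] else cfg$group_a
      gb <- if (is.null(cfg$group_b)) labels[2L] else cfg$group_b
      note("[differential expression] factor '", fct, "': ", gb, " vs ", ga)
      de <- differential_expression(ds, fct, ga, gb)
      files$de_table <- write_de_table(de, out("de_table.tsv"))
      s <- select_seeds(de, cfg$p_cutoff, cfg$fc_cutoff, cfg$use_adjusted)
      note("[differential expression] ", length(s$values),
           " seeds at p <= ", cfg$p_cutoff, ", |logFC| >= ", cfg$fc_cutoff)
      s
    })
  } else {
    seeds <- stage("gene list", read_seed_list(cfg$gene_list))
  }

  net <- stage("network construction", {
    n <- build_network(db, seeds,
                       order = if (cfg$order == "zero") "zero" else "first")
    if (cfg$order == "expand") n <- expand_order(db, n)
    if (!is.null(cfg$exclude)) n <- exclude_nodes(n, cfg$exclude)
    if (isTRUE(cfg$trim)) n <- trim_to_minimum(n)
    note("[network construction] order ", n$order, ": ", network_size(n),
         " nodes, ", igraph::ecount(n$graph), " edges")
    n
  })
  comps <- stage("network construction", net_components(net))
  continent <- comps[[1L]]
  note("[network construction] ", length(comps),
       " component(s); continent has ", network_size(continent), " nodes")
  files$network <- write_network(net, file.path(out_dir, "network"))
  files$graphml <- out("network.graphml")
  files$components <- write_tsv(component_summary(net), out("components.tsv"))

  topo <- stage("topology", topology_table(continent))
  files$topology <- write_topology_table(degree_table(continent),
                                         out("topology.tsv"))

  partition <- stage("module detection",
                     detect_modules(continent, steps = cfg$walk_steps,
                                    baseline = cfg$weight_baseline))
  files$modules <- write_module_table(partition, out("modules.tsv"))
  stage("export", export_graphml(net, files$graphml,
                                 partition = if (identical(network_nodes(net),
                                                           network_nodes(continent)))
                                   partition else NULL,
                                 topology = FALSE))

  enr <- NULL
  if (!is.null(cfg$gmt)) {
    enr <- stage("enrichment", {
      collection <- load_gmt(cfg$gmt, db = db,
                             universe = if (cfg$universe == "db") "db" else "collection")
      selection <- switch(cfg$enrich_selection,
                          top_module = partition$modules[[1L]],
                          seeds = network_nodes(continent)[
                            igraph::V(continent$graph)$is_seed],
                          network = network_nodes(continent),
                          stop("unknown enrich_selection '",
                               cfg$enrich_selection, "'"))
      note("[enrichment] selection '", cfg$enrich_selection, "': ",
           length(selection), " nodes vs ", length(collection$universe),
           "-gene universe")
      enrichment(selection, collection)
    })
    files$enrichment <- write_enrichment_table(enr, out("enrichment.tsv"))
  }

  files$session <- save_session(
    list(version = SESSION_VERSION, config = cfg), out("session.json"))
  writeLines(log, out("run.log"))
  files$log <- out("run.log")

  invisible(list(db = db, de = de, seeds = seeds, network = net,
                 continent = continent, components = comps, topology = topo,
                 partition = partition, enrichment = enr,
                 files = lapply(files, unname), log = log))
}

#' Save a session
#'
#' Writes the core information of a session (version tag plus the fully
#' resolved config) as JSON, so an identical run can be reproduced later
#' without redoing data preparation choices.
#'
#' @param state Named list; must contain `version` and `config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_session <- function(state, path) {
  stopifnot(is.list(state), !is.null(state$version))
  jsonlite::write_json(state, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Restore a session
#'
#' @param path Path to a session JSON written by [save_session()].
#' @return The session state list. A missing or unsupported version tag is
#'   an explicit error, never a silent misparse.
#' @export
restore_session <- function(path) {
  state <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                    error = function(e) stop("cannot parse session file '",
                                             path, "': ", conditionMessage(e),
                                             call. = FALSE))
  if (is.null(state$version) || state$version != SESSION_VERSION) {
    stop("unsupported session version: ",
         if (is.null(state$version)) "none" else state$version, call. = FALSE)
  }
  state
}

#' Re-run a restored session
#'
#' @param state A session state from [restore_session()].
#' @param out_dir Optional new output directory.
#' @return The result bundle of [run_pipeline()].
#' @export
rerun_session <- function(state, out_dir = NULL) {
  cfg <- state$config
  cfg[vapply(cfg, function(x) length(x) == 0L, TRUE)] <- NULL
  run_pipeline(cfg, out_dir = out_dir)
}
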