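#' Run configuration
#'
#' Bundles every tuning parameter of the pipeline with its default:
#' `n_s = 4` non-signature nodes on an admitting path, FDR level
#' `alpha = 0.01`, `n_boot = 2000` bootstrap replicates for the
#' perturbation p-value, `n_perm = 10000` random subsets for the topology
#' degree test. The configuration serializes losslessly to a flat
#' `key = value` text file.
#'
#' @param n_s,alpha,n_boot,n_perm,seed Core numeric parameters.
#' @param universe_mode `"platform"` or `"genome"`.
#' @param distance_rule `"intermediates"` or `"edges"`.
#' @param pathway_edge_rule `"maplink"` or `"shared_genes"`.
#' @param k_zero_penalty,min_signature_nodes,genome_size Secondary knobs.
#' @return A named list of class `subspia_config`.
#' @export
subspia_config <- function(n_s = 4, alpha = 0.01, n_boot = 2000,
                           n_perm = 10000, seed = 1,
                           universe_mode = c("platform", "genome"),
                           distance_rule = c("intermediates", "edges"),
                           pathway_edge_rule = c("maplink", "shared_genes"),
                           k_zero_penalty = 2, min_signature_nodes = 1,
                           genome_size = 25000) {
  cfg <- list(
    n_s = as.integer(n_s), alpha = as.numeric(alpha),
    n_boot = as.integer(n_boot), n_perm = as.integer(n_perm),
    seed = as.integer(seed),
    universe_mode = match.arg(universe_mode),
    distance_rule = match.arg(distance_rule),
    pathway_edge_rule = match.arg(pathway_edge_rule),
    k_zero_penalty = as.numeric(k_zero_penalty),
    min_signature_nodes = as.integer(min_signature_nodes),
    genome_size = as.integer(genome_size)
  )
  stopifnot(
    cfg$n_s >= 0, cfg$alpha > 0, cfg$alpha <= 1,
    cfg$n_boot >= 100, cfg$n_perm >= 100, cfg$min_signature_nodes >= 1
  )
  structure(cfg, class = "subspia_config")
}

#' Read/write a flat key = value configuration file
#'
#' @param path File path.
#' @return For `read_subspia_config()`, a [subspia_config()].
#' @export
read_subspia_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(map_chr(kv, 2), map_chr(kv, 1))
  do.call(subspia_config, as.list(vals))
}

#' @param config A [subspia_config()].
#' @rdname read_subspia_config
#' @export
write_subspia_config <- function(config, path) {
  stopifnot(inherits(config, "subspia_config"))
  writeLines(sprintf("%s = %s", names(config), unlist(config)), path)
  invisible(path)
}

load_pathway_dir <- function(pathway_dir) {
  files <- sort(list.files(pathway_dir,
    pattern = "\\.(xml|kgml|tsv|txt)$",
    full.names = TRUE
  ))
  if (length(files) == 0L) {
    abort(paste0("no pathway files (*.xml, *.kgml, *.tsv, *.txt) in ", pathway_dir))
  }
  map(files, function(f) {
    if (grepl("\\.(xml|kgml)$", f)) {
      parse_kgml(f)
    } else {
      parse_edge_list(f, pathway_id = sub("\\.[^.]+$", "", basename(f)))
    }
  })
}

#' Run the subpathway identification pipeline on files
#'
#' Reads every pathway document in `pathway_dir` (KGML `*.xml`/`*.kgml`,
#' or `*.tsv`/`*.txt` in the edge-list dialect), reads the DEG table,
#' runs [subspia()], and writes three reports plus a run manifest into
#' `out_dir`: `subpathways.tsv` (member genes semicolon-joined),
#' `scores.tsv`, `pathway_calls.tsv` and `manifest.json` (configuration,
#' seed, package version and input digests — enough to re-create the run
#' bit-identically).
#'
#' @param pathway_dir Directory of pathway documents.
#' @param deg_table Path to the DEG table (TSV: `gene_id`, `log_fc`).
#' @param out_dir Output directory (created if missing).
#' @param config A [subspia_config()].
#' @param universe Optional path to a one-gene-per-line universe file;
#'   defaults to the union of pathway genes and DEG-table genes.
#' @return Invisibly, a list with the `subspia_result` and output paths.
#' @export
run_subspia <- function(pathway_dir, deg_table, out_dir,
                        config = subspia_config(), universe = NULL) {
  stopifnot(inherits(config, "subspia_config"))
  graphs <- load_pathway_dir(pathway_dir)
  if (!is.null(universe)) {
    uni <- readLines(universe, warn = FALSE)
    uni <- uni[nzchar(uni)]
  } else {
    tbl <- readr::read_tsv(deg_table,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    uni <- unique(c(unlist(map(graphs, "nodes")), tbl$gene_id))
  }
  deg <- read_deg_table(deg_table, universe = uni)
  fit <- subspia(
    graphs, deg,
    n_s = config$n_s, alpha = config$alpha, n_boot = config$n_boot,
    seed = config$seed, distance_rule = config$distance_rule,
    k_zero_penalty = config$k_zero_penalty,
    min_signature_nodes = config$min_signature_nodes,
    universe_mode = config$universe_mode, genome_size = config$genome_size
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    subpathways = file.path(out_dir, "subpathways.tsv"),
    scores = file.path(out_dir, "scores.tsv"),
    calls = file.path(out_dir, "pathway_calls.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  sp_report <- fit$subpathways |>
    mutate(member_genes = map_chr(.data$members, paste, collapse = ";")) |>
    select(
      "pathway_id", "subpathway_index", "member_genes",
      "n_signature", "n_total"
    )
  readr::write_tsv(sp_report, paths$subpathways, progress = FALSE)
  scores <- fit$scores |>
    mutate(significant = .data$p_g_fdr < config$alpha) |>
    select(
      "pathway_id", "subpathway_index", "n_genes", "n_de",
      "p_nde", "p_pert", "p_g", "p_g_fdr", "significant"
    )
  readr::write_tsv(scores, paths$scores, progress = FALSE)
  readr::write_tsv(fit$calls, paths$calls, progress = FALSE)
  inputs <- c(
    sort(list.files(pathway_dir, full.names = TRUE)), deg_table,
    if (!is.null(universe)) universe
  )
  manifest <- list(
    tool = "subspia",
    version = as.character(utils::packageVersion("subspia")),
    config = unclass(config),
    inputs = lapply(inputs, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, paths$manifest,
    auto_unbox = TRUE,
    pretty = TRUE, digits = NA
  )
  invisible(list(result = fit, paths = paths))
}

#' Topology report for an identified pathway set
#'
#' Builds (or reads) the pathway crosstalk network, intersects the calls
#' with its nodes (absent ids are excluded with a warning), and writes a
#' topology report with the average degree, its permutation p-value, the
#' average clustering coefficient and the average betweenness of the
#' identified set.
#'
#' @param network_source Directory of KGML files, or a TSV edge list with
#'   columns `from`, `to`.
#' @param calls A `pathway_calls.tsv` written by [run_subspia()] (only
#'   significant pathways are used), a plain one-id-per-line file, or a
#'   character vector of pathway ids.
#' @param out_dir Output directory; `topology.tsv` is written there.
#' @param config A [subspia_config()].
#' @param method_label Value of the report's `method` column.
#' @return Invisibly, the one-row topology report tibble.
#' @export
run_topology <- function(network_source, calls, out_dir,
                         config = subspia_config(),
                         method_label = "sub-SPIA") {
  stopifnot(inherits(config, "subspia_config"))
  if (length(network_source) == 1L && dir.exists(network_source)) {
    files <- sort(list.files(network_source,
      pattern = "\\.(xml|kgml)$",
      full.names = TRUE
    ))
    net <- build_pathway_network(files,
      rule = config$pathway_edge_rule
    )
  } else {
    edges <- readr::read_tsv(network_source,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    net <- pathway_network(edges, rule = "supplied")
  }
  if (length(calls) == 1L && file.exists(calls)) {
    tbl <- readr::read_tsv(calls,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
    ids <- if ("significant" %in% names(tbl)) {
      tbl$pathway_id[tbl$significant == "TRUE"]
    } else {
      tbl[[1]]
    }
  } else {
    ids <- as.character(calls)
  }
  if (length(ids) == 0L) {
    abort("empty pathway call set")
  }
  missing <- setdiff(ids, net$nodes)
  if (length(missing) > 0L) {
    warn(paste0(
      length(missing), " pathway id(s) absent from the network were excluded"
    ))
    ids <- intersect(ids, net$nodes)
  }
  if (length(ids) == 0L) {
    abort("no called pathway is present in the network")
  }
  summary <- topology_summary(net, ids,
    n_perm = config$n_perm,
    seed = config$seed
  )
  report <- tibble(
    method = method_label,
    avg_degree = summary$avg_degree,
    degree_p_value = summary$degree_p_value,
    avg_clustering = summary$avg_clustering,
    avg_betweenness = summary$avg_betweenness,
    subset_size = summary$subset_size,
    edge_rule = net$rule
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report, file.path(out_dir, "topology.tsv"), progress = FALSE)
  invisible(report)
}
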