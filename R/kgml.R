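#' Parse a KGML pathway document into a gene graph
#'
#' Reads a KEGG Markup Language (KGML) document and reconstructs the
#' gene-level directed network. Entries holding several gene products
#' (gene families, protein complexes declared as `group` entries) are
#' expanded so each node is a single gene; a relation between multi-gene
#' entries yields the Cartesian product of gene-level edges.
#' Compound-mediated signaling (gene -> compound -> gene) is contracted to a
#' direct gene -> gene edge carrying the downstream relation's subtype.
#' Relation subtypes map to the signed weight beta through
#' [kgml_beta_table()].
#'
#' Gene identifiers are kept exactly as KGML writes them (e.g. `"hsa:1234"`);
#' any identifier mapping is the caller's job.
#'
#' @param x Path to a KGML file, or a single string holding KGML XML.
#' @param beta_table Relation to beta lookup, see [kgml_beta_table()].
#' @return A [gene_graph()].
#' @export
parse_kgml <- function(x, beta_table = kgml_beta_table()) {
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) {
      abort(paste0("malformed KGML document: ", conditionMessage(e)))
    }
  )
  root <- xml2::xml_root(doc)
  pathway_id <- xml2::xml_attr(root, "name")
  pathway_id <- sub("^path:", "", pathway_id %||% "pathway")
  if (is.na(pathway_id)) pathway_id <- "pathway"
  pathway_name <- xml2::xml_attr(root, "title")
  if (is.na(pathway_name)) pathway_name <- pathway_id

  entries <- xml2::xml_find_all(doc, ".//entry")
  entry_id <- xml2::xml_attr(entries, "id")
  entry_type <- xml2::xml_attr(entries, "type")
  entry_name <- xml2::xml_attr(entries, "name")

  # genes per entry id; group entries take the union of their components
  genes_of <- stats::setNames(vector("list", length(entry_id)), entry_id)
  is_compound <- stats::setNames(entry_type == "compound", entry_id)
  for (i in seq_along(entries)) {
    type <- entry_type[[i]]
    if (type %in% c("gene", "ortholog", "enzyme")) {
      genes_of[[i]] <- strsplit(trimws(entry_name[[i]]), "\\s+")[[1]]
    } else if (type == "compound") {
      genes_of[[i]] <- character()
    } else if (type == "group") {
      comp <- xml2::xml_attr(xml2::xml_find_all(entries[[i]], "./component"), "id")
      missing <- setdiff(comp, entry_id)
      if (length(missing) > 0L) {
        abort(paste0(
          "group entry ", entry_id[[i]],
          " references undefined entry id(s): ", toString(missing)
        ))
      }
      genes_of[[i]] <- unique(unlist(genes_of[comp], use.names = FALSE))
    } else {
      genes_of[[i]] <- character() # map/other entries carry no genes here
    }
  }

  rels <- xml2::xml_find_all(doc, ".//relation")
  rel_rows <- list()
  if (length(rels) > 0L) {
    e1 <- xml2::xml_attr(rels, "entry1")
    e2 <- xml2::xml_attr(rels, "entry2")
    missing <- setdiff(c(e1, e2), entry_id)
    if (length(missing) > 0L) {
      abort(paste0("relation references undefined entry id(s): ", toString(missing)))
    }
    for (i in seq_along(rels)) {
      subtypes <- xml2::xml_attr(xml2::xml_find_all(rels[[i]], "./subtype"), "name")
      if (length(subtypes) == 0L) subtypes <- "unknown"
      rel_rows[[i]] <- tibble(entry1 = e1[[i]], entry2 = e2[[i]], relation = subtypes)
    }
  }
  rel_tbl <- if (length(rel_rows) > 0L) bind_rows(rel_rows) else {
    tibble(entry1 = character(), entry2 = character(), relation = character())
  }

  # contract gene -> compound -> gene into gene -> gene, keeping the
  # downstream relation's subtype
  if (nrow(rel_tbl) > 0L && any(is_compound)) {
    to_cpd <- rel_tbl[is_compound[rel_tbl$entry2] & !is_compound[rel_tbl$entry1], ]
    from_cpd <- rel_tbl[is_compound[rel_tbl$entry1] & !is_compound[rel_tbl$entry2], ]
    contracted <- inner_join(
      to_cpd[, c("entry1", "entry2")],
      from_cpd,
      by = c("entry2" = "entry1"),
      relationship = "many-to-many"
    )
    contracted <- tibble(
      entry1 = contracted$entry1,
      entry2 = contracted$entry2.y,
      relation = contracted$relation
    )
    keep <- !is_compound[rel_tbl$entry1] & !is_compound[rel_tbl$entry2]
    rel_tbl <- bind_rows(rel_tbl[keep, ], contracted)
  }

  # Cartesian expansion of entry-level relations into gene-level edges
  edge_rows <- vector("list", nrow(rel_tbl))
  if (nrow(rel_tbl) > 0L) {
    for (i in seq_len(nrow(rel_tbl))) {
      src <- genes_of[[rel_tbl$entry1[[i]]]]
      dst <- genes_of[[rel_tbl$entry2[[i]]]]
      if (length(src) == 0L || length(dst) == 0L) next
      grid <- expand.grid(from = src, to = dst, stringsAsFactors = FALSE)
      grid$relation <- rel_tbl$relation[[i]]
      edge_rows[[i]] <- grid
    }
  }
  edges <- bind_rows(edge_rows)
  all_genes <- unique(unlist(genes_of, use.names = FALSE))
  gene_graph(
    edges = edges, nodes = all_genes,
    pathway_id = pathway_id, pathway_name = pathway_name,
    beta_table = beta_table
  )
}

#' Parse the tab-separated edge-list dialect
#'
#' A plain-text stand-in for KGML used by the synthetic-data generator and
#' test fixtures: one edge per line as `source<TAB>relation<TAB>target`,
#' `#` starting a comment line. The relation vocabulary is the KGML subtype
#' table of [kgml_beta_table()].
#'
#' @param x Path to an edge-list file, or a character vector of lines
#'   (a single string may hold embedded newlines).
#' @param pathway_id,pathway_name Pathway labels for the resulting graph.
#' @param beta_table Relation to beta lookup.
#' @return A [gene_graph()]; the same contract as [parse_kgml()].
#' @export
#' @examples
#' parse_edge_list(c("A\tactivation\tB", "B\tinhibition\tC"))
parse_edge_list <- function(x, pathway_id = "pathway",
                            pathway_name = pathway_id,
                            beta_table = kgml_beta_table()) {
  if (length(x) == 1L && file.exists(x)) {
    lines <- readLines(x, warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  rows <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[[j]]
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3L) {
      abort(paste0("line ", i, ": expected 'source<TAB>relation<TAB>target'"))
    }
    if (!fields[[2]] %in% names(beta_table)) {
      abort(paste0("line ", i, ": unknown relation token '", fields[[2]], "'"))
    }
    rows[[j]] <- tibble(from = fields[[1]], to = fields[[3]], relation = fields[[2]])
  }
  gene_graph(
    edges = bind_rows(rows), pathway_id = pathway_id,
    pathway_name = pathway_name, beta_table = beta_table
  )
}

#' Write a gene graph in the edge-list dialect
#'
#' Inverse of [parse_edge_list()] up to line order; isolated nodes are not
#' representable in the dialect and are dropped with a warning.
#'
#' @param graph A [gene_graph()].
#' @param path Output file path; when `NULL` the lines are returned.
#' @return Invisibly (or visibly for `path = NULL`) the character lines.
#' @export
write_edge_list <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "gene_graph"))
  isolated <- setdiff(graph$nodes, c(graph$edges$from, graph$edges$to))
  if (length(isolated) > 0L) {
    warn(paste0(
      length(isolated), " isolated node(s) not representable in the ",
      "edge-list dialect were dropped"
    ))
  }
  lines <- sprintf("%s\t%s\t%s", graph$edges$from, graph$edges$relation, graph$edges$to)
  if (is.null(path)) {
    return(lines)
  }
  writeLines(lines, path)
  invisible(lines)
}

#' Emit a minimal well-formed KGML document for a gene graph
#'
#' Writes one `gene` entry per node and one relation per edge (subtype =
#' the stored relation string). Optional `map` entries referencing other
#' pathways support pathway-network construction. Parsing the emitted
#' document with [parse_kgml()] recovers the graph whenever every relation
#' is a single KGML subtype token.
#'
#' @param graph A [gene_graph()].
#' @param path Output path; when `NULL` the XML string is returned.
#' @param map_refs Character vector of pathway ids to reference with
#'   `map`-type entries (pathway crosstalk links).
#' @return The XML as a string, invisibly when written to `path`.
#' @export
write_kgml <- function(graph, path = NULL, map_refs = character()) {
  stopifnot(inherits(graph, "gene_graph"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  id_of <- stats::setNames(seq_along(graph$nodes), graph$nodes)
  lines <- c(
    '<?xml version="1.0"?>',
    sprintf(
      '<pathway name="path:%s" org="synthetic" number="0" title="%s">',
      esc(graph$pathway_id), esc(graph$pathway_name)
    ),
    sprintf(
      '  <entry id="%d" name="%s" type="gene"/>',
      id_of, esc(graph$nodes)
    )
  )
  if (length(map_refs) > 0L) {
    lines <- c(lines, sprintf(
      '  <entry id="%d" name="path:%s" type="map"/>',
      length(id_of) + seq_along(map_refs), esc(map_refs)
    ))
  }
  if (nrow(graph$edges) > 0L) {
    lines <- c(lines, sprintf(
      paste0(
        '  <relation entry1="%d" entry2="%d" type="PPrel">\n',
        '    <subtype name="%s" value=""/>\n  </relation>'
      ),
      id_of[graph$edges$from], id_of[graph$edges$to], esc(graph$edges$relation)
    ))
  }
  xml <- paste(c(lines, "</pathway>"), collapse = "\n")
  if (is.null(path)) {
    return(xml)
  }
  writeLines(xml, path)
  invisible(xml)
}
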