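#' Differential-expression input
#'
#' Bundles the three gene lists the scoring model needs: the background
#' universe of `m` genes against which enrichment is judged (typically all
#' genes measured on the platform), the list of `n` genes submitted for
#' analysis (the differentially expressed gene list; a larger submitted
#' list may be supplied), and the signed expression changes
#' \eqn{\Delta E} (log fold-changes) of the signature genes.
#'
#' @param universe Character vector of background gene identifiers (size m).
#' @param delta_e Named numeric vector of signed log fold-changes; the names
#'   are the signature genes.
#' @param analyzed Character vector of genes submitted for analysis (size n);
#'   defaults to the signature genes, which is the usual DEG-list reading.
#' @return An object of class `deg_input` with elements `universe`,
#'   `analyzed`, `delta_e`.
#' @export
#' @examples
#' deg_input(paste0("g", 1:10), c(g1 = 2, g2 = -1))
deg_input <- function(universe, delta_e, analyzed = names(delta_e)) {
  universe <- unique(as.character(universe))
  if (length(delta_e) > 0L &&
    (is.null(names(delta_e)) || any(!nzchar(names(delta_e))))) {
    abort("`delta_e` must be a named numeric vector (gene -> log fold-change)")
  }
  delta_e <- stats::setNames(as.numeric(delta_e), names(delta_e))
  if (anyDuplicated(names(delta_e))) {
    abort("duplicate gene identifiers in `delta_e`")
  }
  if (length(delta_e) > 0L && any(!is.finite(delta_e))) {
    abort("`delta_e` values must be finite")
  }
  analyzed <- unique(as.character(analyzed))
  if (!all(analyzed %in% universe)) {
    abort(paste0(
      "analyzed gene(s) not in universe: ",
      toString(head(setdiff(analyzed, universe), 5))
    ))
  }
  if (!all(names(delta_e) %in% analyzed)) {
    abort("signature genes (names of `delta_e`) must be a subset of `analyzed`")
  }
  structure(
    list(universe = universe, analyzed = analyzed, delta_e = delta_e),
    class = "deg_input"
  )
}

#' @export
print.deg_input <- function(x, ...) {
  cat(
    "<deg_input> m =", length(x$universe), "universe genes, n =",
    length(x$analyzed), "analyzed,", length(x$delta_e), "signature genes\n"
  )
  invisible(x)
}

#' Read a DEG table
#'
#' Reads a tab-separated table with header columns `gene_id`, `log_fc` and
#' optionally `adj_p`. Every row is taken as a signature gene: thresholding
#' (e.g. on adjusted p-values) is the caller's job upstream of this
#' function. Genes absent from the universe are excluded with a warning
#' reporting the count; duplicated gene ids and non-numeric fold-changes
#' are errors.
#'
#' @param path Path to the TSV file (or a literal string with embedded
#'   newlines).
#' @param universe Character vector of background gene identifiers.
#' @return A [deg_input()].
#' @export
read_deg_table <- function(path, universe) {
  tbl <- readr::read_tsv(
    if (length(path) == 1L && file.exists(path)) path else I(path),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!all(c("gene_id", "log_fc") %in% names(tbl))) {
    abort("DEG table must have columns `gene_id` and `log_fc`")
  }
  if (anyDuplicated(tbl$gene_id)) {
    abort(paste0(
      "duplicate gene id(s) in DEG table: ",
      toString(unique(tbl$gene_id[duplicated(tbl$gene_id)]))
    ))
  }
  lfc <- suppressWarnings(as.numeric(tbl$log_fc))
  bad <- which(is.na(lfc) & !tbl$log_fc %in% c("NA", ""))
  if (length(bad) > 0L) {
    abort(paste0("non-numeric log_fc at row ", bad[[1]], ": '", tbl$log_fc[[bad[[1]]]], "'"))
  }
  if (anyNA(lfc)) {
    abort(paste0("missing log_fc at row ", which(is.na(lfc))[[1]]))
  }
  universe <- unique(as.character(universe))
  outside <- !tbl$gene_id %in% universe
  if (any(outside)) {
    warn(paste0(
      sum(outside), " DEG table gene(s) not in the universe were excluded"
    ))
  }
  deg_input(
    universe = universe,
    delta_e = stats::setNames(lfc[!outside], tbl$gene_id[!outside])
  )
}

#' Write a DEG table
#'
#' @param deg A [deg_input()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(deg, path) {
  stopifnot(inherits(deg, "deg_input"))
  readr::write_tsv(
    tibble(gene_id = names(deg$delta_e), log_fc = unname(deg$delta_e)),
    path, progress = FALSE
  )
  invisible(path)
}
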