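#' Upper-tail hypergeometric enrichment probability
#'
#' Probability of observing at least `r` analyzed (DE) genes in a gene set
#' of size `t`, when `n` of the `m` universe genes are analyzed:
#' \deqn{p = 1 - \sum_{x=0}^{r-1} \binom{t}{x}\binom{m-t}{n-x} / \binom{m}{n}.}
#'
#' @param m Universe size (background genes).
#' @param t Genes in the subpathway under investigation.
#' @param n Genes submitted for analysis (the DEG list).
#' @param r Analyzed genes observed in the subpathway.
#' @return `P(X >= r)` for `X ~ Hypergeometric(m, t, n)`; vectorized.
#' @export
#' @examples
#' p_nde(m = 10, t = 4, n = 5, r = 4) # 6/252
p_nde <- function(m, t, n, r) {
  if (any(t > m | n > m | r > pmin(t, n) | r < 0 | m < 0)) {
    abort("require 0 <= r <= min(t, n), t <= m, n <= m")
  }
  phyper(r - 1, t, m - t, n, lower.tail = FALSE)
}

# Signed adjacency of the induced subgraph, column-normalized by the
# out-degree (number of downstream genes) of the source gene:
# B[i, j] = beta(j -> i) / N_ds(j).
beta_matrix <- function(graph, members) {
  members <- sort(unique(as.character(members)))
  e <- graph$edges[graph$edges$from %in% members & graph$edges$to %in% members, ]
  nt <- length(members)
  B <- matrix(0, nt, nt, dimnames = list(members, members))
  if (nrow(e) > 0L) {
    n_ds <- table(factor(e$from, levels = members))
    B[cbind(match(e$to, members), match(e$from, members))] <-
      e$beta / as.numeric(n_ds[e$from])
  }
  B
}

#' Solve the perturbation-factor fixed point
#'
#' Each gene's perturbation factor is its own signed expression change plus
#' the normalized, sign-weighted perturbation inherited from directly
#' upstream genes:
#' \deqn{PF(g_i) = \Delta E(g_i) + \sum_j \beta_{ij} PF(g_j) / N_{ds}(g_j),}
#' where \eqn{N_{ds}(g_j)} is the number of genes downstream of
#' \eqn{g_j} within the subgraph. The linear fixed point
#' \eqn{(I - B)\,pf = \Delta E} is solved directly; genes without measured
#' differential signal take \eqn{\Delta E = 0}.
#'
#' @param graph A [gene_graph()] (or a larger graph restricted through
#'   `members`).
#' @param delta_e Named numeric vector of signed expression changes; genes
#'   not named take 0.
#' @param members Genes of the subpathway; defaults to all graph nodes.
#' @param rcond_min Reciprocal-condition threshold below which the system
#'   is flagged singular instead of solved.
#' @return An object of class `perturbation_state`: list with `pf`, `acc`
#'   (net accumulation `pf - delta_e`), `t_a` (total accumulation),
#'   `beta_matrix`, and logical `singular`.
#' @export
perturbation_factors <- function(graph, delta_e, members = graph$nodes,
                                 rcond_min = 1e-12) {
  stopifnot(inherits(graph, "gene_graph"))
  members <- sort(unique(as.character(members)))
  B <- beta_matrix(graph, members)
  de <- stats::setNames(numeric(length(members)), members)
  known <- intersect(names(delta_e), members)
  de[known] <- delta_e[known]
  A <- diag(length(members)) - B
  if (length(members) > 1L && rcond(A) < rcond_min ||
    length(members) == 1L && abs(A[1, 1]) < rcond_min) {
    return(structure(
      list(
        pf = NULL, acc = NULL, t_a = NA_real_,
        beta_matrix = B, singular = TRUE
      ),
      class = "perturbation_state"
    ))
  }
  pf <- drop(solve(A, de))
  names(pf) <- members
  acc <- pf - de
  structure(
    list(
      pf = pf, acc = acc, t_a = sum(acc),
      beta_matrix = B, singular = FALSE
    ),
    class = "perturbation_state"
  )
}

#' @export
print.perturbation_state <- function(x, ...) {
  if (x$singular) {
    cat("<perturbation_state> singular system (flagged)\n")
  } else {
    cat(
      "<perturbation_state>", length(x$pf), "genes, total accumulation t_A =",
      format(x$t_a), "\n"
    )
  }
  invisible(x)
}

#' Bootstrap perturbation p-value
#'
#' Builds the null distribution of the total net accumulation
#' \eqn{t_A = \sum_g (PF(g) - \Delta E(g))} by repeatedly placing `r`
#' expression changes drawn from the experiment-wide DEG list
#' (`deg$delta_e`, without replacement) onto genes drawn uniformly at
#' random (without replacement) from the subpathway, and recomputing
#' \eqn{t_A}. The returned p-value is the two-sided tail
#' probability of the observed \eqn{t_A} against the median-centered null,
#' with +1 smoothing. Degenerate cases (no signature gene, no edges, a
#' singular linear system, or a null with no variation) return 1.
#'
#' @inheritParams perturbation_factors
#' @param deg A [deg_input()].
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Optional integer seed; the global RNG state is preserved.
#' @return A p-value in (0, 1].
#' @export
p_pert <- function(graph, deg, members = graph$nodes, n_boot = 2000,
                   seed = NULL) {
  stopifnot(inherits(graph, "gene_graph"), inherits(deg, "deg_input"))
  members <- sort(unique(as.character(members)))
  de_genes <- intersect(names(deg$delta_e), members)
  r <- length(de_genes)
  if (r == 0L) {
    return(1)
  }
  ps <- perturbation_factors(graph, deg$delta_e, members)
  if (ps$singular) {
    warn("singular (I - B) system; p_pert set to 1")
    return(1)
  }
  # t_A is linear in the assigned Delta E vector: t_A = sum(M %*% de) with
  # M = (I - B)^{-1} - I, so each replicate costs O(r) after one inversion.
  nt <- length(members)
  M <- solve(diag(nt) - ps$beta_matrix) - diag(nt)
  col_m <- colSums(M)
  de_vals <- unname(deg$delta_e[de_genes])
  t_obs <- sum(col_m[match(de_genes, members)] * de_vals)
  if (nrow(graph$edges[graph$edges$from %in% members &
    graph$edges$to %in% members, ]) == 0L || all(col_m == 0)) {
    return(1)
  }
  pool <- unname(deg$delta_e)
  draw <- function() sum(col_m[sample.int(nt, r)] * sample(pool, r))
  t_null <- if (is.null(seed)) {
    vapply(seq_len(n_boot), function(b) draw(), numeric(1))
  } else {
    withr::with_seed(seed, vapply(seq_len(n_boot), function(b) draw(), numeric(1)))
  }
  center <- median(t_null)
  s_obs <- t_obs - center
  s_null <- t_null - center
  p <- 2 * min(
    (1 + sum(s_null >= s_obs)) / (n_boot + 1),
    (1 + sum(s_null <= s_obs)) / (n_boot + 1)
  )
  min(p, 1)
}

#' Combine enrichment and perturbation evidence
#'
#' For independent uniform p-values the product \eqn{c = P_{NDE} P_{PERT}}
#' has tail probability \eqn{P(U_1 U_2 \le c) = c - c \ln c}; this is the
#' global subpathway p-value. The limit at `c = 0` is 0 and `c = 1` gives 1.
#'
#' @param p_nde,p_pert Probabilities in \[0, 1\]; vectorized.
#' @return The combined probability `c - c*log(c)`.
#' @export
#' @examples
#' combine_pg(0.01, 0.01) # ~1.021e-3
combine_pg <- function(p_nde, p_pert) {
  if (any(p_nde < 0 | p_nde > 1 | p_pert < 0 | p_pert > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  cc <- p_nde * p_pert
  ifelse(cc <= 0, 0, cc - cc * log(cc))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, each at least the raw value,
#' capped at 1), computed with `stats::p.adjust(method = "BH")`.
#'
#' @param p Non-empty numeric vector of probabilities.
#' @return Adjusted p-values in the input order.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0L) {
    abort("`p` must be non-empty")
  }
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Score located subpathways
#'
#' Computes for each located subpathway the hypergeometric enrichment
#' p-value `p_nde` (t = all genes of the trimmed tree, r = its signature
#' genes), the bootstrap perturbation p-value `p_pert` on the directed
#' subgraph induced by the subpathway's members, their product `c`, the
#' combined `p_g = c - c*log(c)`, and Benjamini-Hochberg adjusted `p_g_fdr`
#' over all scored subpathways as one family.
#'
#' @param subpathways Tibble from [locate_subpathways()] (possibly several
#'   pathways bound together).
#' @param graphs A single [gene_graph()] or a list of them; matched to rows
#'   by `pathway_id`.
#' @param deg A [deg_input()].
#' @param n_boot Bootstrap replicates for `p_pert`.
#' @param seed Optional integer master seed; per-subpathway seeds are
#'   derived deterministically from it.
#' @param universe_mode `"platform"` takes m from `deg$universe`;
#'   `"genome"` uses `genome_size`.
#' @param genome_size Universe size under `universe_mode = "genome"`.
#' @return A tibble with columns `pathway_id`, `subpathway_index`,
#'   `n_genes`, `n_de`, `p_nde`, `p_pert`, `c`, `p_g`, `p_g_fdr`.
#' @export
score_subpathways <- function(subpathways, graphs, deg, n_boot = 2000,
                              seed = NULL,
                              universe_mode = c("platform", "genome"),
                              genome_size = 25000) {
  stopifnot(inherits(deg, "deg_input"))
  universe_mode <- match.arg(universe_mode)
  if (inherits(graphs, "gene_graph")) {
    graphs <- stats::setNames(list(graphs), graphs$pathway_id)
  } else {
    names(graphs) <- map_chr(graphs, "pathway_id")
  }
  empty <- tibble(
    pathway_id = character(), subpathway_index = integer(),
    n_genes = integer(), n_de = integer(), p_nde = numeric(),
    p_pert = numeric(), c = numeric(), p_g = numeric(), p_g_fdr = numeric()
  )
  if (nrow(subpathways) == 0L) {
    return(empty)
  }
  m <- if (universe_mode == "platform") length(deg$universe) else genome_size
  n <- length(deg$analyzed)
  rows <- map(seq_len(nrow(subpathways)), function(i) {
    g <- graphs[[subpathways$pathway_id[[i]]]]
    if (is.null(g)) {
      abort(paste0("no graph supplied for pathway ", subpathways$pathway_id[[i]]))
    }
    members <- subpathways$members[[i]]
    t_i <- length(members)
    r_i <- subpathways$n_signature[[i]]
    pn <- p_nde(m = m, t = t_i, n = n, r = r_i)
    pp <- p_pert(g, deg,
      members = members, n_boot = n_boot,
      seed = if (is.null(seed)) NULL else (seed + i) %% .Machine$integer.max
    )
    tibble(
      pathway_id = subpathways$pathway_id[[i]],
      subpathway_index = subpathways$subpathway_index[[i]],
      n_genes = t_i, n_de = r_i, p_nde = pn, p_pert = pp
    )
  })
  out <- bind_rows(rows)
  out$c <- out$p_nde * out$p_pert
  out$p_g <- combine_pg(out$p_nde, out$p_pert)
  out$p_g_fdr <- fdr_adjust(out$p_g)
  out
}

#' Roll subpathway scores up to pathway calls
#'
#' A pathway is significantly enriched if and only if it contains at least
#' one significant subpathway: its reported p-value is the minimum
#' FDR-adjusted `p_g` over its subpathways, and it is called significant
#' when that minimum is below `alpha`. Pathways without any located
#' subpathway are absent from the output.
#'
#' @param scores Tibble from [score_subpathways()].
#' @param alpha FDR significance level (default 0.01).
#' @return A tibble sorted by ascending `p_g_fdr` with columns
#'   `pathway_id`, `n_subpathways`, `p_g_fdr`, `significant`.
#' @export
call_pathways <- function(scores, alpha = 0.01) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha <= 1)
  scores |>
    group_by(.data$pathway_id) |>
    summarise(
      n_subpathways = n(),
      p_g_fdr = min(.data$p_g_fdr),
      .groups = "drop"
    ) |>
    mutate(significant = .data$p_g_fdr < alpha) |>
    arrange(.data$p_g_fdr, .data$pathway_id)
}
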