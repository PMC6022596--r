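# Term enrichment over an ontology DAG: true-path annotation propagation,
# exact upper-tail hypergeometric tests, and an elim-style pass that removes
# the genes of significantly enriched descendant terms before testing their
# ancestors.

#' Ontology DAG constructor
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param parents named list term id -> character vector of `is_a` parent
#'   ids. Every parent must be a declared term; the graph must be acyclic.
#' @return object of class `go_dag` with precomputed ancestor sets and
#'   roots.
#' @export
go_dag <- function(terms, parents) {
  if (anyDuplicated(terms$id))
    stop_param("duplicate term id(s): %s",
               paste(unique(terms$id[duplicated(terms$id)])[1:3],
                     collapse = ", "))
  parents <- parents[terms$id]
  names(parents) <- terms$id
  parents <- lapply(parents, function(p) if (is.null(p)) character() else p)
  for (id in terms$id) {
    bad <- setdiff(parents[[id]], terms$id)
    if (length(bad))
      stop_param("term '%s' has undeclared is_a parent(s): %s",
                 id, paste(bad, collapse = ", "))
  }
  edges <- data.frame(child = rep(names(parents), lengths(parents)),
                      parent = unlist(parents, use.names = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = terms$id)
  if (!igraph::is_dag(g)) stop_param("is_a relations contain a cycle")
  # ancestors by reachability along child -> parent edges
  anc <- lapply(igraph::ego(g, order = igraph::vcount(g), mode = "out",
                            mindist = 1),
                function(v) sort(names(v)))
  names(anc) <- terms$id
  roots <- terms$id[lengths(parents) == 0]
  structure(list(terms = terms, parents = parents, ancestors = anc,
                 roots = roots, graph = g),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("Ontology DAG: %d terms, %d root(s)\n",
              nrow(x$terms), length(x$roots)))
  invisible(x)
}

#' True-path propagation of gene annotations
#'
#' Annotates each gene to every ancestor of its directly annotated terms
#' (each term once), per the true-path rule.
#'
#' @param dag a [go_dag].
#' @param direct named list gene -> character vector of directly annotated
#'   term ids.
#' @return named list gene -> sorted character vector including ancestors.
#' @export
propagate_annotations <- function(dag, direct) {
  unknown <- setdiff(unique(unlist(direct, use.names = FALSE)), dag$terms$id)
  if (length(unknown))
    stop_param("annotation to unknown term(s): %s",
               paste(head(unknown, 5), collapse = ", "))
  lapply(direct, function(terms)
    sort(unique(c(terms, unlist(dag$ancestors[terms], use.names = FALSE)))))
}

#' Exact upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of seeing
#' at least `k` annotated genes in a sample of `n` from a universe of `N`
#' genes of which `K` are annotated. Exact (no normal approximation);
#' vectorized over its arguments.
#'
#' @param fg_annotated annotated genes in the study set (k).
#' @param fg_total study-set size (n).
#' @param bg_annotated annotated genes in the background (K).
#' @param bg_total background size (N).
#' @return p-value(s) in \[0, 1\].
#' @export
fisher_term_test <- function(fg_annotated, fg_total, bg_annotated, bg_total) {
  if (any(fg_annotated > fg_total) || any(fg_total > bg_total) ||
      any(fg_annotated > bg_annotated) || any(bg_annotated > bg_total) ||
      any(c(fg_annotated, fg_total, bg_annotated, bg_total) < 0))
    stop_param("inconsistent counts: need k <= n <= N and k <= K <= N")
  phyper(fg_annotated - 1, bg_annotated, bg_total - bg_annotated, fg_total,
         lower.tail = FALSE)
}

#' Term enrichment of a gene set over an ontology DAG
#'
#' Tests every term annotating at least `min_count` background genes with
#' the exact hypergeometric test, using propagated annotations. With
#' `method = "elim"`, terms are processed children-before-parents and the
#' annotated genes of any term with `p < elim_alpha` are removed from all
#' of its ancestors before those are tested, decorrelating inherited
#' signal; when no term reaches `elim_alpha` the results equal the classic
#' per-term tests.
#'
#' @param dag a [go_dag].
#' @param annotation named list gene -> term ids. Propagated with the
#'   true-path rule unless `propagate = FALSE` (then assumed already
#'   propagated).
#' @param fg study (foreground) gene ids; must be a subset of `bg`.
#' @param bg background gene ids.
#' @param method `"classic"` or `"elim"`.
#' @param elim_alpha significance level that triggers elimination.
#' @param min_count minimum background annotation count for a term to be
#'   tested.
#' @param propagate propagate annotations before testing?
#' @return data.frame sorted by ascending p-value with columns `term_id`,
#'   `name`, `fg_annotated`, `fg_total`, `bg_annotated`, `bg_total`,
#'   `p_value`, `q_value` (Benjamini-Hochberg; reported alongside, never
#'   used for filtering).
#' @export
go_enrichment <- function(dag, annotation, fg, bg,
                          method = c("classic", "elim"),
                          elim_alpha = 0.01, min_count = 1L,
                          propagate = TRUE) {
  method <- match.arg(method)
  if (!all(fg %in% bg))
    stop_param("foreground gene(s) outside the background: %s",
               paste(head(setdiff(fg, bg), 3), collapse = ", "))
  if (propagate) annotation <- propagate_annotations(dag, annotation)
  annotation <- annotation[intersect(names(annotation), bg)]
  term_genes <- split(rep(names(annotation), lengths(annotation)),
                      unlist(annotation, use.names = FALSE))
  bg_n <- vapply(term_genes, length, 0L)
  term_genes <- term_genes[bg_n >= min_count]
  if (!length(term_genes)) return(enrichment_frame(character(0)))
  N <- length(bg)
  n <- length(fg)

  if (method == "classic") {
    k <- vapply(term_genes, function(g) sum(g %in% fg), 0L)
    K <- vapply(term_genes, length, 0L)
    p <- fisher_term_test(k, n, K, N)
  } else {
    ord <- topo_children_first(dag)
    ord <- ord[ord %in% names(term_genes)]
    eliminated <- setNames(vector("list", length(ord)), ord)
    k <- K <- setNames(integer(length(ord)), ord)
    p <- setNames(numeric(length(ord)), ord)
    for (t in ord) {
      genes <- setdiff(term_genes[[t]], eliminated[[t]])
      K[t] <- length(genes)
      k[t] <- sum(genes %in% fg)
      p[t] <- if (K[t] == 0) 1 else fisher_term_test(k[t], n, K[t], N)
      if (p[t] < elim_alpha) {
        for (a in intersect(dag$ancestors[[t]], ord))
          eliminated[[a]] <- union(eliminated[[a]], term_genes[[t]])
      }
    }
    term_genes <- term_genes[ord]
  }
  res <- enrichment_frame(names(term_genes))
  res$fg_annotated <- unname(k)
  res$fg_total <- n
  res$bg_annotated <- unname(K)
  res$bg_total <- N
  res$p_value <- unname(p)
  res$q_value <- p.adjust(res$p_value, method = "BH")
  nm <- setNames(dag$terms$name, dag$terms$id)
  res$name <- unname(nm[res$term_id])
  res <- res[order(res$p_value, res$term_id), ]
  rownames(res) <- NULL
  res
}

enrichment_frame <- function(term_ids) {
  data.frame(term_id = term_ids, name = NA_character_,
             fg_annotated = integer(length(term_ids)),
             fg_total = integer(length(term_ids)),
             bg_annotated = integer(length(term_ids)),
             bg_total = integer(length(term_ids)),
             p_value = numeric(length(term_ids)),
             q_value = numeric(length(term_ids)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# topological order with children before parents (edges run child->parent)
topo_children_first <- function(dag) {
  names(igraph::topo_sort(dag$graph, mode = "out"))
}
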