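# Orthologue clustering: protein all-vs-all hits -> weighted similarity
# graph -> Markov clustering (MCL) -> lineage-specific cluster selection.

#' Build an undirected similarity graph from protein alignment hits
#'
#' Edge weight is `-log10(evalue)`, with e-values of 0 (or below
#' `evalue_cap`) capped at `-log10(evalue_cap)`. Reciprocal hits between the
#' same pair are merged keeping the maximum weight; self hits are dropped;
#' hits above `evalue_max` are dropped.
#'
#' @param hits an `hsp_records` data.frame.
#' @param species_map named character vector gene id -> species id (may
#'   cover more genes than appear in hits; genes in hits but not in the map
#'   are carried with species `NA`).
#' @param evalue_max inclusion threshold; default 1e-5.
#' @param evalue_cap floor for e-values before taking `-log10`; default
#'   1e-200 (weight cap 200).
#' @return object of class `similarity_graph`: list with `nodes`
#'   (data.frame id, species) and `edges` (data.frame from, to, weight with
#'   `from < to` lexicographically).
#' @export
build_similarity_graph <- function(hits, species_map = NULL,
                                   evalue_max = 1e-5, evalue_cap = 1e-200) {
  h <- hits[hits$evalue <= evalue_max & hits$query_id != hits$subject_id, ,
            drop = FALSE]
  ids <- sort(unique(c(hits$query_id, hits$subject_id, names(species_map))))
  if (nrow(h)) {
    w <- -log10(pmax(h$evalue, evalue_cap))
    a <- pmin(h$query_id, h$subject_id)
    b <- pmax(h$query_id, h$subject_id)
    agg <- tapply(w, paste(a, b, sep = "\r"), max)
    pair <- strsplit(names(agg), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(pair, `[`, "", 1),
                        to = vapply(pair, `[`, "", 2),
                        weight = as.numeric(agg),
                        stringsAsFactors = FALSE, row.names = NULL)
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  species <- if (is.null(species_map)) rep(NA_character_, length(ids))
             else unname(species_map[ids])
  structure(list(nodes = data.frame(id = ids, species = species,
                                    stringsAsFactors = FALSE),
                 edges = edges),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("Similarity graph: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Markov clustering of a similarity graph
#'
#' Standard MCL: the weighted adjacency matrix gets self loops (each node's
#' maximum incident weight, 1 for isolated nodes), is column-normalized,
#' then expansion (matrix squaring) and inflation (elementwise power,
#' renormalize) alternate, pruning entries below `prune`, until the matrix
#' changes by less than `tol` or `max_iter` is reached (with a warning).
#' Clusters are the attractor sets: rows with positive diagonal mass seed a
#' cluster containing every node with flow into them; overlapping attractor
#' sets are merged. Output is independent of node order (nodes are processed
#' in lexicographic id order).
#'
#' @param graph a `similarity_graph`.
#' @param inflation inflation exponent (> 1); larger values give finer
#'   clusters.
#' @param max_iter maximum expansion/inflation iterations.
#' @param prune matrix entries below this are zeroed each iteration.
#' @param tol convergence threshold on the max absolute entry change.
#' @return an [ortho_group_set]; cluster ids `CL0001...` ordered by each
#'   cluster's lexicographically smallest member.
#' @export
mcl_cluster <- function(graph, inflation = 1.5, max_iter = 100L,
                        prune = 1e-5, tol = 1e-8) {
  if (inflation <= 1) stop_param("'inflation' must be > 1")
  ids <- sort(graph$nodes$id)
  n <- length(ids)
  if (n == 0) return(ortho_group_set(setNames(list(), character())))
  i <- match(graph$edges$from, ids)
  j <- match(graph$edges$to, ids)
  w <- graph$edges$weight
  loops <- rep(1, n)
  if (length(w)) {
    mx <- tapply(c(w, w), c(i, j), max)
    loops[as.integer(names(mx))] <- mx
  }
  A <- Matrix::sparseMatrix(i = c(i, j, seq_len(n)),
                            j = c(j, i, seq_len(n)),
                            x = c(w, w, loops), dims = c(n, n))
  M <- normalize_columns(A)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Mprev <- M
    M <- M %*% M                                   # expansion
    M <- methods::as(M, "CsparseMatrix")
    M@x <- M@x^inflation                           # inflation
    M@x[M@x < prune] <- 0
    M <- normalize_columns(Matrix::drop0(M))
    if (max(abs(M - Mprev)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("MCL did not converge in %d iterations; returning current clustering",
                    max_iter), call. = FALSE)
  attractors <- which(Matrix::diag(M) > prune)
  member_sets <- lapply(attractors, function(a) which(M[a, ] > prune))
  # merge overlapping attractor sets
  assign <- integer(n)
  next_cl <- 0L
  for (s in member_sets) {
    hit <- unique(assign[s])
    hit <- hit[hit != 0L]
    if (length(hit) == 0L) {
      next_cl <- next_cl + 1L
      assign[s] <- next_cl
    } else {
      keep <- min(hit)
      assign[s] <- keep
      assign[assign %in% setdiff(hit, keep)] <- keep
    }
  }
  for (v in which(assign == 0L)) {               # stray nodes: follow flow
    flow <- M[, v]
    flow[v] <- 0
    tgt <- which(flow > 0)
    if (length(tgt) && any(assign[tgt] > 0L)) {
      tgt <- tgt[assign[tgt] > 0L]
      assign[v] <- assign[tgt[which.max(flow[tgt])]]
    } else {
      next_cl <- next_cl + 1L
      assign[v] <- next_cl
    }
  }
  species <- setNames(graph$nodes$species, graph$nodes$id)[ids]
  species[is.na(species)] <- "unknown"
  clusters <- split(ids, assign)
  clusters <- clusters[order(vapply(clusters, min, ""))]
  names(clusters) <- sprintf("CL%04d", seq_along(clusters))
  ortho_group_set(lapply(clusters, function(g)
    lapply(split(g, species[g]), unname)))
}

normalize_columns <- function(M) {
  cs <- Matrix::colSums(M)
  zero <- cs == 0
  if (any(zero)) {                     # fully pruned column: reset to self
    M <- M + Matrix::sparseMatrix(i = which(zero), j = which(zero),
                                  x = 1, dims = dim(M))
    cs[zero] <- 1
  }
  methods::as(M %*% Matrix::Diagonal(x = 1 / cs), "CsparseMatrix")
}

#' Select lineage-specific orthologue clusters
#'
#' Keeps groups with at least one member gene from every target species and
#' no member from any outgroup species — the construction of a
#' lineage-unique cluster set from a full clustering.
#'
#' @param groups an [ortho_group_set].
#' @param target_species species that must all be represented.
#' @param outgroup_species species that must be absent; disjoint from
#'   targets.
#' @return the selected [ortho_group_set] subset.
#' @export
select_lineage_specific <- function(groups, target_species,
                                    outgroup_species = character()) {
  if (!length(target_species)) stop_param("'target_species' must be non-empty")
  if (length(intersect(target_species, outgroup_species)))
    stop_param("target and outgroup species overlap: %s",
               paste(intersect(target_species, outgroup_species),
                     collapse = ", "))
  keep <- vapply(groups, function(g) {
    present <- names(g)[lengths(g) > 0]
    all(target_species %in% present) &&
      !any(outgroup_species %in% present)
  }, TRUE)
  ortho_group_set(unclass(groups)[keep])
}
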