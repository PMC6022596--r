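#' CDS catalogue constructor
#'
#' A `cds_catalog` maps species to named coding sequences. Gene identifiers
#' must be unique within a species; the pipeline additionally requires them
#' to be unique across the whole catalogue so that alignment subject ids
#' resolve unambiguously.
#'
#' @param species named list; each element a named character vector of
#'   sequences (names are gene ids).
#' @param ancestors optional named character vector of ancestral sequences
#'   per orthologue group (kept by the synthetic generator so a query genome
#'   can be planted from the same ancestors).
#' @return an object of class `cds_catalog`.
#' @export
cds_catalog <- function(species, ancestors = NULL) {
  if (!is.list(species) || is.null(names(species)) || any(names(species) == ""))
    stop_param("'species' must be a named list of named sequence vectors")
  for (sp in names(species)) {
    g <- species[[sp]]
    if (length(g) && (is.null(names(g)) || anyDuplicated(names(g))))
      stop_param("gene ids must be present and unique within species '%s'", sp)
    if (any(nchar(g) == 0))
      stop_param("zero-length sequence in species '%s'", sp)
  }
  all_ids <- unlist(lapply(species, names), use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop_param("gene ids must be unique across the catalogue (duplicated: %s)",
               paste(unique(all_ids[duplicated(all_ids)])[1:3], collapse = ", "))
  structure(list(species = species, ancestors = ancestors),
            class = "cds_catalog")
}

#' @export
print.cds_catalog <- function(x, ...) {
  n <- vapply(x$species, length, 0L)
  cat(sprintf("CDS catalogue: %d species, %d genes (%s)\n",
              length(n), sum(n),
              paste(sprintf("%s:%d", names(n), n), collapse = ", ")))
  invisible(x)
}

# flatten to a single named vector of sequences + species lookup
catalog_flat <- function(catalog) {
  seqs <- unlist(catalog$species, use.names = FALSE)
  ids <- unlist(lapply(catalog$species, names), use.names = FALSE)
  sp <- rep(names(catalog$species), vapply(catalog$species, length, 0L))
  list(seq = setNames(seqs, ids), species = setNames(sp, ids))
}

#' Orthologue group set constructor
#'
#' Maps group id to species to member gene ids. Groups may lack some species
#' (lineage-specific clusters); empty groups are disallowed and a gene may
#' belong to at most one group.
#'
#' @param groups named list: group id -> named list (species -> character
#'   vector of gene ids).
#' @return an object of class `ortho_group_set`.
#' @export
ortho_group_set <- function(groups) {
  if (!is.list(groups) || (length(groups) && is.null(names(groups))))
    stop_param("'groups' must be a named list")
  sizes <- vapply(groups, function(g) length(unlist(g, use.names = FALSE)), 0L)
  if (any(sizes == 0L))
    stop_param("empty orthologue group(s): %s",
               paste(head(names(groups)[sizes == 0L], 3), collapse = ", "))
  genes <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(genes))
    stop_param("gene(s) assigned to more than one group: %s",
               paste(unique(genes[duplicated(genes)])[1:3], collapse = ", "))
  structure(groups, class = "ortho_group_set")
}

#' @export
print.ortho_group_set <- function(x, ...) {
  cat(sprintf("Orthologue group set: %d groups, %d genes\n",
              length(x), length(unlist(x, use.names = FALSE))))
  invisible(x)
}

#' Multiple sequence alignment with a foreground/background partition
#'
#' @param sequences named character vector of aligned sequences (amino-acid
#'   alphabet plus the gap character `-`); all the same length.
#' @param foreground,background disjoint subsets of the taxon names. Taxa in
#'   neither set are carried but ignored by the convergence scan.
#' @return an object of class `msa`.
#' @export
msa <- function(sequences, foreground = character(), background = character()) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop_param("alignment rows must carry unique taxon names")
  L <- unique(nchar(sequences))
  if (length(L) > 1)
    stop_param("ragged alignment: row lengths %s", paste(L, collapse = ", "))
  taxa <- names(sequences)
  if (length(intersect(foreground, background)))
    stop_param("foreground and background overlap: %s",
               paste(intersect(foreground, background), collapse = ", "))
  missing <- setdiff(c(foreground, background), taxa)
  if (length(missing))
    stop_param("partition names absent from alignment: %s",
               paste(missing, collapse = ", "))
  structure(list(sequences = sequences, foreground = foreground,
                 background = background, length = L %||% 0L),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("MSA: %d taxa x %d columns (%d foreground, %d background)\n",
              length(x$sequences), x$length,
              length(x$foreground), length(x$background)))
  invisible(x)
}

#' Ground-truth record for synthetic data
#'
#' Every synthetic generator records what it planted so recovery can be
#' scored exactly: per-group presence status, the divergences used, planted
#' convergent alignment columns, and planted enriched terms.
#'
#' @param ... fields to set (`group_status`, `query_divergence`,
#'   `read_error_rate`, `seed`, `planted_columns`, `enriched_terms`).
#' @return an object of class `sim_truth`.
#' @export
sim_truth <- function(...) {
  x <- list(group_status = NULL, query_divergence = NULL,
            read_error_rate = NULL, seed = NULL,
            planted_columns = NULL, enriched_terms = NULL)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(x))
  if (length(unknown))
    stop_param("unknown sim_truth field(s): %s", paste(unknown, collapse = ", "))
  x[names(dots)] <- dots
  structure(x, class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Synthetic ground truth\n")
  if (!is.null(x$group_status))
    cat(sprintf("  groups: %d (%d LOST, %d PRESENT)\n",
                length(x$group_status), sum(x$group_status == "LOST"),
                sum(x$group_status == "PRESENT")))
  if (!is.null(x$planted_columns))
    cat(sprintf("  planted MSA columns: %s\n",
                paste(x$planted_columns, collapse = ", ")))
  if (!is.null(x$enriched_terms) && length(x$enriched_terms))
    cat(sprintf("  enriched terms: %s\n",
                paste(names(x$enriched_terms), collapse = ", ")))
  if (!is.null(x$seed)) cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
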