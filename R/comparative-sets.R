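# Cross-species comparison of presence/absence calls: merge computed and
# imported statuses into a matrix, count Venn-style sharing categories for
# a focal species against two others, and compare protein domain sets.

#' Build a presence/absence status matrix across species
#'
#' Combines statuses computed by this pipeline (for the focal species) with
#' imported statuses for other species into one rectangular group x species
#' matrix. Missing cells become `NO_DATA`; duplicated (group, species)
#' entries must agree or an error is raised.
#'
#' @param computed data.frame from [classify_pav] (columns `group_id`,
#'   `status`), or `NULL`.
#' @param focal_species species name for the computed statuses.
#' @param imported data.frame with columns `group_id`, `species`, `status`
#'   (see [read_status_tsv]), or `NULL`.
#' @param species_order character vector fixing the column order; defaults
#'   to focal species followed by imported species in order of appearance.
#' @return character matrix of class `pav_matrix` (rows = groups, columns =
#'   species).
#' @export
build_pav_matrix <- function(computed = NULL, focal_species = NULL,
                             imported = NULL, species_order = NULL) {
  long <- list()
  if (!is.null(computed)) {
    if (is.null(focal_species))
      stop_param("'focal_species' required with computed statuses")
    long[[1]] <- data.frame(group_id = computed$group_id,
                            species = focal_species,
                            status = computed$status,
                            stringsAsFactors = FALSE)
  }
  if (!is.null(imported))
    long[[length(long) + 1L]] <- imported[c("group_id", "species", "status")]
  if (!length(long)) stop_param("no statuses supplied")
  d <- do.call(rbind, long)
  bad <- setdiff(unique(d$status), PAV_STATUSES)
  if (length(bad))
    stop_param("unknown status label(s): %s", paste(bad, collapse = ", "))
  key <- paste(d$group_id, d$species, sep = "\r")
  if (anyDuplicated(key)) {
    per <- tapply(d$status, key, function(s) length(unique(s)))
    if (any(per > 1))
      stop_param("conflicting duplicate statuses for: %s",
                 paste(head(sub("\r", "/", names(per)[per > 1]), 3),
                       collapse = ", "))
    d <- d[!duplicated(key), , drop = FALSE]
  }
  species <- species_order %||% unique(d$species)
  extra <- setdiff(unique(d$species), species)
  if (length(extra))
    stop_param("species absent from 'species_order': %s",
               paste(extra, collapse = ", "))
  groups <- unique(d$group_id)
  m <- matrix("NO_DATA", nrow = length(groups), ncol = length(species),
              dimnames = list(groups, species))
  m[cbind(match(d$group_id, groups), match(d$species, species))] <- d$status
  class(m) <- c("pav_matrix", class(m))
  m
}

#' @export
print.pav_matrix <- function(x, ...) {
  cat(sprintf("PAV matrix: %d groups x %d species\n", nrow(x), ncol(x)))
  tab <- table(factor(x, levels = PAV_STATUSES))
  cat(paste(sprintf("  %s: %d", names(tab), tab), collapse = "\n"), "\n")
  invisible(x)
}

#' Venn-style sharing categories for a focal species against two others
#'
#' For the rows where the focal species holds `status_of_interest`
#' (`focal_total`), counts how the two other species share it:
#' `shared_all` (both match), `shared_with_exactly_one` (one matches and
#' the other holds the *opposite definite* status — LOST vs CONSERVED),
#' `focal_unique` (both hold the opposite definite status), and
#' `others_only` (rows where the focal species holds the opposite definite
#' status and both others hold `status_of_interest`). Rows where a
#' non-focal cell is `NO_DATA` or `INDETERMINATE` count toward
#' `focal_total` only; `unresolved` reports how many such rows there are,
#' so the three sharing categories need not sum to `focal_total`.
#'
#' @param matrix a `pav_matrix`.
#' @param focal focal species name.
#' @param others character vector of exactly two other species.
#' @param status_of_interest `"CONSERVED"` or `"LOST"`.
#' @return list of class `venn_counts`.
#' @export
venn_categories <- function(matrix, focal, others,
                            status_of_interest = c("CONSERVED", "LOST")) {
  status_of_interest <- match.arg(status_of_interest)
  if (length(others) != 2L) stop_param("'others' must name exactly 2 species")
  if (focal %in% others) stop_param("'focal' cannot be one of 'others'")
  missing <- setdiff(c(focal, others), colnames(matrix))
  if (length(missing))
    stop_param("unknown species: %s", paste(missing, collapse = ", "))
  opposite <- if (status_of_interest == "CONSERVED") "LOST" else "CONSERVED"
  f <- matrix[, focal]
  o1 <- matrix[, others[1]]
  o2 <- matrix[, others[2]]
  in_focal <- f == status_of_interest
  n_match <- (o1 == status_of_interest) + (o2 == status_of_interest)
  n_opp <- (o1 == opposite) + (o2 == opposite)
  definite <- n_match + n_opp == 2L
  counts <- list(
    focal_total = sum(in_focal),
    shared_all = sum(in_focal & n_match == 2L),
    shared_with_exactly_one = sum(in_focal & definite & n_match == 1L),
    focal_unique = sum(in_focal & n_opp == 2L),
    others_only = sum(f == opposite & n_match == 2L),
    unresolved = sum(in_focal & !definite & n_match < 2L))
  structure(c(counts, list(focal = focal, others = others,
                           status = status_of_interest)),
            class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat(sprintf("%s genes in %s: %d total\n", x$status, x$focal, x$focal_total))
  cat(sprintf("  shared with both %s and %s: %d\n",
              x$others[1], x$others[2], x$shared_all))
  cat(sprintf("  shared with exactly one: %d\n", x$shared_with_exactly_one))
  cat(sprintf("  unique to %s: %d\n", x$focal_unique))
  cat(sprintf("  %s in both others only: %d\n", x$status, x$others_only))
  if (x$unresolved > 0)
    cat(sprintf("  unresolved (NO_DATA/INDETERMINATE in a non-focal species): %d\n",
                x$unresolved))
  invisible(x)
}

#' Compare two protein-domain identifier sets
#'
#' `IDENTICAL` when the sets are equal and non-empty, `NO_DOMAINS` when the
#' focal set is empty, `DIFFERENT` otherwise (fewer, extra or different
#' domains).
#'
#' @param focal_domains,reference_domains character vectors of opaque
#'   domain identifiers.
#' @return one of `"IDENTICAL"`, `"DIFFERENT"`, `"NO_DOMAINS"`.
#' @export
compare_domain_sets <- function(focal_domains, reference_domains) {
  focal <- unique(focal_domains)
  ref <- unique(reference_domains)
  if (length(focal) == 0) return("NO_DOMAINS")
  if (setequal(focal, ref)) "IDENTICAL" else "DIFFERENT"
}
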