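# Horizontal (breadth) coverage and lost/conserved classification.
#
# Breadth is the fraction of a CDS covered by at least one mapped read: the
# size of the union of hit subject intervals divided by the CDS length.
# Per-group coverage is averaged across reference species, and a group is
# called LOST when the mean breadth is < 2%, CONSERVED when > 50%, and
# INDETERMINATE in between (ties at the thresholds included: the bounds are
# strict on both sides).

#' Size of the union of 1-based inclusive intervals
#'
#' Intervals are clipped to `[1, cds_length]`; order and duplication do not
#' affect the result.
#'
#' @param intervals two-column matrix or data.frame (start, end), or a list
#'   of length-2 vectors; 1-based inclusive.
#' @param cds_length sequence length in bp (>= 0).
#' @return number of covered bases.
#' @export
union_covered_bases <- function(intervals, cds_length) {
  if (length(cds_length) != 1L || is.na(cds_length) || cds_length < 0)
    stop_param("'cds_length' must be a single non-negative number")
  if (is.list(intervals) && !is.data.frame(intervals))
    intervals <- do.call(rbind, intervals)
  if (is.null(intervals) || NROW(intervals) == 0L) return(0L)
  intervals <- as.matrix(intervals)
  s <- pmax(as.integer(intervals[, 1]), 1L)
  e <- pmin(as.integer(intervals[, 2]), as.integer(cds_length))
  keep <- s <= e
  if (!any(keep)) return(0L)
  s <- s[keep]; e <- e[keep]
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  cm <- cummax(e)
  new_run <- c(TRUE, s[-1] > head(cm, -1) + 1L)
  run_start <- s[new_run]
  run_last <- c(which(new_run)[-1] - 1L, length(s))
  sum(cm[run_last] - run_start + 1L)
}

#' Horizontal coverage of every catalogue CDS from alignment hits
#'
#' One record per CDS, including zero-coverage records for CDSs without
#' hits. Hits whose subject id is not in the catalogue are an error.
#'
#' @param hits an `hsp_records` data.frame (see [read_tabular_hits]).
#' @param catalog a [cds_catalog].
#' @return data.frame with columns `species_id`, `gene_id`, `covered_bases`,
#'   `cds_length`, `horizontal_coverage` (percent).
#' @export
horizontal_coverage <- function(hits, catalog) {
  flat <- catalog_flat(catalog)
  lens <- nchar(flat$seq)
  unknown <- setdiff(unique(hits$subject_id), names(flat$seq))
  if (length(unknown))
    stop_param("hit(s) to unknown subject(s): %s",
               paste(head(unknown, 5), collapse = ", "))
  covered <- setNames(integer(length(flat$seq)), names(flat$seq))
  if (NROW(hits)) {
    by_gene <- split(seq_len(nrow(hits)), hits$subject_id)
    for (gid in names(by_gene)) {
      idx <- by_gene[[gid]]
      covered[gid] <- union_covered_bases(
        cbind(hits$s_start[idx], hits$s_end[idx]), lens[gid])
    }
  }
  data.frame(species_id = unname(flat$species),
             gene_id = names(flat$seq),
             covered_bases = unname(covered),
             cds_length = unname(lens),
             horizontal_coverage = unname(100 * covered / lens),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean horizontal coverage per orthologue group
#'
#' Within a species, a group's value is the mean breadth over that species'
#' member genes (groups are single-copy per species in the usual panel, so
#' this is usually the single member's value). The group mean is taken over
#' species, either excluding species without a member (`na_species =
#' "exclude"`, the default) or counting them as zero coverage
#' (`na_species = "zero"`).
#'
#' @param records coverage records from [horizontal_coverage].
#' @param groups an [ortho_group_set].
#' @param na_species how to treat species with no member gene for a group.
#' @return data.frame with `group_id`, one `cov.<species>` column per
#'   species (NA when the species has no member), and `mean_coverage`.
#' @export
group_mean_coverage <- function(records, groups,
                                na_species = c("exclude", "zero")) {
  na_species <- match.arg(na_species)
  if (!length(groups)) stop_param("'groups' is empty")
  cov_by_gene <- setNames(records$horizontal_coverage, records$gene_id)
  species <- sort(unique(records$species_id))
  per_sp <- matrix(NA_real_, nrow = length(groups), ncol = length(species),
                   dimnames = list(names(groups), species))
  for (gid in names(groups)) {
    members <- groups[[gid]]
    if (!length(unlist(members, use.names = FALSE)))
      stop_param("group '%s' has no members", gid)
    for (sp in names(members)) {
      vals <- cov_by_gene[members[[sp]]]
      vals <- vals[!is.na(vals)]
      if (length(vals) && sp %in% species)
        per_sp[gid, sp] <- mean(vals)
    }
  }
  if (na_species == "zero") per_sp[is.na(per_sp)] <- 0
  means <- rowMeans(per_sp, na.rm = TRUE)
  means[is.nan(means)] <- NA_real_
  out <- data.frame(group_id = names(groups), stringsAsFactors = FALSE,
                    row.names = NULL)
  for (sp in species) out[[paste0("cov.", sp)]] <- unname(per_sp[, sp])
  out$mean_coverage <- unname(means)
  out
}

#' Classify orthologue groups as lost, conserved or indeterminate
#'
#' Strict thresholds: LOST when mean coverage < `lost_max`, CONSERVED when
#' > `conserved_min`, INDETERMINATE when in `[lost_max, conserved_min]`
#' (including exact ties), NO_DATA when no species contributed a value.
#'
#' @param group_cov output of [group_mean_coverage] (needs `group_id` and
#'   `mean_coverage`).
#' @param lost_max upper (exclusive) mean-coverage bound for LOST, percent.
#' @param conserved_min lower (exclusive) bound for CONSERVED, percent.
#' @return data.frame with `group_id`, `mean_coverage`, `status`.
#' @export
classify_pav <- function(group_cov, lost_max = 2, conserved_min = 50) {
  if (!(lost_max >= 0 && lost_max < conserved_min && conserved_min <= 100))
    stop_param("need 0 <= lost_max < conserved_min <= 100 (got %s, %s)",
               format(lost_max), format(conserved_min))
  m <- group_cov$mean_coverage
  status <- ifelse(is.na(m), "NO_DATA",
            ifelse(m < lost_max, "LOST",
            ifelse(m > conserved_min, "CONSERVED", "INDETERMINATE")))
  data.frame(group_id = group_cov$group_id, mean_coverage = m,
             status = status, stringsAsFactors = FALSE, row.names = NULL)
}
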