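# Detection of convergent lineage-specific substitutions: alignment columns
# where every foreground taxon shares one residue that differs from a
# residue conserved across the background taxa.

#' Scan an alignment for convergent foreground-specific columns
#'
#' A column is called when (a) the background has a strict-majority
#' consensus residue present in at least `bg_conservation_min` of the
#' background taxa (a tied majority means no consensus and the column is
#' never called), (b) all foreground taxa share one residue (when
#' `fg_unanimity`; otherwise a strict-majority foreground consensus is
#' used), (c) the foreground residue differs from the background consensus,
#' and (d) gaps are handled per `allow_gaps`: when `FALSE` any gap in a
#' partitioned taxon rejects the column, when `TRUE` gapped taxa are
#' excluded from the fractions (at least one ungapped taxon must remain on
#' each side). Columns are numbered in original alignment coordinates.
#'
#' @param msa an [msa] with non-empty foreground and background sets.
#' @param bg_conservation_min minimum fraction of (ungapped) background taxa
#'   carrying the consensus residue; default 1.0 (full conservation).
#' @param fg_unanimity require all foreground taxa to agree? Default `TRUE`.
#' @param allow_gaps exclude gapped taxa instead of rejecting the column?
#' @return data.frame of class `convergent_sites` with columns `column`
#'   (1-based), `background_residue`, `foreground_residue`,
#'   `background_conservation`.
#' @export
scan_convergent_columns <- function(msa, bg_conservation_min = 1.0,
                                    fg_unanimity = TRUE, allow_gaps = FALSE) {
  if (!length(msa$foreground) || !length(msa$background))
    stop_param("both foreground and background taxa are required")
  check_fraction(bg_conservation_min, "bg_conservation_min")
  m <- msa_matrix(msa)
  fg <- m[msa$foreground, , drop = FALSE]
  bg <- m[msa$background, , drop = FALSE]
  out <- list()
  for (col in seq_len(msa$length)) {
    fg_res <- fg[, col]
    bg_res <- bg[, col]
    if (!allow_gaps && any(c(fg_res, bg_res) == "-")) next
    fg_res <- fg_res[fg_res != "-"]
    bg_res <- bg_res[bg_res != "-"]
    if (!length(fg_res) || !length(bg_res)) next
    # (a) strict-majority background consensus above the threshold
    tab <- table(bg_res)
    top <- max(tab)
    if (sum(tab == top) != 1L) next                     # tie: no consensus
    consensus <- names(tab)[which.max(tab)]
    conservation <- top / length(bg_res)
    if (conservation < bg_conservation_min) next
    # (b) foreground agreement
    if (fg_unanimity) {
      if (length(unique(fg_res)) != 1L) next
      fg_call <- fg_res[1]
    } else {
      ftab <- table(fg_res)
      ftop <- max(ftab)
      if (sum(ftab == ftop) != 1L) next
      fg_call <- names(ftab)[which.max(ftab)]
    }
    # (c) foreground differs from background consensus
    if (fg_call == consensus) next
    out[[length(out) + 1L]] <- data.frame(
      column = col, background_residue = consensus,
      foreground_residue = fg_call,
      background_conservation = unname(conservation),
      stringsAsFactors = FALSE)
  }
  sites <- if (length(out)) do.call(rbind, out) else
    data.frame(column = integer(), background_residue = character(),
               foreground_residue = character(),
               background_conservation = numeric(),
               stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  class(sites) <- c("convergent_sites", "data.frame")
  sites
}

msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$sequences, "", fixed = TRUE))
  rownames(m) <- names(msa$sequences)
  m
}

#' Tabular report of convergent sites with per-taxon residues
#'
#' One row per called site carrying the scan's summary columns plus the
#' residue of every alignment taxon at that column; round-trips through
#' TSV via [utils::write.table]/[utils::read.delim].
#'
#' @param sites output of [scan_convergent_columns].
#' @param msa the [msa] the sites were called from.
#' @return data.frame with one `res.<taxon>` column per taxon.
#' @export
column_report <- function(sites, msa) {
  if (NROW(sites) && max(sites$column) > msa$length)
    stop_param("site column %d exceeds alignment length %d",
               max(sites$column), msa$length)
  m <- msa_matrix(msa)
  rep_df <- as.data.frame(sites)[, c("column", "background_residue",
                                     "foreground_residue",
                                     "background_conservation")]
  for (taxon in rownames(m))
    rep_df[[paste0("res.", taxon)]] <-
      if (NROW(sites)) m[taxon, sites$column] else character()
  rep_df
}
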