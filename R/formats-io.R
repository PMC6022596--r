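# Readers/writers for the external formats the pipeline touches, plus a
# naive exact-seed read mapper usable where an external aligner's tabular
# output is not available. Coordinates are 1-based inclusive throughout.

HIT_COLUMNS <- c("query_id", "subject_id", "pct_identity", "aln_length",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bit_score")

#' Read 12-column tabular alignment hits
#'
#' Parses the standard 12-column tabular hit format (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore),
#' excludes hits with e-value above `evalue_max`, and strand-normalizes
#' subject coordinates: records with `s_start > s_end` are swapped and
#' flagged `strand = "-"`. Input order is preserved.
#'
#' @param path file path.
#' @param evalue_max e-value inclusion threshold (hits with larger e-value
#'   are dropped); default 1e-5.
#' @return data.frame of class `hsp_records` with the 12 standard columns
#'   plus `strand`.
#' @export
read_tabular_hits <- function(path, evalue_max = 1e-5) {
  if (!file.exists(path)) stop_param("hit file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad))
    stop_param("line %d: expected 12 tab-separated columns, found %d",
               bad[1], length(fields[[bad[1]]]))
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num_cols <- 3:12
  nums <- suppressWarnings(apply(m[, num_cols, drop = FALSE], 2, as.numeric))
  nums <- matrix(nums, ncol = length(num_cols))
  if (anyNA(nums)) {
    bad <- which(rowSums(is.na(nums)) > 0)[1]
    stop_param("line %d: unparsable numeric field", bad)
  }
  h <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                  stringsAsFactors = FALSE)
  h[HIT_COLUMNS[3:12]] <- as.data.frame(nums)
  int_cols <- c("aln_length", "mismatches", "gap_opens",
                "q_start", "q_end", "s_start", "s_end")
  h[int_cols] <- lapply(h[int_cols], as.integer)
  h$strand <- ifelse(h$s_start <= h$s_end, "+", "-")
  flip <- h$strand == "-"
  if (any(flip)) {
    tmp <- h$s_start[flip]
    h$s_start[flip] <- h$s_end[flip]
    h$s_end[flip] <- tmp
  }
  h <- h[h$evalue <= evalue_max, , drop = FALSE]
  rownames(h) <- NULL
  class(h) <- c("hsp_records", "data.frame")
  h
}

empty_hits <- function() {
  h <- data.frame(query_id = character(), subject_id = character(),
                  pct_identity = numeric(), aln_length = integer(),
                  mismatches = integer(), gap_opens = integer(),
                  q_start = integer(), q_end = integer(),
                  s_start = integer(), s_end = integer(),
                  evalue = numeric(), bit_score = numeric(),
                  strand = character(), stringsAsFactors = FALSE)
  class(h) <- c("hsp_records", "data.frame")
  h
}

#' Write hits in the 12-column tabular format
#'
#' Inverse of [read_tabular_hits]: minus-strand hits are written with their
#' original (descending) subject coordinates so that read/write round-trips.
#'
#' @param hits an `hsp_records` data.frame.
#' @param path output path.
#' @export
write_tabular_hits <- function(hits, path) {
  out <- hits[, HIT_COLUMNS, drop = FALSE]
  flip <- hits$strand == "-"
  if (any(flip)) {
    tmp <- out$s_start[flip]
    out$s_start[flip] <- out$s_end[flip]
    out$s_end[flip] <- tmp
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Naive exact-seed read mapper
#'
#' A deliberately simple, fully specified mapper: exact k-mer seeding at
#' every read offset on both strands, ungapped full-read placement on each
#' seeded diagonal (the read must lie entirely within the subject), and a
#' hit is reported when the matched fraction of read bases reaches
#' `min_match_fraction`. Every passing (read, subject, offset, strand)
#' placement is reported once; the synthetic e-value is 0.
#'
#' @param reads a `read_pairs` object (mates are treated as independent
#'   reads named `<id>/1`, `<id>/2`) or a named character vector.
#' @param catalog a [cds_catalog].
#' @param k seed length (<= shortest read).
#' @param min_match_fraction minimum fraction of matching read bases.
#' @return an `hsp_records` data.frame (see [read_tabular_hits]).
#' @export
naive_map <- function(reads, catalog, k = 16L, min_match_fraction = 0.8) {
  if (!inherits(catalog, "cds_catalog") ||
      sum(lengths(catalog$species)) == 0)
    stop_param("'catalog' must be a non-empty cds_catalog")
  if (inherits(reads, "read_pairs")) {
    reads <- setNames(c(reads$seq1, reads$seq2),
                      c(paste0(reads$id, "/1"), paste0(reads$id, "/2")))
  }
  if (is.null(names(reads))) names(reads) <- sprintf("r%d", seq_along(reads))
  if (!length(reads)) return(empty_hits())
  if (k > min(nchar(reads)))
    stop_param("seed length k=%d exceeds shortest read (%d bp)",
               k, min(nchar(reads)))
  check_fraction(min_match_fraction, "min_match_fraction")

  flat <- catalog_flat(catalog)
  index <- kmer_index(flat$seq, k)

  hits_list <- list()
  for (L in sort(unique(nchar(reads)))) {
    rd <- reads[nchar(reads) == L]
    fwd <- find_placements(rd, "+", index, flat$seq, k, L)
    rev <- find_placements(setNames(reverse_complement(rd), names(rd)),
                           "-", index, flat$seq, k, L)
    cand <- rbind(fwd, rev)
    if (is.null(cand) || !nrow(cand)) next
    # ungapped extension: mismatch count over the full read at the diagonal
    qseq <- ifelse(cand$strand == "+", reads[cand$query_id],
                   reverse_complement(reads[cand$query_id]))
    sseq <- substring(flat$seq[cand$subject_id], cand$s_start,
                      cand$s_start + L - 1L)
    mm <- count_mismatches(qseq, sseq, L)
    keep <- (L - mm) / L >= min_match_fraction
    if (!any(keep)) next
    cand <- cand[keep, , drop = FALSE]
    mm <- mm[keep]
    cand$pct_identity <- round(100 * (L - mm) / L, 2)
    cand$aln_length <- L
    cand$mismatches <- mm
    cand$gap_opens <- 0L
    cand$q_start <- 1L
    cand$q_end <- L
    cand$s_end <- cand$s_start + L - 1L
    cand$evalue <- 0
    cand$bit_score <- 2 * (L - mm)
    hits_list[[as.character(L)]] <- cand
  }
  if (!length(hits_list)) return(empty_hits())
  h <- do.call(rbind, hits_list)
  h <- h[order(h$query_id, h$subject_id, h$s_start, h$strand), ]
  h <- h[, c(HIT_COLUMNS, "strand"), drop = FALSE]
  rownames(h) <- NULL
  class(h) <- c("hsp_records", "data.frame")
  h
}

kmer_index <- function(seqs, k) {
  per <- lapply(names(seqs), function(id) {
    L <- nchar(seqs[[id]])
    if (L < k) return(NULL)
    pos <- seq_len(L - k + 1L)
    data.table::data.table(kmer = substring(seqs[[id]], pos, pos + k - 1L),
                           subject_id = id, pos = pos)
  })
  idx <- data.table::rbindlist(per)
  data.table::setkey(idx, kmer)
  idx
}

# seeded candidate diagonals: every read k-mer joined against the subject
# k-mer index; a diagonal is kept only if the whole read fits the subject
find_placements <- function(reads, strand, index, subjects, k, L) {
  qpos <- seq_len(L - k + 1L)
  seeds <- data.table::data.table(
    query_id = rep(names(reads), each = length(qpos)),
    qpos = rep(qpos, times = length(reads)),
    kmer = as.vector(vapply(reads, function(s)
      substring(s, qpos, qpos + k - 1L), character(length(qpos)))))
  m <- index[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (!nrow(m)) return(NULL)
  m[, s_start := pos - qpos + 1L]
  m <- unique(m[, .(query_id, subject_id, s_start)])
  m <- m[s_start >= 1L & s_start + L - 1L <= nchar(subjects[subject_id])]
  if (!nrow(m)) return(NULL)
  out <- as.data.frame(m)
  out$strand <- strand
  out
}

# vectorized Hamming distance between equal-length string vectors
count_mismatches <- function(a, b, L) {
  if (!length(a)) return(integer())
  ra <- charToRaw(paste(a, collapse = ""))
  rb <- charToRaw(paste(b, collapse = ""))
  as.integer(colSums(matrix(ra != rb, nrow = L)))
}

#' Read / write FASTA
#'
#' Thin wrappers around Biostrings returning plain named character vectors.
#' Duplicate record ids are an error.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_param("FASTA file not found: %s", path)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop_param("duplicate FASTA ids: %s",
               paste(unique(ids[duplicated(ids)])[1:3], collapse = ", "))
  setNames(as.character(x), ids)
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write FASTQ
#'
#' Qualities are ignored on read and written as a constant placeholder
#' (`I`): the pipeline never consumes quality scores.
#'
#' @param path file path.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_param("FASTQ file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_fastq
#' @param reads a `read_pairs` object (written as `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`) or a named character vector (written to `path`).
#' @param prefix output prefix for paired files.
#' @export
write_fastq <- function(reads, path = NULL, prefix = NULL) {
  write_one <- function(seqs, ids, p) {
    x <- Biostrings::DNAStringSet(setNames(seqs, ids))
    Biostrings::writeXStringSet(
      x, p, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(seqs))))
    p
  }
  if (inherits(reads, "read_pairs")) {
    if (is.null(prefix)) stop_param("'prefix' required for paired reads")
    invisible(c(write_one(reads$seq1, paste0(reads$id, "/1"),
                          paste0(prefix, "_1.fastq")),
                write_one(reads$seq2, paste0(reads$id, "/2"),
                          paste0(prefix, "_2.fastq"))))
  } else {
    if (is.null(path)) stop_param("'path' required")
    invisible(write_one(unname(reads), names(reads), path))
  }
}

#' Read an aligned FASTA into an [msa]
#'
#' @param path aligned FASTA path.
#' @param foreground,background taxon partitions (see [msa]).
#' @param partition optional path to a two-column TSV (taxon, role) with
#'   roles `foreground`, `background` or `ignore`; overrides the vectors.
#' @return an [msa].
#' @export
read_msa_fasta <- function(path, foreground = character(),
                           background = character(), partition = NULL) {
  seqs <- read_fasta(path)
  if (!is.null(partition)) {
    p <- read.delim(partition, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(p) < 2) stop_param("partition file needs 2 columns (taxon, role)")
    bad <- setdiff(unique(p[[2]]), c("foreground", "background", "ignore"))
    if (length(bad))
      stop_param("unknown partition role(s): %s", paste(bad, collapse = ", "))
    foreground <- p[[1]][p[[2]] == "foreground"]
    background <- p[[1]][p[[2]] == "background"]
  }
  msa(seqs, foreground = foreground, background = background)
}

#' @rdname read_msa_fasta
#' @param x an [msa].
#' @export
write_msa_fasta <- function(x, path) {
  write_fasta(x$sequences, path)
}

#' Read / write a minimal OBO 1.2 ontology
#'
#' Supports the `[Term]` stanza fields `id`, `name`, `namespace` and `is_a`
#' (trailing `! comment` text is stripped). An `is_a` reference to an
#' undeclared term is an error.
#'
#' @param path OBO file path.
#' @return a [go_dag].
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop_param("OBO file not found: %s", path)
  lines <- trimws(readLines(path))
  in_term <- FALSE
  terms <- list()
  cur <- NULL
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(id = NULL, name = NA_character_,
                  namespace = NA_character_, is_a = character())
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      kv <- regmatches(ln, regexec("^([a-zA-Z_]+):\\s*(.*)$", ln))[[1]]
      if (length(kv) == 3) {
        val <- sub("\\s*!.*$", "", kv[3])
        switch(kv[2],
               id = cur$id <- val,
               name = cur$name <- val,
               namespace = cur$namespace <- val,
               is_a = cur$is_a <- c(cur$is_a, val))
      }
    }
  }
  terms <- flush(cur, terms)
  if (!length(terms)) stop_param("no [Term] stanzas in %s", path)
  terms_df <- data.frame(
    id = vapply(terms, `[[`, "", "id"),
    name = vapply(terms, `[[`, "", "name"),
    namespace = vapply(terms, `[[`, "", "namespace"),
    stringsAsFactors = FALSE, row.names = NULL)
  go_dag(terms_df, lapply(terms, `[[`, "is_a"))
}

#' @rdname read_obo
#' @param dag a [go_dag].
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    writeLines(c("", "[Term]", paste0("id: ", id)), con)
    if (!is.na(dag$terms$name[i]))
      writeLines(paste0("name: ", dag$terms$name[i]), con)
    if (!is.na(dag$terms$namespace[i]))
      writeLines(paste0("namespace: ", dag$terms$namespace[i]), con)
    for (p in dag$parents[[id]]) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Read / write gene-to-term annotations
#'
#' Two tab-separated columns: gene id, semicolon-joined term ids.
#'
#' @param path TSV path.
#' @return named list gene -> character vector of term ids.
#' @export
read_annotation_tsv <- function(path) {
  if (!file.exists(path)) stop_param("annotation file not found: %s", path)
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop_param("annotation TSV needs 2 columns (gene, terms)")
  if (anyDuplicated(d[[1]]))
    stop_param("duplicate gene id(s) in annotation: %s",
               paste(unique(d[[1]][duplicated(d[[1]])])[1:3], collapse = ", "))
  setNames(strsplit(d[[2]], ";", fixed = TRUE), d[[1]])
}

#' @rdname read_annotation_tsv
#' @param annotation named list gene -> term ids.
#' @export
write_annotation_tsv <- function(annotation, path) {
  d <- data.frame(gene = names(annotation),
                  terms = vapply(annotation, paste, "", collapse = ";"))
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write per-species presence/absence statuses
#'
#' Three tab-separated columns with header: `group_id`, `species`, `status`.
#' Admitted statuses: `LOST`, `CONSERVED`, `INDETERMINATE`, `NO_DATA`, `NA`
#' (read as `NO_DATA`).
#'
#' @param path TSV path.
#' @return data.frame with columns `group_id`, `species`, `status`.
#' @export
read_status_tsv <- function(path) {
  if (!file.exists(path)) stop_param("status file not found: %s", path)
  d <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL)
  need <- c("group_id", "species", "status")
  if (!all(need %in% names(d)))
    stop_param("status TSV must have columns: %s", paste(need, collapse = ", "))
  d$status[d$status %in% c("NA", "")] <- "NO_DATA"
  bad <- setdiff(unique(d$status), PAV_STATUSES)
  if (length(bad))
    stop_param("unknown status label(s): %s", paste(bad, collapse = ", "))
  d[need]
}

#' @rdname read_status_tsv
#' @param statuses data.frame with columns `group_id`, `species`, `status`.
#' @export
write_status_tsv <- function(statuses, path) {
  write.table(statuses[c("group_id", "species", "status")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write orthologue group membership tables
#'
#' Three tab-separated columns with header: `group_id`, `species`,
#' `gene_id`; one row per member gene.
#'
#' @param path TSV path.
#' @return an [ortho_group_set].
#' @export
read_groups_tsv <- function(path) {
  if (!file.exists(path)) stop_param("groups file not found: %s", path)
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("group_id", "species", "gene_id")
  if (!all(need %in% names(d)))
    stop_param("groups TSV must have columns: %s", paste(need, collapse = ", "))
  groups <- lapply(split(d, d$group_id), function(g)
    lapply(split(g$gene_id, g$species), unname))
  ortho_group_set(groups[unique(d$group_id)])
}

#' @rdname read_groups_tsv
#' @param groups an [ortho_group_set].
#' @export
write_groups_tsv <- function(groups, path) {
  rows <- lapply(names(groups), function(gid) {
    sp <- rep(names(groups[[gid]]), lengths(groups[[gid]]))
    data.frame(group_id = gid, species = sp,
               gene_id = unlist(groups[[gid]], use.names = FALSE))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Percentage of reads aligned, rounded half-up to one decimal
#'
#' A read counts once however many hits it has; callers must pass distinct
#' aligned-read counts, not hit counts.
#'
#' @param n_aligned_reads number of reads with at least one hit.
#' @param n_total_reads total number of reads (> 0).
#' @return percentage with one decimal place.
#' @export
aligned_read_fraction <- function(n_aligned_reads, n_total_reads) {
  if (n_total_reads <= 0) stop_param("'n_total_reads' must be > 0")
  if (n_aligned_reads < 0 || n_aligned_reads > n_total_reads)
    stop_param("need 0 <= n_aligned_reads <= n_total_reads")
  round_half_up(100 * n_aligned_reads / n_total_reads, 1)
}
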