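# Independent brute-force oracles and small fixture builders. Oracles here
# deliberately share no code with the implementation paths they check.

# per-base bitmap count of covered positions
bitmap_union <- function(intervals, len) {
  bits <- logical(len)
  for (i in seq_len(NROW(intervals))) {
    s <- max(1L, intervals[i, 1])
    e <- min(len, intervals[i, 2])
    if (s <= e) bits[s:e] <- TRUE
  }
  sum(bits)
}

# all-offsets ungapped Hamming scan on both strands, full containment
brute_force_map <- function(reads, catalog, min_match_fraction) {
  flat <- pavcomp:::catalog_flat(catalog)
  out <- list()
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (rid in names(reads)) {
    for (strand in c("+", "-")) {
      rd <- if (strand == "+") reads[[rid]] else rc(reads[[rid]])
      rv <- strsplit(rd, "")[[1]]
      L <- length(rv)
      for (sid in names(flat$seq)) {
        sv <- strsplit(flat$seq[[sid]], "")[[1]]
        if (length(sv) < L) next
        for (off in 0:(length(sv) - L)) {
          matches <- sum(rv == sv[(off + 1):(off + L)])
          if (matches / L >= min_match_fraction)
            out[[length(out) + 1L]] <- data.frame(
              query_id = rid, subject_id = sid,
              s_start = off + 1L, s_end = off + L, strand = strand,
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(data.frame(query_id = character(),
                                      subject_id = character(),
                                      s_start = integer(), s_end = integer(),
                                      strand = character()))
  do.call(rbind, out)
}

hit_key <- function(h) {
  sort(paste(h$query_id, h$subject_id, h$s_start, h$s_end, h$strand))
}

# direct summation of the hypergeometric upper tail
hyper_tail_sum <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# per-row exhaustive classification of Venn sharing categories
venn_brute <- function(m, focal, others, status) {
  opp <- if (status == "CONSERVED") "LOST" else "CONSERVED"
  res <- c(focal_total = 0, shared_all = 0, shared_with_exactly_one = 0,
           focal_unique = 0, others_only = 0, unresolved = 0)
  for (r in seq_len(nrow(m))) {
    f <- m[r, focal]; a <- m[r, others[1]]; b <- m[r, others[2]]
    if (f == opp && a == status && b == status)
      res["others_only"] <- res["others_only"] + 1
    if (f != status) next
    res["focal_total"] <- res["focal_total"] + 1
    if (a == status && b == status)
      res["shared_all"] <- res["shared_all"] + 1
    else if ((a == status && b == opp) || (a == opp && b == status))
      res["shared_with_exactly_one"] <- res["shared_with_exactly_one"] + 1
    else if (a == opp && b == opp)
      res["focal_unique"] <- res["focal_unique"] + 1
    else res["unresolved"] <- res["unresolved"] + 1
  }
  res
}

# independent per-column re-evaluation of the convergence conditions
scan_brute <- function(msa_obj, bg_min = 1.0) {
  m <- do.call(rbind, strsplit(msa_obj$sequences, ""))
  rownames(m) <- names(msa_obj$sequences)
  called <- integer()
  for (col in seq_len(ncol(m))) {
    fg <- m[msa_obj$foreground, col]
    bg <- m[msa_obj$background, col]
    if (any(c(fg, bg) == "-")) next
    tab <- sort(table(bg), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) next
    if (tab[1] / length(bg) < bg_min) next
    if (length(unique(fg)) != 1) next
    if (fg[1] == names(tab)[1]) next
    called <- c(called, col)
  }
  called
}

# hsp_records builder for in-code fixtures
make_hits <- function(query_id, subject_id, s_start, s_end,
                      evalue = 1e-50, pct = 95, len = NULL) {
  n <- length(query_id)
  len <- len %||% (abs(s_end - s_start) + 1L)
  h <- data.frame(query_id = query_id, subject_id = subject_id,
                  pct_identity = rep_len(pct, n),
                  aln_length = as.integer(rep_len(len, n)),
                  mismatches = 0L, gap_opens = 0L,
                  q_start = 1L, q_end = as.integer(rep_len(len, n)),
                  s_start = pmin(s_start, s_end),
                  s_end = pmax(s_start, s_end),
                  evalue = rep_len(evalue, n),
                  bit_score = rep_len(2 * len, n),
                  strand = ifelse(s_start <= s_end, "+", "-"),
                  stringsAsFactors = FALSE)
  class(h) <- c("hsp_records", "data.frame")
  h
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# planted-partition similarity graph on n_blocks x block_size nodes
planted_partition_graph <- function(n_blocks = 5, block_size = 20,
                                    p_in = 0.9, p_out = 0.05) {
  n <- n_blocks * block_size
  blocks <- rep(seq_len(n_blocks), each = block_size)
  ids <- sprintf("n%03d", seq_len(n))
  from <- to <- character()
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    p <- if (blocks[a] == blocks[b]) p_in else p_out
    if (runif(1) < p) { from <- c(from, ids[a]); to <- c(to, ids[b]) }
  }
  hits <- make_hits(from, to, 1L, 100L, evalue = 1e-50, len = 100L)
  list(graph = build_similarity_graph(hits, setNames(rep("SPX", n), ids)),
       truth = setNames(blocks, ids), ids = ids)
}

cluster_labels <- function(groups, ids) {
  lab <- setNames(rep(NA_integer_, length(ids)), ids)
  for (i in seq_along(groups))
    lab[unlist(groups[[i]], use.names = FALSE)] <- i
  lab
}
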