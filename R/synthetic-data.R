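# Synthetic data generation: every input the pipeline consumes can be
# produced here with recorded ground truth, seed-reproducibly. The defaults
# describe the desk-scale validation conditions used throughout the test
# suite: a 5-species reference panel of 300 single-copy orthologue groups at
# 5% interspecies divergence, a query genome with 20% of groups deleted, and
# 150 bp paired-end reads with 1% substitution error.

#' Build a multi-species reference CDS panel with orthologue structure
#'
#' Draws one random ancestral CDS per orthologue group and derives each
#' species' member by i.i.d. per-site substitution at the stated divergence,
#' so each group is exactly single-copy per species and pairwise divergence
#' within a group is analytically known.
#'
#' @param n_species number of reference species (>= 2).
#' @param n_groups number of orthologue groups (>= 1).
#' @param gene_length_range integer pair; CDS lengths are drawn uniformly in
#'   this inclusive range (bp).
#' @param interspecies_divergence per-site substitution probability from the
#'   group ancestor to each species member, in \[0, 0.5\].
#' @param seed integer seed; fully determines the output.
#' @param species_ids optional character vector of species names; default
#'   `SP1..SPn`.
#' @return list with `catalog` (a [cds_catalog] carrying the group ancestors)
#'   and `groups` (an [ortho_group_set]).
#' @export
build_reference_panel <- function(n_species, n_groups,
                                  gene_length_range = c(300L, 1500L),
                                  interspecies_divergence = 0.05,
                                  seed = NULL, species_ids = NULL) {
  if (n_species < 2) stop_param("'n_species' must be >= 2")
  if (n_groups < 1) stop_param("'n_groups' must be >= 1")
  check_fraction(interspecies_divergence, "interspecies_divergence", max = 0.5)
  if (length(gene_length_range) != 2L || any(gene_length_range < 1) ||
      gene_length_range[1] > gene_length_range[2])
    stop_param("'gene_length_range' must be an increasing positive pair")
  if (!is.null(seed)) set.seed(seed)
  species_ids <- species_ids %||% sprintf("SP%d", seq_len(n_species))
  if (length(species_ids) != n_species || anyDuplicated(species_ids))
    stop_param("'species_ids' must be %d unique names", n_species)

  group_ids <- sprintf("OG%04d", seq_len(n_groups))
  lens <- sample(gene_length_range[1]:gene_length_range[2], n_groups,
                 replace = TRUE)
  ancestors <- setNames(vapply(lens, random_seq, ""), group_ids)

  species <- list()
  groups <- setNames(vector("list", n_groups), group_ids)
  for (sp in species_ids) {
    genes <- vapply(ancestors, mutate_seq, "",
                    divergence = interspecies_divergence)
    names(genes) <- sprintf("%s_g%04d", sp, seq_len(n_groups))
    species[[sp]] <- genes
    for (i in seq_len(n_groups))
      groups[[i]][[sp]] <- names(genes)[i]
  }
  list(catalog = cds_catalog(species, ancestors = ancestors),
       groups = ortho_group_set(groups))
}

#' Plant a query genome with a known subset of orthologues deleted
#'
#' Deletes `round(loss_fraction * n_groups)` groups outright (no homologous
#' sequence remains), mutates each retained group's ancestral CDS at the
#' query divergence, shuffles gene order, and joins genes with random
#' intergenic spacers. The returned truth records every group's status.
#'
#' @param catalog a [cds_catalog] carrying group ancestors (as produced by
#'   [build_reference_panel]).
#' @param loss_fraction fraction of groups to delete, in \[0, 1).
#' @param query_divergence per-site substitution probability from the group
#'   ancestor to the query copy.
#' @param intergenic_length mean spacer length (bp); each spacer length is
#'   drawn uniformly in \[0.5x, 1.5x\] of this value.
#' @param seed integer seed.
#' @return list with `genome` (single character string) and `truth`
#'   (a [sim_truth] with `group_status`).
#' @export
plant_query_genome <- function(catalog, loss_fraction = 0.2,
                               query_divergence = 0.05,
                               intergenic_length = 200L, seed = NULL) {
  if (!inherits(catalog, "cds_catalog") || length(catalog$species) == 0)
    stop_param("'catalog' must be a non-empty cds_catalog")
  ancestors <- catalog$ancestors
  if (is.null(ancestors) || length(ancestors) == 0)
    stop_param("'catalog' carries no ancestral group sequences")
  check_fraction(loss_fraction, "loss_fraction")
  if (loss_fraction >= 1) stop_param("'loss_fraction' must be < 1")
  check_fraction(query_divergence, "query_divergence", max = 0.5)
  if (intergenic_length < 0) stop_param("'intergenic_length' must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  group_ids <- names(ancestors)
  n_groups <- length(group_ids)
  n_lost <- floor(loss_fraction * n_groups + 0.5)
  lost <- if (n_lost > 0) sample(group_ids, n_lost) else character()
  status <- setNames(rep("PRESENT", n_groups), group_ids)
  status[lost] <- "LOST"

  retained <- sample(setdiff(group_ids, lost))
  genes <- vapply(ancestors[retained], mutate_seq, "",
                  divergence = query_divergence)
  lo <- floor(0.5 * intergenic_length)
  hi <- ceiling(1.5 * intergenic_length)
  spacer_len <- if (hi > lo) sample(lo:hi, length(genes) + 1L, replace = TRUE)
                else rep(lo, length(genes) + 1L)
  spacers <- vapply(spacer_len, random_seq, "")
  pieces <- character(2L * length(genes) + 1L)
  pieces[seq(1L, length(pieces), by = 2L)] <- spacers
  if (length(genes)) pieces[seq(2L, length(pieces) - 1L, by = 2L)] <- genes
  truth <- sim_truth(group_status = status,
                     query_divergence = query_divergence,
                     seed = seed)
  list(genome = paste(pieces, collapse = ""), truth = truth)
}

#' Simulate uniform paired-end shotgun reads with substitution errors
#'
#' Draws `ceiling(depth * genome_length / (2 * read_length))` fragment
#' positions uniformly over all fully-contained placements, emits mate 1
#' forward and mate 2 reverse-complemented from the other fragment end, and
#' applies i.i.d. per-base substitution errors. Insert size is constant at
#' `insert_mean` by default; set `insert_sd > 0` for normally distributed
#' inserts (rounded, clamped to \[read_length, genome length\]).
#'
#' @param genome single character string.
#' @param depth target mean per-base depth (> 0).
#' @param read_length read length in bp.
#' @param insert_mean outer fragment length (>= read_length).
#' @param error_rate per-base substitution error probability.
#' @param insert_sd standard deviation of the insert size (0 = constant).
#' @param seed integer seed.
#' @return object of class `read_pairs`: list with `id`, `seq1`, `seq2`
#'   character vectors.
#' @export
simulate_reads <- function(genome, depth, read_length = 150L,
                           insert_mean = 300L, error_rate = 0.01,
                           insert_sd = 0, seed = NULL) {
  G <- nchar(genome)
  if (depth <= 0) stop_param("'depth' must be > 0")
  if (read_length > insert_mean || insert_mean > G)
    stop_param("need read_length <= insert_mean <= genome length (%d <= %d <= %d)",
               read_length, insert_mean, G)
  check_fraction(error_rate, "error_rate")
  if (!is.null(seed)) set.seed(seed)

  n_pairs <- as.integer(ceiling(depth * G / (2 * read_length)))
  ins <- if (insert_sd > 0) {
    pmin(pmax(as.integer(round(rnorm(n_pairs, insert_mean, insert_sd))),
              read_length), G)
  } else rep(as.integer(insert_mean), n_pairs)
  starts <- vapply(G - ins + 1L, function(m) sample.int(m, 1L), 0L)
  seq1 <- substring(genome, starts, starts + read_length - 1L)
  seq2 <- reverse_complement(
    substring(genome, starts + ins - read_length, starts + ins - 1L))
  structure(list(id = sprintf("read%06d", seq_len(n_pairs)),
                 seq1 = add_read_errors(seq1, error_rate),
                 seq2 = add_read_errors(seq2, error_rate)),
            class = "read_pairs")
}

add_read_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0) return(reads)
  L <- nchar(reads)
  chars <- strsplit(paste(reads, collapse = ""), "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < error_rate)
  if (length(hit)) {
    cur <- match(chars[hit], DNA_ALPHABET)
    step <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- DNA_ALPHABET[(cur - 1L + step) %% 4L + 1L]
  }
  ends <- cumsum(L)
  substring(paste(chars, collapse = ""), ends - L + 1L, ends)
}

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("%d read pairs (%d bp mates)\n", length(x$id),
              if (length(x$seq1)) nchar(x$seq1[1]) else 0L))
  invisible(x)
}

#' Plant an MSA with known convergent foreground-specific columns
#'
#' Planted columns carry one residue shared by every background taxon and a
#' different residue shared by every foreground taxon. All other columns
#' start from a single shared residue (so the foreground can never differ
#' from the background consensus there) and then receive i.i.d. background
#' noise substitutions at `background_noise`.
#'
#' @param n_background,n_foreground taxon counts (foreground >= 1).
#' @param length alignment length in columns.
#' @param n_convergent number of planted columns (<= length).
#' @param background_noise per-cell substitution probability applied to
#'   background taxa at non-planted columns.
#' @param seed integer seed.
#' @return list with `msa` (an [msa]) and `truth` (a [sim_truth] whose
#'   `planted_columns` are 1-based column indices).
#' @export
plant_msa <- function(n_background = 17L, n_foreground = 3L, length = 120L,
                      n_convergent = 9L, background_noise = 0, seed = NULL) {
  if (n_foreground < 1) stop_param("'n_foreground' must be >= 1")
  if (n_background < 1) stop_param("'n_background' must be >= 1")
  if (n_convergent > length)
    stop_param("'n_convergent' (%d) exceeds alignment length (%d)",
               n_convergent, length)
  check_fraction(background_noise, "background_noise")
  if (!is.null(seed)) set.seed(seed)

  bg_taxa <- sprintf("BG%02d", seq_len(n_background))
  fg_taxa <- sprintf("FG%02d", seq_len(n_foreground))
  n_taxa <- n_background + n_foreground
  base <- sample(AA_ALPHABET, length, replace = TRUE)
  m <- matrix(rep(base, each = n_taxa), nrow = n_taxa,
              dimnames = list(c(bg_taxa, fg_taxa), NULL))

  planted <- sort(if (n_convergent > 0) sample.int(length, n_convergent)
                  else integer())
  for (col in planted) {
    bg_res <- base[col]
    fg_res <- sample(setdiff(AA_ALPHABET, bg_res), 1L)
    m[fg_taxa, col] <- fg_res
  }
  noise_cols <- setdiff(seq_len(length), planted)
  if (background_noise > 0 && base::length(noise_cols)) {
    block <- m[bg_taxa, noise_cols, drop = FALSE]
    hit <- which(runif(base::length(block)) < background_noise)
    if (base::length(hit)) {
      cur <- match(block[hit], AA_ALPHABET)
      step <- sample.int(19L, base::length(hit), replace = TRUE)
      block[hit] <- AA_ALPHABET[(cur - 1L + step) %% 20L + 1L]
      m[bg_taxa, noise_cols] <- block
    }
  }
  aln <- setNames(collapse_columns(t(m)), rownames(m))
  list(msa = msa(aln, foreground = fg_taxa, background = bg_taxa),
       truth = sim_truth(planted_columns = planted, seed = seed))
}

#' Plant a GO DAG and gene annotations with known term enrichment
#'
#' Builds a single-rooted layered is_a DAG, annotates genes to leaf-layer
#' terms at a baseline rate, and over-annotates a chosen foreground gene set
#' to `enriched_terms` terms so that the annotation odds in the foreground
#' are `effect_odds` times the background odds. With `effect_odds = 1` no
#' term is planted and the truth is empty.
#'
#' @param n_genes total gene universe size.
#' @param n_terms number of non-root terms.
#' @param dag_depth number of layers below the root (>= 1).
#' @param foreground character vector of foreground gene ids (subset of the
#'   universe `g0001..`), or an integer count to sample.
#' @param enriched_terms number of leaf terms to plant enrichment into.
#' @param effect_odds planted odds ratio (>= 1).
#' @param baseline_rate baseline annotation probability per (gene, term).
#' @param seed integer seed.
#' @return list with `dag` (a [go_dag]), `annotation` (direct gene -> term
#'   list), `genes` (the universe), `foreground`, and `truth` (a [sim_truth]
#'   whose `enriched_terms` maps term id -> planted odds ratio).
#' @export
plant_annotation <- function(n_genes = 2000L, n_terms = 40L, dag_depth = 3L,
                             foreground = 200L, enriched_terms = 3L,
                             effect_odds = 8, baseline_rate = 0.05,
                             seed = NULL) {
  if (effect_odds < 1) stop_param("'effect_odds' must be >= 1")
  if (dag_depth < 1) stop_param("'dag_depth' must be >= 1 (cyclic or rootless structures are not representable)")
  if (n_terms < dag_depth) stop_param("'n_terms' must be >= 'dag_depth'")
  check_fraction(baseline_rate, "baseline_rate", max = 0.5)
  if (!is.null(seed)) set.seed(seed)

  genes <- sprintf("g%04d", seq_len(n_genes))
  if (is.numeric(foreground) && length(foreground) == 1L)
    foreground <- sample(genes, foreground)
  if (!all(foreground %in% genes))
    stop_param("'foreground' contains genes outside the universe")

  # layered DAG: root GO:ROOT, then dag_depth layers; each term draws one
  # parent from the layer above (guaranteed acyclic, single root)
  root <- "GO:0000000"
  term_ids <- sprintf("GO:%07d", seq_len(n_terms))
  layer <- sort(rep_len(seq_len(dag_depth), n_terms))
  parents <- setNames(vector("list", n_terms), term_ids)
  for (i in seq_len(n_terms)) {
    pool <- if (layer[i] == 1L) root else term_ids[layer == layer[i] - 1L]
    parents[[i]] <- sample(pool, 1L)
  }
  terms_df <- data.frame(
    id = c(root, term_ids),
    name = c("synthetic root", sprintf("synthetic term %d", seq_len(n_terms))),
    namespace = "biological_process", stringsAsFactors = FALSE)
  dag <- go_dag(terms_df, c(setNames(list(character()), root), parents))

  leaf_terms <- term_ids[layer == dag_depth]
  planted <- if (effect_odds > 1 && enriched_terms > 0)
    sample(leaf_terms, min(enriched_terms, length(leaf_terms))) else character()

  is_fg <- genes %in% foreground
  base_odds <- baseline_rate / (1 - baseline_rate)
  p_enriched <- (base_odds * effect_odds) / (1 + base_odds * effect_odds)
  ann <- setNames(vector("list", n_genes), genes)
  for (t in leaf_terms) {
    p <- rep(baseline_rate, n_genes)
    if (t %in% planted) p[is_fg] <- p_enriched
    hit <- which(runif(n_genes) < p)
    for (i in hit) ann[[i]] <- c(ann[[i]], t)
  }
  ann <- ann[lengths(ann) > 0]
  truth <- sim_truth(enriched_terms = setNames(rep(effect_odds,
                                                   length(planted)), planted),
                     seed = seed)
  list(dag = dag, annotation = ann, genes = genes,
       foreground = foreground, truth = truth)
}
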