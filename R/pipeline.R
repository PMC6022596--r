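# End-to-end orchestration from a single config: read inputs, map reads (or
# load precomputed hits), compute coverage, classify, compare across
# species, and optionally cluster / enrich / scan. All stage outputs are
# written to disk (auditability over speed) and the run summary carries
# checksums so identical config + seed gives identical summaries.

#' Read and validate a run configuration
#'
#' The YAML layout mirrors [run_all]'s `config` list. Paths are resolved
#' relative to the YAML file's directory.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_param("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  cfg <- resolve_paths(cfg, base)
  validate_config(cfg)
  cfg
}

resolve_paths <- function(x, base) {
  path_keys <- c("reads_1", "reads_2", "hits_tsv", "groups_tsv",
                 "imported_status_tsv", "protein_hits_tsv",
                 "species_map_tsv", "obo", "annotation_tsv", "fg", "bg",
                 "msa_fasta", "partition_tsv", "out_dir")
  fix <- function(node, key, parent) {
    if (is.list(node)) {
      for (k in names(node)) node[[k]] <- fix(node[[k]], k, key)
      node
    } else if (is.character(node) &&
               (key %in% path_keys || parent == "references")) {
      ifelse(grepl("^/", node), node, file.path(base, node))
    } else node
  }
  fix(x, "", "")
}

validate_config <- function(cfg) {
  must_exist <- c(unlist(cfg$references, use.names = FALSE),
                  cfg$reads_1, cfg$reads_2, cfg$hits_tsv, cfg$groups_tsv,
                  cfg$imported_status_tsv,
                  cfg$cluster$protein_hits_tsv, cfg$cluster$species_map_tsv,
                  cfg$enrichment$obo, cfg$enrichment$annotation_tsv,
                  cfg$enrichment$fg, cfg$enrichment$bg,
                  cfg$convscan$msa_fasta, cfg$convscan$partition_tsv)
  for (p in must_exist)
    if (!file.exists(p)) stop_param("config references missing file: %s", p)
  invisible(cfg)
}

#' Run the presence/absence stages end-to-end
#'
#' Stages: load reference CDS FASTAs -> obtain hits (either a precomputed
#' tabular hit file or [naive_map] over FASTQ reads) -> horizontal coverage
#' -> group means -> classification -> optional cross-species matrix and
#' Venn categories. Intermediate TSVs and a JSON summary are written to
#' `config$out_dir`.
#'
#' Config fields: `references` (named list species -> FASTA path),
#' `groups_tsv`, one of `hits_tsv` or `reads_1`/`reads_2`, optional
#' `imported_status_tsv`, `focal_species` (default `"QUERY"`), optional
#' `venn` (list: `others` = two species), thresholds `evalue_max`,
#' `lost_max`, `conserved_min`, mapper settings `k`,
#' `min_match_fraction`, `na_species`, and `seed`.
#'
#' @param config list or YAML path (see [read_run_config]).
#' @return run summary list (invisibly returns it; also written as JSON).
#' @export
run_pav <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  out_dir <- cfg$out_dir %||% stop_param("config needs 'out_dir'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  log_stage <- function(stage, msg)
    message(sprintf("[%s] %s", stage, msg))

  if (is.null(cfg$references)) stop_param("config needs 'references'")
  log_stage("io", sprintf("reading %d reference FASTA(s)", length(cfg$references)))
  species <- lapply(cfg$references, function(p) {
    if (!file.exists(p)) stop_param("io: reference FASTA not found: %s", p)
    read_fasta(p)
  })
  catalog <- cds_catalog(species)
  if (is.null(cfg$groups_tsv)) stop_param("config needs 'groups_tsv'")
  groups <- read_groups_tsv(cfg$groups_tsv)

  inputs <- c(unlist(cfg$references, use.names = FALSE), cfg$groups_tsv)
  if (!is.null(cfg$hits_tsv)) {
    log_stage("io", sprintf("reading hits from %s", cfg$hits_tsv))
    hits <- read_tabular_hits(cfg$hits_tsv,
                              evalue_max = cfg$evalue_max %||% 1e-5)
    inputs <- c(inputs, cfg$hits_tsv)
  } else if (!is.null(cfg$reads_1)) {
    log_stage("map", "mapping reads with the naive k-mer mapper")
    reads <- c(read_fastq(cfg$reads_1),
               if (!is.null(cfg$reads_2)) read_fastq(cfg$reads_2))
    hits <- naive_map(reads, catalog, k = cfg$k %||% 16L,
                      min_match_fraction = cfg$min_match_fraction %||% 0.8)
    inputs <- c(inputs, cfg$reads_1, cfg$reads_2)
  } else stop_param("config needs 'hits_tsv' or 'reads_1'")

  log_stage("coverage", sprintf("%d hits over %d CDSs", nrow(hits),
                                sum(lengths(catalog$species))))
  cov <- horizontal_coverage(hits, catalog)
  cov_path <- file.path(out_dir, "coverage.tsv")
  write.table(cov, cov_path, sep = "\t", quote = FALSE, row.names = FALSE)

  gcov <- group_mean_coverage(cov, groups,
                              na_species = cfg$na_species %||% "exclude")
  calls <- classify_pav(gcov, lost_max = cfg$lost_max %||% 2,
                        conserved_min = cfg$conserved_min %||% 50)
  group_path <- file.path(out_dir, "group_status.tsv")
  write.table(merge(gcov, calls[c("group_id", "status")], by = "group_id"),
              group_path, sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("classify", paste(sprintf("%s=%d",
                                      names(table(calls$status)),
                                      table(calls$status)), collapse = " "))

  outputs <- c(cov_path, group_path)
  venn <- NULL
  if (!is.null(cfg$imported_status_tsv)) {
    imported <- read_status_tsv(cfg$imported_status_tsv)
    inputs <- c(inputs, cfg$imported_status_tsv)
    pm <- build_pav_matrix(calls, cfg$focal_species %||% "QUERY", imported)
    pm_path <- file.path(out_dir, "pav_matrix.tsv")
    write.table(data.frame(group_id = rownames(pm), unclass(pm),
                           check.names = FALSE),
                pm_path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, pm_path)
    if (!is.null(cfg$venn)) {
      venn <- lapply(c(CONSERVED = "CONSERVED", LOST = "LOST"),
                     function(s) unclass(venn_categories(
                       pm, cfg$focal_species %||% "QUERY",
                       unlist(cfg$venn$others), s))[c("focal_total", "shared_all",
                                              "shared_with_exactly_one",
                                              "focal_unique", "others_only",
                                              "unresolved")])
      venn_path <- file.path(out_dir, "venn.json")
      jsonlite::write_json(venn, venn_path, auto_unbox = TRUE, pretty = TRUE)
      outputs <- c(outputs, venn_path)
    }
  }

  summary <- list(
    tool = "pavcomp", version = as.character(packageVersion("pavcomp")),
    seed = cfg$seed,
    thresholds = list(evalue_max = cfg$evalue_max %||% 1e-5,
                      lost_max = cfg$lost_max %||% 2,
                      conserved_min = cfg$conserved_min %||% 50),
    n_hits = nrow(hits),
    status_counts = as.list(table(calls$status)),
    venn = venn,
    checksums = list(inputs = as.list(tools::md5sum(sort(unique(inputs)))),
                     outputs = as.list(tools::md5sum(outputs))))
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}

#' Run every configured stage
#'
#' [run_pav] plus, when the corresponding config blocks are present:
#' `cluster` (protein hits + species map -> [mcl_cluster], optional
#' `targets`/`outgroups` -> [select_lineage_specific]), `enrichment`
#' (OBO + annotation TSV + `fg`/`bg` gene-list files -> [go_enrichment]),
#' and `convscan` (aligned FASTA + partition TSV ->
#' [scan_convergent_columns]).
#'
#' @param config list or YAML path.
#' @return merged run summary (invisibly; also written as JSON).
#' @export
run_all <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  summary <- run_pav(cfg)
  out_dir <- cfg$out_dir

  if (!is.null(cfg$cluster)) {
    message("[cluster] Markov clustering of protein hits")
    ph <- read_tabular_hits(cfg$cluster$protein_hits_tsv,
                            evalue_max = cfg$evalue_max %||% 1e-5)
    smap <- read.delim(cfg$cluster$species_map_tsv, header = FALSE,
                       stringsAsFactors = FALSE)
    graph <- build_similarity_graph(ph, setNames(smap[[2]], smap[[1]]))
    clusters <- mcl_cluster(graph, inflation = cfg$cluster$inflation %||% 1.5)
    write_groups_tsv(clusters, file.path(out_dir, "clusters.tsv"))
    summary$n_clusters <- length(clusters)
    if (!is.null(cfg$cluster$targets)) {
      spec <- select_lineage_specific(clusters, unlist(cfg$cluster$targets),
                                      unlist(cfg$cluster$outgroups) %||%
                                        character())
      write_groups_tsv(spec, file.path(out_dir, "lineage_specific.tsv"))
      summary$n_lineage_specific <- length(spec)
    }
  }

  if (!is.null(cfg$enrichment)) {
    message("[enrich] term enrichment")
    dag <- read_obo(cfg$enrichment$obo)
    ann <- read_annotation_tsv(cfg$enrichment$annotation_tsv)
    fg <- readLines(cfg$enrichment$fg)
    bg <- readLines(cfg$enrichment$bg)
    res <- go_enrichment(dag, ann, fg, bg,
                         method = cfg$enrichment$method %||% "classic",
                         elim_alpha = cfg$enrichment$elim_alpha %||% 0.01)
    write.table(res, file.path(out_dir, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_terms_tested <- nrow(res)
  }

  if (!is.null(cfg$convscan)) {
    message("[convscan] scanning for convergent substitutions")
    aln <- read_msa_fasta(cfg$convscan$msa_fasta,
                          partition = cfg$convscan$partition_tsv)
    sites <- scan_convergent_columns(
      aln, bg_conservation_min = cfg$convscan$bg_conservation_min %||% 1.0)
    write.table(column_report(sites, aln),
                file.path(out_dir, "convergent_sites.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_convergent_sites <- nrow(sites)
  }

  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}
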