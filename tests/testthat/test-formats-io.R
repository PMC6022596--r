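test_that("tabular hits parse, strand-normalize and filter by e-value", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("r1\tg1\t98.0\t150\t3\t0\t1\t150\t51\t200\t1e-60\t250",
               "r2\tg1\t95.0\t150\t7\t0\t1\t150\t200\t51\t1e-40\t200",
               "r3\tg2\t90.0\t150\t15\t0\t1\t150\t1\t150\t1e-3\t80"),
             f)
  h <- read_tabular_hits(f, evalue_max = 1e-5)
  expect_equal(nrow(h), 2)                       # e-value 1e-3 excluded
  expect_equal(h$s_start, c(51L, 51L))
  expect_equal(h$s_end, c(200L, 200L))
  expect_equal(h$strand, c("+", "-"))
  expect_equal(h$query_id, c("r1", "r2"))        # order preserved
  # round trip preserves records including original minus orientation
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_tabular_hits(h, f2)
  expect_equal(read_tabular_hits(f2, 1e-5), h)
})

test_that("malformed hit lines are rejected with their line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("r1\tg1\t98.0\t150\t3\t0\t1\t150\t51\t200\t1e-60\t250",
               "r2\tg1\t98.0\t150"), f)
  expect_error(read_tabular_hits(f), "line 2.*12")
  writeLines(c("r1\tg1\tninety\t150\t3\t0\t1\t150\t51\t200\t1e-60\t250"), f)
  expect_error(read_tabular_hits(f), "line 1.*numeric")
})

test_that("FASTA and FASTQ round-trip through files", {
  set.seed(4)
  seqs <- setNames(vapply(sample(50:150, 100, replace = TRUE), function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    ""), sprintf("seq%03d", 1:100))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f), seqs)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(seqs, path = fq)
  expect_identical(read_fastq(fq), seqs)
  # paired output under a shared prefix
  reads <- simulate_reads(paste(rep("ACGT", 500), collapse = ""), 1, 20, 50,
                          seed = 5)
  prefix <- file.path(withr::local_tempdir(), "sim")
  write_fastq(reads, prefix = prefix)
  r1 <- read_fastq(paste0(prefix, "_1.fastq"))
  expect_identical(unname(r1), reads$seq1)
  expect_identical(names(r1), paste0(reads$id, "/1"))
})

test_that("duplicate FASTA ids and ragged MSAs are rejected", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGG"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">a", "ACDEF", ">b", "ACD"), f)
  expect_error(read_msa_fasta(f), "ragged")
})

test_that("minimal OBO files round-trip and undeclared parents error", {
  terms <- data.frame(id = c("GO:1", "GO:2", "GO:3"),
                      name = c("root", "mid", "leaf"),
                      namespace = "biological_process")
  dag <- go_dag(terms, list("GO:1" = character(), "GO:2" = "GO:1",
                            "GO:3" = c("GO:1", "GO:2")))
  f <- withr::local_tempfile(fileext = ".obo")
  write_obo(dag, f)
  dag2 <- read_obo(f)
  expect_equal(dag2$terms$id, dag$terms$id)
  expect_equal(dag2$parents, dag$parents)
  writeLines(c("[Term]", "id: GO:9", "name: orphan", "is_a: GO:8 ! missing"),
             f)
  expect_error(read_obo(f), "GO:9.*GO:8")
})

test_that("annotation, status and group TSVs round-trip with validation", {
  dir <- withr::local_tempdir()
  ann <- list(g1 = c("GO:1", "GO:2"), g2 = "GO:2")
  f <- file.path(dir, "ann.tsv")
  write_annotation_tsv(ann, f)
  expect_identical(read_annotation_tsv(f), ann)

  st <- data.frame(group_id = c("OG1", "OG1", "OG2"),
                   species = c("ZMU", "ZMA", "ZMU"),
                   status = c("LOST", "CONSERVED", "NO_DATA"),
                   stringsAsFactors = FALSE)
  f2 <- file.path(dir, "status.tsv")
  write_status_tsv(st, f2)
  expect_identical(read_status_tsv(f2), st)
  st$status[1] <- "GONE"
  write_status_tsv(st, f2)
  expect_error(read_status_tsv(f2), "GONE")

  panel <- build_reference_panel(3, 8, c(200, 300), 0.05, seed = 2)
  f3 <- file.path(dir, "groups.tsv")
  write_groups_tsv(panel$groups, f3)
  g2 <- read_groups_tsv(f3)
  expect_equal(lapply(g2, lapply, sort), lapply(panel$groups, lapply, sort),
               ignore_attr = TRUE)
})

test_that("naive_map places exact substrings at 1-based coordinates", {
  set.seed(12)
  gene <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  catalog <- cds_catalog(list(SP1 = c(g = gene)))
  read <- substr(gene, 101, 250)
  h <- naive_map(setNames(read, "r1"), catalog, k = 16,
                 min_match_fraction = 0.9)
  expect_equal(h$s_start, 101L)
  expect_equal(h$s_end, 250L)
  expect_equal(h$strand, "+")
  expect_equal(h$mismatches, 0L)
  expect_equal(h$evalue, 0)
  # reverse-complemented placement is found on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  h2 <- naive_map(setNames(rc, "r2"), catalog, k = 16,
                  min_match_fraction = 0.9)
  expect_equal(h2$s_start, 101L)
  expect_equal(h2$strand, "-")
  # a read sharing no k-mer with any CDS yields nothing
  h3 <- naive_map(setNames(strrep("A", 60), "r3"), catalog, k = 16,
                  min_match_fraction = 0.5)
  expect_equal(nrow(h3), 0)
  expect_error(naive_map(setNames(read, "r"), catalog, k = 200), "seed length")
})

test_that("naive_map equals the brute-force all-offsets Hamming oracle", {
  set.seed(33)
  for (rep in 1:3) {
    genes <- setNames(vapply(sample(60:120, 4), function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
      ""), sprintf("g%d", 1:4))
    catalog <- cds_catalog(list(SPA = genes[1:2], SPB = genes[3:4]))
    # reads: planted substrings with up to 2 substitutions, plus random ones
    reads <- character(50)
    for (i in 1:50) {
      if (i <= 35) {
        g <- sample(genes, 1)
        L <- 30
        s <- sample(nchar(g) - L + 1, 1)
        rd <- substr(g, s, s + L - 1)
        v <- strsplit(rd, "")[[1]]
        nmut <- sample(0:2, 1)
        pos <- sample(L, nmut)
        v[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
        rd <- paste(v, collapse = "")
        if (runif(1) < 0.5)
          rd <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(rd)))
      } else {
        rd <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                    collapse = "")
      }
      reads[i] <- rd
    }
    names(reads) <- sprintf("r%02d", 1:50)
    # k = 8 with <= 10% mismatches over 30 bp guarantees an intact seed
    got <- naive_map(reads, catalog, k = 8, min_match_fraction = 0.9)
    want <- brute_force_map(as.list(reads), catalog, 0.9)
    expect_identical(hit_key(got), hit_key(want))
  }
})

test_that("aligned read percentages reproduce self-consistent published counts", {
  expect_equal(aligned_read_fraction(24495631, 908769239), 2.7)
  expect_equal(aligned_read_fraction(16727940, 908769239), 1.8)
  expect_equal(aligned_read_fraction(0, 1000), 0)
  expect_error(aligned_read_fraction(5, 0), "n_total")
  expect_error(aligned_read_fraction(10, 5), "<=")
})
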