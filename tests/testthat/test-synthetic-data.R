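test_that("reference panels have single-copy orthologue structure", {
  panel <- build_reference_panel(5, 30, c(300, 600), 0.05, seed = 42)
  expect_length(panel$catalog$species, 5)
  expect_true(all(lengths(panel$catalog$species) == 30))
  expect_length(panel$groups, 30)
  expect_true(all(vapply(panel$groups, function(g)
    all(lengths(g) == 1) && length(g) == 5, TRUE)))
  lens <- nchar(unlist(panel$catalog$species))
  expect_true(all(lens >= 300 & lens <= 600))
  # zero divergence: members are identical copies of the ancestor
  p0 <- build_reference_panel(2, 1, c(300, 300), 0, seed = 1)
  seqs <- unlist(p0$catalog$species, use.names = FALSE)
  expect_identical(seqs[1], seqs[2])
})

test_that("pairwise divergence within groups matches the substitution model", {
  d <- 0.05
  panel <- build_reference_panel(2, 300, c(300, 600), d, seed = 9)
  a <- panel$catalog$species[[1]]
  b <- panel$catalog$species[[2]]
  mismatches <- total <- 0
  for (i in seq_along(a)) {
    va <- strsplit(a[[i]], "")[[1]]
    vb <- strsplit(b[[i]], "")[[1]]
    mismatches <- mismatches + sum(va != vb)
    total <- total + length(va)
  }
  # two independently mutated copies differ at a site when exactly one
  # mutated, or both mutated to different residues (2/3 of the time)
  p_expected <- 2 * d * (1 - d) + (2 / 3) * d^2
  se <- sqrt(p_expected * (1 - p_expected) / total)
  expect_lt(abs(mismatches / total - p_expected), 3 * se)
})

test_that("planted query genomes delete the stated fraction of groups", {
  panel <- build_reference_panel(3, 100, c(300, 500), 0.05, seed = 5)
  pg <- plant_query_genome(panel$catalog, 0.2, 0.05, 100, seed = 6)
  expect_equal(sum(pg$truth$group_status == "LOST"), 20)
  # conservation: every group has a status
  expect_setequal(names(pg$truth$group_status), names(panel$groups))
  expect_equal(sum(pg$truth$group_status %in% c("PRESENT", "LOST")), 100)
  # at zero query divergence retained ancestors appear verbatim and lost
  # ones leave no homologous sequence at all
  anc <- panel$catalog$ancestors
  pgv <- plant_query_genome(panel$catalog, 0.2, 0, 100, seed = 8)
  present <- vapply(names(anc), function(g)
    grepl(anc[[g]], pgv$genome, fixed = TRUE), TRUE)
  expect_identical(unname(present),
                   unname(pgv$truth$group_status == "PRESENT"))
  pg0 <- plant_query_genome(panel$catalog, 0, 0, 100, seed = 8)
  expect_true(all(pg0$truth$group_status == "PRESENT"))
})

test_that("generators are byte-identical under the same seed", {
  panel <- build_reference_panel(3, 20, c(300, 400), 0.05, seed = 77)
  panel2 <- build_reference_panel(3, 20, c(300, 400), 0.05, seed = 77)
  expect_identical(panel, panel2)
  g1 <- plant_query_genome(panel$catalog, 0.3, 0.04, 150, seed = 13)
  g2 <- plant_query_genome(panel$catalog, 0.3, 0.04, 150, seed = 13)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$truth$group_status, g2$truth$group_status)
  r1 <- simulate_reads(g1$genome, 2, 100, 250, 0.01, seed = 14)
  r2 <- simulate_reads(g1$genome, 2, 100, 250, 0.01, seed = 14)
  expect_identical(r1, r2)
  m1 <- plant_msa(10, 3, 80, 5, 0.1, seed = 15)
  m2 <- plant_msa(10, 3, 80, 5, 0.1, seed = 15)
  expect_identical(m1, m2)
  a1 <- plant_annotation(200, 12, 2, 30, 2, 6, seed = 16)
  a2 <- plant_annotation(200, 12, 2, 30, 2, 6, seed = 16)
  expect_identical(a1$annotation, a2$annotation)
})

test_that("read counts follow the depth formula exactly", {
  genome <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                  collapse = "")
  for (depth in c(0.5, 1, 3.3, 30)) for (rl in c(50L, 150L)) {
    reads <- simulate_reads(genome, depth, rl, insert_mean = 2 * rl, seed = 1)
    expect_length(reads$id, ceiling(depth * 5000 / (2 * rl)))
  }
  # the stated desk example: 100 kb, depth 30, 150 bp -> 10 000 pairs
  g2 <- strrep("ACGT", 25000)
  expect_length(simulate_reads(g2, 30, 150, 300, seed = 2)$id, 10000)
})

test_that("error-free reads are exact genome substrings and depth is on target", {
  genome <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
                  collapse = "")
  reads <- simulate_reads(genome, 5, 100, 250, error_rate = 0, seed = 21)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  expect_true(all(vapply(reads$seq1, grepl, TRUE, x = genome, fixed = TRUE)))
  expect_true(all(vapply(vapply(reads$seq2, rc, ""), grepl, TRUE,
                         x = genome, fixed = TRUE)))
  # mean depth: every read lies fully inside, so the exact mean is
  # 2 * L * n_pairs / G, which must sit within 3 SE of the target
  depth_mean <- 2 * 100 * length(reads$id) / 20000
  expect_lt(abs(depth_mean - 5), 3 * sqrt(5 / length(reads$id)))
})

test_that("planted MSAs record exactly the planted convergent columns", {
  pm <- plant_msa(17, 3, 120, 9, 0, seed = 7)
  expect_length(pm$truth$planted_columns, 9)
  expect_true(all(pm$truth$planted_columns >= 1 &
                  pm$truth$planted_columns <= 120))
  expect_equal(pm$msa$length, 120)
  m <- do.call(rbind, strsplit(pm$msa$sequences, ""))
  rownames(m) <- names(pm$msa$sequences)
  for (col in pm$truth$planted_columns) {
    bg <- unique(m[pm$msa$background, col])
    fg <- unique(m[pm$msa$foreground, col])
    expect_length(bg, 1)
    expect_length(fg, 1)
    expect_false(bg == fg)
  }
  expect_length(plant_msa(10, 2, 50, 0, 0, seed = 3)$truth$planted_columns, 0)
  expect_error(plant_msa(10, 0, 50, 2, 0, seed = 3), "foreground")
  expect_error(plant_msa(10, 2, 50, 60, 0, seed = 3), "exceeds")
})

test_that("planted annotations have a single-rooted DAG and honest truth", {
  pa <- plant_annotation(300, 15, 3, 40, 2, 8, seed = 31)
  roots <- pa$dag$terms$id[lengths(pa$dag$parents) == 0]
  expect_length(roots, 1)
  expect_length(pa$truth$enriched_terms, 2)
  expect_true(all(pa$truth$enriched_terms == 8))
  # no planted effect at odds 1
  pa1 <- plant_annotation(300, 15, 3, 40, 2, 1, seed = 32)
  expect_length(pa1$truth$enriched_terms, 0)
  expect_error(plant_annotation(300, 15, 0, 40, 2, 8, seed = 1), "dag_depth")
  expect_error(plant_annotation(300, 15, 3, 40, 2, 0.5, seed = 1),
               "effect_odds")
})

test_that("generator parameter validation rejects invalid requests", {
  expect_error(build_reference_panel(1, 10), "n_species")
  expect_error(build_reference_panel(3, 0), "n_groups")
  expect_error(build_reference_panel(3, 10, interspecies_divergence = 0.7),
               "interspecies_divergence")
  panel <- build_reference_panel(2, 5, c(200, 300), 0.02, seed = 1)
  expect_error(plant_query_genome(cds_catalog(list(SP1 = c(g1 = "ACGT"))),
                                  0.2), "ancestral")
  expect_error(plant_query_genome(panel$catalog, 1.2), "loss_fraction")
  genome <- plant_query_genome(panel$catalog, 0, seed = 2)$genome
  expect_error(simulate_reads(genome, 0), "depth")
  expect_error(simulate_reads(genome, 5, 300, 200), "insert_mean")
})
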