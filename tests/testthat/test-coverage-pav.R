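test_that("interval union matches the per-base bitmap oracle", {
  expect_equal(union_covered_bases(rbind(c(1, 50), c(41, 90)), 100), 90)
  expect_equal(union_covered_bases(list(), 100), 0)
  expect_equal(union_covered_bases(rbind(c(10, 5)), 100), 0)
  expect_error(union_covered_bases(rbind(c(1, 5)), -1), "non-negative")
  set.seed(8)
  for (rep in 1:20) {
    len <- sample(100:5000, 1)
    n <- sample(1:200, 1)
    s <- sample(len, n, replace = TRUE)
    iv <- cbind(s, pmin(len, s + sample(0:300, n, replace = TRUE)))
    expect_identical(union_covered_bases(iv, len), bitmap_union(iv, len))
    # order and duplication independence
    expect_identical(union_covered_bases(iv[sample(n), , drop = FALSE], len),
                     union_covered_bases(rbind(iv, iv), len))
  }
})

test_that("horizontal coverage composes from per-CDS interval unions", {
  catalog <- cds_catalog(list(
    SP1 = c(gA = strrep("A", 100), gB = strrep("C", 200)),
    SP2 = c(gC = strrep("G", 150))))
  hits <- make_hits(c("r1", "r2", "r3"), c("gA", "gA", "gC"),
                    c(1L, 41L, 1L), c(50L, 90L, 150L))
  cov <- horizontal_coverage(hits, catalog)
  expect_setequal(cov$gene_id, c("gA", "gB", "gC"))
  expect_equal(cov$horizontal_coverage[cov$gene_id == "gA"], 90)
  expect_equal(cov$horizontal_coverage[cov$gene_id == "gB"], 0)
  expect_equal(cov$horizontal_coverage[cov$gene_id == "gC"], 100)
  expect_error(horizontal_coverage(
    make_hits("r", "nope", 1L, 10L), catalog), "unknown subject.*nope")
  # compositional oracle on a random fixture
  set.seed(91)
  lens <- sample(80:400, 6)
  genes <- setNames(vapply(lens, function(n) strrep("A", n), ""),
                    sprintf("g%d", 1:6))
  cat2 <- cds_catalog(list(SPX = genes))
  n <- 120
  gid <- sample(names(genes), n, replace = TRUE)
  s <- vapply(gid, function(g) sample(nchar(genes[[g]]), 1), 0L)
  e <- pmin(nchar(genes[gid]), s + sample(10:80, n, replace = TRUE))
  h <- make_hits(sprintf("r%03d", 1:n), gid, as.integer(s), as.integer(e))
  cov2 <- horizontal_coverage(h, cat2)
  for (g in names(genes)) {
    idx <- h$subject_id == g
    expect_equal(cov2$covered_bases[cov2$gene_id == g],
                 union_covered_bases(cbind(h$s_start[idx], h$s_end[idx]),
                                     nchar(genes[[g]])))
  }
})

test_that("group means average across species with NA exclusion", {
  records <- data.frame(
    species_id = c("ATH", "OSA", "MAC", "PDA", "SPO"),
    gene_id = sprintf("g%d", 1:5),
    covered_bases = c(60L, 40L, 20L, 40L, 40L),
    cds_length = 100L,
    horizontal_coverage = c(60, 40, 20, 40, 40))
  groups <- ortho_group_set(list(OG1 = list(ATH = "g1", OSA = "g2",
                                            MAC = "g3", PDA = "g4",
                                            SPO = "g5")))
  expect_equal(group_mean_coverage(records, groups)$mean_coverage, 40)
  # species with no member are excluded from the mean, not counted as 0
  g2 <- ortho_group_set(list(OG1 = list(ATH = "g1")))
  expect_equal(group_mean_coverage(records, g2)$mean_coverage, 60)
  expect_equal(group_mean_coverage(records, g2,
                                   na_species = "zero")$mean_coverage, 12)
  # members that never appear in the records at all -> NA -> NO_DATA
  g3 <- ortho_group_set(list(OG1 = list(ZZZ = "absent")))
  gc3 <- group_mean_coverage(records, g3)
  expect_true(is.na(gc3$mean_coverage))
  expect_equal(classify_pav(gc3)$status, "NO_DATA")
})

test_that("classification applies strict thresholds with an indeterminate band", {
  gc <- data.frame(group_id = sprintf("OG%d", 1:6),
                   mean_coverage = c(1.9, 55, 2.0, 50.0, 0, NA))
  calls <- classify_pav(gc)
  expect_equal(calls$status, c("LOST", "CONSERVED", "INDETERMINATE",
                               "INDETERMINATE", "LOST", "NO_DATA"))
  expect_equal(classify_pav(gc, lost_max = 5,
                            conserved_min = 40)$status[1], "LOST")
  expect_error(classify_pav(gc, lost_max = 60, conserved_min = 50),
               "lost_max")
})

test_that("adding hits never decreases coverage nor flips conserved to lost", {
  set.seed(55)
  genes <- setNames(vapply(sample(100:300, 4), function(n) strrep("A", n), ""),
                    sprintf("g%d", 1:4))
  catalog <- cds_catalog(list(SPX = genes))
  groups <- ortho_group_set(lapply(setNames(names(genes),
                                            paste0("OG", 1:4)),
                                   function(g) list(SPX = g)))
  random_hits <- function(n) {
    gid <- sample(names(genes), n, replace = TRUE)
    s <- vapply(gid, function(g) sample(nchar(genes[[g]]), 1), 0L)
    e <- pmin(nchar(genes[gid]), s + sample(5:60, n, replace = TRUE))
    make_hits(sprintf("r%03d", seq_len(n)), gid, as.integer(s), as.integer(e))
  }
  base <- random_hits(40)
  for (rep in 1:5) {
    more <- rbind(base, random_hits(10))
    class(more) <- class(base)
    c0 <- horizontal_coverage(base, catalog)
    c1 <- horizontal_coverage(more, catalog)
    expect_true(all(c1$covered_bases[order(c1$gene_id)] >=
                    c0$covered_bases[order(c0$gene_id)]))
    s0 <- classify_pav(group_mean_coverage(c0, groups))$status
    s1 <- classify_pav(group_mean_coverage(c1, groups))$status
    expect_false(any(s0 == "CONSERVED" & s1 == "LOST"))
    base <- more
  }
})
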