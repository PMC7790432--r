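test_that("sample retention keeps exactly the samples reaching the read depth", {
  m <- matrix(c(9999L, 10000L, 12000L), 1,
              dimnames = list("a", c("s1", "s2", "s3")))
  tab <- otu_table(m, as.Date("2016-01-01") + 0:2)
  kept <- filter_samples_min_reads(tab, 10000)
  expect_identical(sample_ids(kept), c("s2", "s3"))
  expect_identical(otu_ids(kept), "a")
  expect_identical(filter_samples_min_reads(tab, 0)$counts, tab$counts)
  expect_warning(filter_samples_min_reads(tab, 1e9), "all samples removed")

  # oracle: independent per-sample summation on random depths
  set.seed(7)
  depths <- sample(5000:15000, 50)
  counts <- vapply(depths, function(d) as.integer(rmultinom(1, d, rep(1, 30))),
                   integer(30))
  dimnames(counts) <- list(sprintf("o%02d", 1:30), sprintf("s%02d", 1:50))
  tab <- otu_table(counts, as.Date("2016-01-01") + 0:49)
  kept <- filter_samples_min_reads(tab, 10000)
  expect_identical(sample_ids(kept),
                   sprintf("s%02d", which(depths >= 10000)))
})

test_that("global threshold arithmetic is a ceiling of fraction times total", {
  expect_identical(global_threshold_min_count(20476979, 1e-5), 205L)
  expect_identical(global_threshold_min_count(20476979, 0), 0L)
  expect_identical(global_threshold_min_count(1000, 0.005), 5L)
  expect_identical(global_threshold_min_count(999, 0.005), 5L)
  expect_identical(global_threshold_min_count(0, 0.5), 0L)
})

test_that("global OTU threshold retains exactly the OTUs reaching the cut-off", {
  m <- rbind(low = rep(51L, 4), edge = c(205L, 0L, 0L, 0L),
             high = rep(750L, 4))
  m["low", 1] <- 48L   # total 204: one read short
  colnames(m) <- paste0("s", 1:4)
  tab <- otu_table(m, as.Date("2016-01-01") + 0:3)
  kept <- apply_global_threshold(tab, 1e-5, total_reads = 20476979)
  expect_setequal(otu_ids(kept), c("edge", "high"))
  expect_identical(apply_global_threshold(tab, 0)$counts, tab$counts)

  # brute-force recount oracle on a random 200-OTU table
  tab <- random_table(200, 12, lambda = 3, seed = 11)
  kept <- apply_global_threshold(tab, 1e-3)
  min_count <- ceiling(1e-3 * sum(tab$counts))
  expect_setequal(otu_ids(kept),
                  rownames(tab$counts)[rowSums(tab$counts) >= min_count])

  # monotonicity: a larger fraction never enlarges the retained set
  prev <- otu_ids(tab)
  for (f in c(0, 1e-4, 1e-3, 1e-2, 0.1)) {
    cur <- otu_ids(apply_global_threshold(tab, f))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # idempotence at the default reference total
  once <- apply_global_threshold(tab, 1e-3)
  twice <- apply_global_threshold(once, 1e-3,
                                  total_reads = otu_grand_total(tab))
  expect_identical(twice$counts, once$counts)
})

test_that("trophic annotation applies most-specific-rank-first rule precedence", {
  tax <- taxonomy_table(
    c("o1", "o2", "o3"),
    c("Eukaryota;Alveolata;Dinoflagellata;Syndiniales;Dino-Group-II",
      "Eukaryota;Archaeplastida;Chlorophyta;Mamiellophyceae",
      "Eukaryota;Alveolata;Dinoflagellata;Dinophyceae;Gymnodiniales;Gymnodiniaceae;Amoebophrya"))
  rules <- trophic_lookup(
    rank = c("class", "class", "genus"),
    pattern = c("Syndiniales", "Dinophyceae", "Amoebophrya"),
    label = c("parasitoid", "non_parasitoid", "parasitoid"),
    source = c("lit1", "lit2", "lit3"))
  ann <- annotate_trophic(tax, rules)
  expect_identical(ann$label, c("parasitoid", "unknown", "parasitoid"))
  # o3: the genus rule (more specific) wins over the conflicting class rule
  expect_identical(ann$matched_rank[3], "genus")
  expect_identical(ann$source[1], "lit1")

  # within one rank, file order wins; prefix patterns match Dino-Groups
  rules2 <- trophic_lookup(rank = c("order", "order"),
                           pattern = c("Dino-Group", "Dino-Group-II"),
                           label = c("parasitoid", "non_parasitoid"))
  expect_identical(annotate_trophic(tax, rules2)$label[1], "parasitoid")
})

test_that("annotation summaries reproduce printed survey fractions", {
  labs <- rep(c("parasitoid", "unknown", "non_parasitoid"),
              c(6056, 33000, 59284 - 6056 - 33000))
  s <- annotation_summary(labs)
  expect_identical(s$n_otus_total, 59284L)
  expect_equal(s$pct_parasitoid, 10.2)
  expect_true(s$pct_unknown > 55)

  s2 <- annotation_summary(rep(c("parasitoid", "unknown"), c(461, 2790 - 461)))
  expect_equal(s2$pct_parasitoid, 16.5)
  expect_equal(annotation_summary(rep("non_parasitoid", 10))$pct_parasitoid, 0)
  # percentages recompute from counts under half-away-from-zero rounding
  expect_equal(s2$pct_unknown, round_half_away(100 * s2$n_unknown / 2790, 1))
  expect_equal(round_half_away(c(0.25, -0.25, 0.15), 1), c(0.3, -0.3, 0.2))
})

test_that("relative abundances divide by the configured denominator set", {
  m <- matrix(c(50L, 50L, 30L, 70L), 2,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  tab <- otu_table(m, as.Date("2016-01-01") + 0:1)
  ser <- relative_abundance(tab)
  expect_equal(ser$A$values, c(0.5, 0.3))

  # single-parasitoid denominator: its own series is constant 1
  only <- relative_abundance(tab, subjects = "A",
                             denominator_mode = "custom",
                             denominator_otus = "A")
  expect_equal(only$A$values, c(1, 1))

  # conservation: per-sample sum over all subjects is 1
  tab <- random_table(40, 15, seed = 3)
  all_ser <- relative_abundance(tab)
  sums <- Reduce(`+`, lapply(all_ser, `[[`, "values"))
  expect_true(all(abs(sums - 1) < 1e-9))

  # group map sums members before division
  grp <- relative_abundance(tab, subjects = list(g = otu_ids(tab)[1:5]))
  manual <- colSums(tab$counts[1:5, ]) / colSums(tab$counts)
  expect_equal(grp$g$values, unname(manual))

  # zero denominator flags the sample missing, with a warning
  m2 <- matrix(c(0L, 0L, 3L, 2L, 1L, 0L), 3,
               dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  tab2 <- otu_table(m2, as.Date("2016-01-01") + 0:1)
  expect_warning(z <- relative_abundance(tab2, subjects = "A",
                                         denominator_mode = "custom",
                                         denominator_otus = c("A", "B")),
                 "zero denominator")
  expect_true(is.na(z$A$values[1]))
  expect_equal(z$A$values[2], 2 / 3)
})

test_that("taxon aggregation conserves reads and groups unassigned OTUs", {
  tab <- random_table(30, 8, seed = 5)
  lineages <- paste0("Eukaryota;SG;Phylum", rep(1:4, length.out = 29))
  tax <- taxonomy_table(otu_ids(tab), c(lineages, ""))   # last OTU unassigned
  agg <- aggregate_by_taxon(tab, tax, "division")
  expect_identical(otu_grand_total(agg), otu_grand_total(tab))
  expect_true("unassigned" %in% otu_ids(agg))
  expect_identical(nrow(agg$counts), 5L)
  # single-OTU group equals that OTU's counts
  single <- aggregate_by_taxon(
    otu_table(tab$counts[1, , drop = FALSE], tab$sample_dates),
    tax, "division")
  expect_identical(unname(single$counts[1, ]), unname(tab$counts[1, ]))
})

test_that("phylum-level OTU counts of the parasitoid overview table behave", {
  tax <- table1_taxonomy()
  counts <- count_otus_by_rank(tax, "division")
  expect_identical(sum(counts), 461L)
  expect_identical(length(counts), 10L)
  expect_identical(names(counts)[1], "Dinoflagellata")
  expect_identical(as.integer(counts["Cercozoa"]), 140L)
})
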