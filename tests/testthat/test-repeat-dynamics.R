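# Repeat accounting, enrichment classification and density tracks.

rc <- function(family, chrom, start, end, superfamily = "Gypsy",
               complete = TRUE, genome = "tetraploid") {
  data.frame(family = family, superfamily = superfamily, chrom = chrom,
             start = start, end = end, complete = complete,
             genome_label = genome, subgenome = subgenome_of(chrom),
             stringsAsFactors = FALSE)
}

fam_stats <- function(family, partition, n_copies, total_bp,
                      superfamily = "Gypsy", n_complete = 1L) {
  data.frame(genome_label = "tetraploid", partition = partition,
             family = family, superfamily = superfamily, n_copies = n_copies,
             total_bp = total_bp, n_complete = n_complete,
             stringsAsFactors = FALSE)
}

test_that("overlapping same-family copies are merged for bp but counted as copies", {
  copies <- rbind(rc("f1", "Cq1A", 100, 200), rc("f1", "Cq1A", 150, 250))
  s <- summarize_repeats(copies)
  whole <- s[s$partition == "whole", ]
  expect_equal(whole$total_bp, 150)
  expect_equal(whole$n_copies, 2L)
  raw <- summarize_repeats(copies, bp_policy = "sum")
  expect_equal(raw$total_bp[raw$partition == "whole"], 200)
  expect_equal(nrow(summarize_repeats(copies[0, ])), 0)
})

test_that("subgenome partitions sum exactly to the whole-genome totals", {
  sim <- simulate_genomes(sim_config(seed = 12), sequences = FALSE)
  reps <- sim$repeats[sim$repeats$genome_label == "tetraploid", ]
  s <- summarize_repeats(reps)
  for (f in unique(s$family)) {
    parts <- s[s$family == f & s$partition != "whole", ]
    whole <- s[s$family == f & s$partition == "whole", ]
    expect_equal(sum(parts$total_bp), whole$total_bp, info = f)
    expect_equal(sum(parts$n_copies), whole$n_copies, info = f)
  }
})

test_that("enrichment classes follow the two-fold boundary and zero-count escapes", {
  s <- rbind(
    fam_stats("bEnr", "A", 100L, 5e5), fam_stats("bEnr", "B", 200L, 1e6),
    fam_stats("bEnr", "whole", 300L, 1.5e6),
    fam_stats("flat", "A", 150L, 5e5), fam_stats("flat", "B", 160L, 5e5),
    fam_stats("flat", "whole", 310L, 1e6),
    fam_stats("bOnly", "B", 50L, 2e5), fam_stats("bOnly", "whole", 50L, 2e5))
  e <- ltr_family_enrichment(s, avg_copy_threshold = 100)
  expect_equal(e$class[e$family == "bEnr"], "B_enriched")  # log2fc exactly 1
  expect_equal(e$log2fc[e$family == "bEnr"], 1)
  expect_equal(e$class[e$family == "flat"], "not_enriched")
  expect_equal(e$class[e$family == "bOnly"], "B_specific")
  expect_true(e$highly_repeated[e$family == "bEnr"])
  expect_false(e$highly_repeated[e$family == "bOnly"])
})

test_that("swapping subgenome labels mirrors enrichment calls", {
  sim <- simulate_genomes(sim_config(seed = 13), sequences = FALSE)
  reps <- sim$repeats[sim$repeats$genome_label == "tetraploid", ]
  s <- summarize_repeats(reps)
  swapped <- s
  swapped$partition <- ifelse(s$partition == "A", "B",
                              ifelse(s$partition == "B", "A", s$partition))
  e1 <- ltr_family_enrichment(s)
  e2 <- ltr_family_enrichment(swapped)
  e2 <- e2[match(e1$family, e2$family), ]
  flip <- c(A_enriched = "B_enriched", B_enriched = "A_enriched",
            A_specific = "B_specific", B_specific = "A_specific",
            not_enriched = "not_enriched")
  expect_equal(unname(flip[e1$class]), e2$class)
  expect_equal(e1$log2fc, -e2$log2fc)
  expect_equal(e1$highly_repeated, e2$highly_repeated)
})

test_that("TE-space attribution degenerates cleanly for equal subgenomes", {
  a <- fam_stats("f1", "A", 10L, 1e6)
  res <- te_space_attribution(a, a, size_diff_bp = 5e6)
  expect_equal(res$te_diff_bp, 0)
  expect_equal(res$pct_explained, 0)
  expect_true(is.na(te_space_attribution(a, a, size_diff_bp = 0)$pct_explained))
})

test_that("window density counts by start position and pads empty chromosomes", {
  feats <- data.frame(chrom = "Cq1A",
                      start = c(1e5, 5e5, 9.9e5, 9.99999e5, 1.5e6),
                      end = c(1e5, 5e5, 9.9e5, 1.000005e6, 1.5e6) + 100)
  d <- window_density(feats, c(Cq1A = 2.5e6, Cq1B = 2.5e6), window_bp = 1e6)
  cq1a <- d[d$chrom == "Cq1A", ]
  # the straddling feature belongs to the window containing its start
  expect_equal(cq1a$count, c(4L, 1L, 0L))
  expect_equal(cq1a$end[3], 2.5e6)
  expect_equal(d$count[d$chrom == "Cq1B"], rep(0L, 3))
})

test_that("diploid-relative dynamics report reductions and expansions", {
  sub <- fam_stats("f1", "whole", 60L, 3e5)
  dip <- fam_stats("f1", "whole", 100L, 5e5)
  res <- dynamics_vs_diploid(sub, dip)
  expect_equal(res$by_superfamily$delta_copies, -40)
  expect_equal(res$by_superfamily$label, "contraction")
  expect_equal(res$summary$pct_reduction, 100)
  same <- dynamics_vs_diploid(sub, sub)
  expect_equal(same$by_superfamily$delta_copies, 0)
  expect_equal(same$summary$net_bp_change, 0)
})

test_that("a planted subgenome expansion is flagged against the diploid", {
  sim <- simulate_genomes(sim_config(seed = 14), sequences = FALSE)
  reps <- sim$repeats
  sB <- summarize_repeats(reps[reps$genome_label == "tetraploid" &
                                 reps$subgenome == "B", ])
  sDipB <- summarize_repeats(reps[reps$genome_label == "diploidB", ])
  res <- dynamics_vs_diploid(sB[sB$partition == "B", ],
                             sDipB[sDipB$partition == "whole", ])
  # GypsyFam1 carries a planted 2x expansion in B (160 copies vs 80 diploid)
  gypsy <- res$by_superfamily[res$by_superfamily$superfamily == "Gypsy", ]
  expect_equal(gypsy$label, "expansion")
  expect_gt(gypsy$delta_bp, 0)
})

test_that("planted family biases classify to the planted side", {
  for (seed in 1:10) {
    sim <- simulate_genomes(sim_config(seed = seed), sequences = FALSE)
    reps <- sim$repeats[sim$repeats$genome_label == "tetraploid", ]
    e <- ltr_family_enrichment(summarize_repeats(reps))
    truth <- sim$truth$families
    for (f in e$family) {
      expect_equal(e$class[e$family == f], truth$class[truth$family == f],
                   info = paste("seed", seed, f))
    }
  }
})
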