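# Discordant-pair counting and inversion genotyping rules.

pair_row <- function(id, pos1, pos2, chrom = "Cq3B", rl = 100L) {
  data.frame(read_id = id, chrom1 = chrom, pos1 = pos1, end1 = pos1 + rl,
             mapq1 = 60L, chrom2 = chrom, pos2 = pos2, end2 = pos2 + rl,
             mapq2 = 60L, insert = pos2 + rl - pos1, proper = FALSE,
             stringsAsFactors = FALSE)
}

paper_bp <- function() {
  breakpoint_pair("Cq3B", 11136405, 63361214,
                  insert_min = 52223700, insert_max = 52225600)
}

test_that("the insert gate must contain the breakpoint span", {
  bp <- paper_bp()
  expect_lt(bp$insert_min, bp$span)
  expect_gt(bp$insert_max, bp$span)
  expect_equal(bp$span, 52224809)
  expect_error(breakpoint_pair("c", 1000, 2000, insert_min = 1, insert_max = 10),
               "gate")
  expect_error(breakpoint_pair("c", 2000, 1000), "pos_left")
})

test_that("discordant pairs are counted only inside both windows and the gate", {
  bp <- paper_bp()
  inside <- pair_row("p1", 11136300L, 63361150L)
  expect_equal(count_discordant_pairs(inside, bp), 1L)
  # inside both windows but with an insert above the gate
  gate_out <- pair_row("p2", 11135905L, 63361714L)
  expect_equal(count_discordant_pairs(gate_out, bp), 0L)
  off_window <- pair_row("p3", 11130000L, 63361150L)
  expect_equal(count_discordant_pairs(off_window, bp), 0L)
  expect_equal(count_discordant_pairs(inside[0, ], bp), 0L)
  # mate order must not matter
  swapped <- inside
  swapped[, c("pos1", "end1", "pos2", "end2")] <-
    swapped[, c("pos2", "end2", "pos1", "end1")]
  expect_equal(count_discordant_pairs(swapped, bp), 1L)
})

test_that("counting is permutation-invariant and idempotent", {
  bp <- paper_bp()
  pairs <- rbind(pair_row("p1", 11136300L, 63361150L),
                 pair_row("p2", 11136500L, 63361300L),
                 pair_row("p3", 5000000L, 5010000L))
  n1 <- count_discordant_pairs(pairs, bp)
  n2 <- count_discordant_pairs(pairs[c(3, 1, 2), ], bp)
  expect_equal(n1, 2L)
  expect_equal(n1, n2)
  expect_equal(count_discordant_pairs(pairs, bp), n1)
})

test_that("genotype calls follow the discordant/spanning decision rule", {
  bp <- breakpoint_pair("Cq3B", 100000, 300000)
  glen <- 400000
  disc <- rbind(pair_row("d1", 99800L, 299800L),
                pair_row("d2", 99700L, 299900L),
                pair_row("d3", 99900L, 299850L))
  # inflate depth with background pairs far from the breakpoints
  bg <- pair_row(paste0("bg", 1:10000), 10000L + 1:10000, 10300L + 1:10000)
  absent <- genotype_inversion(rbind(disc, bg), bp, "a1", genome_length = glen)
  expect_equal(absent$call, "absent")
  expect_equal(absent$n_discordant, 3L)

  span <- rbind(pair_row("s1", 99950L, 100150L),   # both mates around pos_left
                pair_row("s2", 299950L, 300100L))
  span$insert <- 300L                              # concordant geometry
  present <- genotype_inversion(rbind(span, bg), bp, "a2", genome_length = glen)
  expect_equal(present$call, "present")
  expect_gte(present$n_span_left, 1L)
  expect_gte(present$n_span_right, 1L)

  left_only <- rbind(pair_row("s1", 99950L, 100150L))
  inc <- genotype_inversion(rbind(left_only, bg), bp, "a3", genome_length = glen)
  expect_equal(inc$call, "inconclusive")
  expect_equal(inc$n_span_right, 0L)
})

test_that("low-coverage accessions are excluded with a reason", {
  bp <- breakpoint_pair("Cq3B", 100000, 300000)
  thin <- pair_row("p1", 99950L, 100150L)
  call <- genotype_inversion(thin, bp, "lowcov", genome_length = 400000)
  expect_true(call$excluded)
  expect_true(is.na(call$call))
  expect_match(call$reason, "coverage")
})

test_that("genotype summary reports counts and within-ecotype percentages", {
  calls <- data.frame(
    accession = sprintf("a%02d", 1:6),
    call = c("present", "absent", "absent", "inconclusive", "absent", "present"),
    excluded = FALSE, stringsAsFactors = FALSE)
  eco <- setNames(c(rep("coastal", 3), rep("highland", 3)), calls$accession)
  s <- genotype_summary(calls, eco)
  expect_equal(s$n[s$ecotype == "coastal" & s$call == "absent"], 2L)
  expect_equal(s$pct[s$ecotype == "coastal" & s$call == "absent"], 100 * 2 / 3)
  expect_equal(sum(s$n), 6L)
  expect_error(genotype_summary(calls, eco[-1]), "unlabeled")
  expect_equal(nrow(genotype_summary(calls[0, ], eco)), 0)
})

test_that("breakpoints are recovered from pooled non-carrier alignments", {
  cfg <- sim_config(seed = 21, panel = sim_default_panel(0, 3, depth = 10))
  L <- cfg$chrom_length
  bpt <- list(chrom = "Cq3B", pos_left = as.integer(0.25 * L),
              pos_right = as.integer(0.75 * L))
  pan <- simulate_panel_alignments(cfg, bpt)
  pooled <- do.call(rbind, pan$pairs)
  bp <- locate_breakpoints(pooled,
                           c(bpt$pos_left - 2000, bpt$pos_left + 2000),
                           c(bpt$pos_right - 2000, bpt$pos_right + 2000),
                           "Cq3B")
  expect_lte(abs(bp$pos_left - bpt$pos_left), cfg$read_length)
  expect_lte(abs(bp$pos_right - bpt$pos_right), cfg$read_length)
  # uniform coverage with no discordant pairs is an error, not a guess
  conc <- pooled[pooled$proper, , drop = FALSE]
  expect_error(locate_breakpoints(conc,
                                  c(1000, 3000), c(50000, 52000), "Cq3B"),
               "no breakpoint signal")
})
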