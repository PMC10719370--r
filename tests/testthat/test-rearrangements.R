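# Rearrangement calling against planted synthetic truth and hand-built
# block configurations.

fake_block <- function(id, cq, cs, sq, eq, ss, es, n = 10,
                       orientation = "forward") {
  df <- data.frame(block_id = id, genome_q = "tetraploid",
                   genome_s = "tetraploid", chrom_q = cq, chrom_s = cs,
                   orientation = orientation, n_anchors = n, score = 1000,
                   start_q = sq, end_q = eq, start_s = ss, end_s = es,
                   rank_q_min = 0L, rank_q_max = n - 1L, rank_s_min = 0L,
                   rank_s_max = n - 1L, stringsAsFactors = FALSE)
  df$anchors <- list(data.frame(
    gene_q = sprintf("%s_g%02d", cq, 1:n), gene_s = sprintf("%s_g%02d", cs, 1:n),
    rank_q = 0:(n - 1), rank_s = 0:(n - 1), score = 100,
    stringsAsFactors = FALSE))
  df
}

sim_blocks <- function(seed = 1, events = sim_default_events()) {
  sim <- simulate_genomes(sim_config(seed = seed, events = events),
                          sequences = FALSE)
  tet <- sim$genes$tetraploid
  tetA <- tet[tet$subgenome == "A", ]; tetB <- tet[tet$subgenome == "B", ]
  chain <- function(a, gq, gs) {
    chain_collinear_blocks(dedupe_anchors(a, gq, gs), gq, gs)
  }
  list(sim = sim, tet = tet,
       self = chain(sim$anchors$self, tetA, tetB),
       dip = list(A = chain(sim$anchors$A, tetA, sim$genes$diploidA),
                  B = chain(sim$anchors$B, tetB, sim$genes$diploidB)))
}

test_that("a fully collinear genome yields no rearrangement calls", {
  x <- sim_blocks(seed = 6, events = list())
  expect_equal(nrow(detect_translocations(x$self, x$dip)), 0)
  expect_equal(nrow(detect_inversions(x$self)), 0)
  expect_equal(nrow(detect_segmental_duplications(x$self, x$tet)), 0)
})

test_that("planted events are recovered with correct kind and near-exact endpoints", {
  x <- sim_blocks(seed = 8)
  ev <- rbind(detect_translocations(x$self, x$dip),
              detect_inversions(x$self),
              detect_segmental_duplications(x$self, x$tet))
  truth <- x$sim$truth$events
  expect_equal(nrow(ev), nrow(truth))      # no false positives
  tol <- 2 * x$sim$config$chrom_length / x$sim$config$genes_per_chrom
  for (i in seq_len(nrow(truth))) {
    hit <- ev[ev$kind == truth$kind[i], , drop = FALSE]
    expect_equal(nrow(hit), 1, info = truth$kind[i])
    # match the truth interval against whichever event interval shares its
    # chromosome (inversions carry both homoeologous intervals)
    cand <- rbind(
      data.frame(chrom = hit$chrom1, start = hit$start1, end = hit$end1),
      data.frame(chrom = hit$chrom2, start = hit$start2, end = hit$end2))
    cand <- cand[!is.na(cand$chrom) & cand$chrom == truth$chrom1[i], ,
                 drop = FALSE]
    expect_gte(nrow(cand), 1)
    d <- abs(cand$start - truth$start1[i]) + abs(cand$end - truth$end1[i])
    expect_lt(min(d), 2 * tol)
    if (!is.na(truth$chrom2[i]) && truth$kind[i] != "inversion") {
      cand2 <- rbind(
        data.frame(chrom = hit$chrom1, start = hit$start1, end = hit$end1),
        data.frame(chrom = hit$chrom2, start = hit$start2, end = hit$end2))
      cand2 <- cand2[!is.na(cand2$chrom) & cand2$chrom == truth$chrom2[i], ,
                     drop = FALSE]
      d2 <- abs(cand2$start - truth$start2[i]) + abs(cand2$end - truth$end2[i])
      expect_lt(min(d2), 2 * tol)
    }
  }
})

test_that("a one-way insertion gives a single, not reciprocal, translocation", {
  blocks <- rbind(
    fake_block("b1", "Cq4A", "Cq2B", 200000, 300000, 200000, 300000),
    fake_block("b2", "Cq4A", "Cq4B", 0, 190000, 0, 190000))
  dip <- list(
    A = fake_block("dA", "Cq4A", "Pa4", 0, 400000, 0, 400000),
    B = fake_block("dB", "Cq2B", "Su2", 0, 100000, 0, 100000))
  ev <- detect_translocations(blocks, dip)
  expect_equal(ev$kind, "translocation")
  expect_equal(ev$chrom1, "Cq2B")
  expect_equal(ev$scope, "intra_subgenome")  # exchange pair Cq2B/Cq4B
})

test_that("missing diploid evidence flags the call instead of dropping it", {
  blocks <- fake_block("b1", "Cq1A", "Cq2B", 0, 100000, 0, 100000)
  ev <- detect_translocations(blocks, list())
  expect_equal(ev$kind, "translocation")
  expect_equal(ev$note, "diploid-unconfirmed")
})

test_that("bp accounting merges overlapping event intervals before summation", {
  ev <- rbind(
    polyrearrange:::new_event("inversion", "Cq1A", 0, 1000000),
    polyrearrange:::new_event("inversion", "Cq1A", 500000, 1500000),
    polyrearrange:::new_event("translocation", "Cq1B", 0, 2000000, n_genes = 150L,
              scope = "intra_subgenome"))
  ev <- polyrearrange:::finish_events(ev)
  tot <- rearrangement_totals(ev, c(A = 1e7, B = 1e7))
  expect_equal(tot$by_subgenome$bp[tot$by_subgenome$subgenome == "A"], 1500000)
  expect_equal(tot$by_subgenome$bp[tot$by_subgenome$subgenome == "B"], 2000000)
  expect_equal(tot$total_bp, 3500000)
  # 2 Mb / 150 genes exceeds both major thresholds
  expect_true(ev$major[ev$kind == "translocation"])
  expect_false(any(ev$major[ev$kind == "inversion"]))
  empty <- rearrangement_totals(polyrearrange:::finish_events(polyrearrange:::empty_events()), c(A = 1e7, B = 1e7))
  expect_equal(empty$total_bp, 0)
})

test_that("mapping-swap scan flags only the planted exchange windows", {
  clean <- simulate_diploid_readmap(swapped = NULL)
  expect_equal(nrow(detect_mapping_swaps(clean)), 0)
  tr <- simulate_diploid_readmap(swapped = c(41, 50))
  det <- detect_mapping_swaps(tr)
  expect_equal(nrow(det), 1)
  expect_equal(det$start, 40e6)
  expect_equal(det$end, 50e6)
  expect_equal(det$n_windows, 10L)
})
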