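# Anchor dedup, DP chaining against small closed-form cases, and the
# exhaustive-chain oracle property.

perfect_instance <- function(n, inverted = FALSE, score = 100) {
  rs <- if (inverted) rev(seq_len(n)) - 1L else seq_len(n) - 1L
  a <- data.frame(gene_q = sprintf("q%03d", seq_len(n) - 1L),
                  gene_s = sprintf("s%03d", rs),
                  rank_q = seq_len(n) - 1L, rank_s = rs,
                  start_q = (seq_len(n) - 1L) * 1000L, start_s = rs * 1000L,
                  score = score + seq_len(n) / 100, stringsAsFactors = FALSE)
  instance_gene_tables(a)
}

test_that("top-n limiting keeps the best-scoring subject hits per query", {
  inst <- perfect_instance(20)
  # non-consecutive subject ranks so the tandem-collapse rule stays out of play
  ranks <- c(2L, 5L, 8L, 11L, 14L, 17L, 19L)
  hits <- data.frame(gene_q = "q000", gene_s = sprintf("s%03d", ranks),
                     pident = 95, evalue = 1e-50,
                     score = 100 + seq_along(ranks), stringsAsFactors = FALSE)
  kept <- dedupe_anchors(hits, inst$genes_q, inst$genes_s, top_n = 5)
  expect_equal(nrow(kept), 5)
  expect_setequal(kept$gene_s, sprintf("s%03d", ranks[3:7]))
  expect_equal(nrow(dedupe_anchors(kept[0, ], inst$genes_q, inst$genes_s)), 0)
})

test_that("tandem arrays hitting one partner collapse to the best copy", {
  inst <- perfect_instance(10)
  # query genes at consecutive ranks 4 and 5 both hit s007
  tandem <- data.frame(gene_q = c("q004", "q005"), gene_s = "s007",
                       pident = 95, evalue = 1e-50, score = c(120, 150),
                       stringsAsFactors = FALSE)
  kept <- dedupe_anchors(tandem, inst$genes_q, inst$genes_s)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$gene_q, "q005")
})

test_that("chaining respects the match_size threshold and orientation", {
  inst <- perfect_instance(10)
  b <- chain_collinear_blocks(inst$anchors, inst$genes_q, inst$genes_s,
                              match_size = 8)
  expect_equal(nrow(b), 1)
  expect_equal(b$orientation, "forward")
  expect_equal(b$n_anchors, 10L)

  short <- perfect_instance(7)
  expect_equal(nrow(chain_collinear_blocks(short$anchors, short$genes_q,
                                           short$genes_s, match_size = 8)), 0)
  inv <- perfect_instance(10, inverted = TRUE)
  bi <- chain_collinear_blocks(inv$anchors, inv$genes_q, inv$genes_s,
                               match_size = 8)
  expect_equal(bi$orientation, "inverted")
  expect_error(chain_collinear_blocks(inst$anchors, inst$genes_q,
                                      inst$genes_s, match_size = 1),
               "match_size")
})

test_that("a gap larger than max_gap_genes splits a chain", {
  inst <- perfect_instance(20)
  # remove anchors 9..12, leaving a 4-rank hole: chains of 8 and 8 with gap 4
  a <- inst$anchors[-(9:12), ]
  whole <- chain_collinear_blocks(a, inst$genes_q, inst$genes_s,
                                  match_size = 4, max_gap_genes = 25)
  expect_equal(nrow(whole), 1)
  split <- chain_collinear_blocks(a, inst$genes_q, inst$genes_s,
                                  match_size = 4, max_gap_genes = 3)
  expect_equal(nrow(split), 2)
})

test_that("DP block set equals exhaustive maximal-chain enumeration", {
  for (k in 1:60) {
    n <- 5 + (k %% 16)
    a <- random_anchor_instance(n, seed = 1000 + k)
    inst <- instance_gene_tables(a)
    blk <- chain_collinear_blocks(inst$anchors, inst$genes_q, inst$genes_s,
                                  match_size = 4, max_gap_genes = 25)
    expect_identical(blocks_as_sets(blk), oracle_as_sets(
      oracle_blocks(a, match_size = 4, max_gap = 25), a),
      info = paste("instance", k))
  }
})

test_that("block orientation matches the sign of the anchor rank relation and no anchor repeats", {
  sim <- simulate_genomes(sim_config(seed = 2), sequences = FALSE)
  tet <- sim$genes$tetraploid
  tetA <- tet[tet$subgenome == "A", ]; tetB <- tet[tet$subgenome == "B", ]
  b <- chain_collinear_blocks(dedupe_anchors(sim$anchors$self, tetA, tetB),
                              tetA, tetB)
  seen <- character(0)
  for (i in seq_len(nrow(b))) {
    m <- b$anchors[[i]]
    slope <- sign(cor(m$rank_q, m$rank_s, method = "spearman"))
    expect_equal(unname(slope), if (b$orientation[i] == "inverted") -1 else 1)
    key <- paste(m$gene_q, m$gene_s)
    expect_length(intersect(seen, key), 0)
    seen <- c(seen, key)
  }
})

test_that("raising match_size never increases the number of blocks", {
  for (k in 1:10) {
    a <- random_anchor_instance(18, seed = 2000 + k)
    inst <- instance_gene_tables(a)
    counts <- vapply(c(3, 5, 8), function(ms) {
      nrow(chain_collinear_blocks(inst$anchors, inst$genes_q, inst$genes_s,
                                  match_size = ms))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("collinearity summary covers the zero-, partial- and all-collinear cases", {
  inst <- perfect_instance(10)
  b <- chain_collinear_blocks(inst$anchors, inst$genes_q, inst$genes_s,
                              match_size = 8)
  s <- collinearity_summary(b, c("gq vs gs" = 20))
  expect_equal(s$n_collinear, 20)  # both sides of every anchor
  expect_equal(s$pct, 100)
  s0 <- collinearity_summary(b[0, ], c("gq vs gs" = 20))
  expect_equal(s0$pct, 0)
  expect_true(is.na(collinear_fraction(0, 0)))
})
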