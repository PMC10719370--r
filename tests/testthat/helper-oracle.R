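# Independent brute-force oracle for collinear-block chaining: exhaustively
# enumerates maximal monotone chains (source-to-sink paths of the anchor DAG
# under the gap rule) and replays the same greedy best-chain-first extraction.
# Anchor scores in test instances are kept above the largest possible gap
# penalty (2 * max_gap) so the optimum chain is always maximal and the
# enumeration is exhaustive over candidates.

enum_max_chains <- function(rq, rs, max_gap) {
  n <- length(rq)
  succ <- lapply(seq_len(n), function(i) {
    which(rq > rq[i] & rs > rs[i] &
            rq - rq[i] - 1 <= max_gap & rs - rs[i] - 1 <= max_gap)
  })
  has_pred <- rep(FALSE, n)
  for (i in seq_len(n)) has_pred[succ[[i]]] <- TRUE
  chains <- list()
  dfs <- function(chain, i) {
    nxt <- succ[[i]]
    if (!length(nxt)) {
      chains[[length(chains) + 1]] <<- chain
      return(invisible())
    }
    for (j in nxt) dfs(c(chain, j), j)
  }
  for (i in which(!has_pred)) dfs(i, i)
  chains
}

chain_score <- function(a, idx, inverted) {
  rs <- if (inverted) -a$rank_s[idx] else a$rank_s[idx]
  rq <- a$rank_q[idx]
  sum(a$score[idx]) -
    sum(rq[-1] - rq[-length(rq)] - 1) -
    sum(rs[-1] - rs[-length(rs)] - 1)
}

oracle_blocks <- function(a, match_size = 8, max_gap = 25) {
  alive <- rep(TRUE, nrow(a))
  blocks <- list()
  repeat {
    best <- NULL
    idx <- which(alive)
    if (length(idx) < match_size) break
    for (orient in c("forward", "inverted")) {
      inverted <- orient == "inverted"
      rs <- if (inverted) -a$rank_s[idx] else a$rank_s[idx]
      for (p in enum_max_chains(a$rank_q[idx], rs, max_gap)) {
        if (length(p) < match_size) next
        cand <- list(idx = idx[p], orientation = orient,
                     score = chain_score(a, idx[p], inverted))
        if (is.null(best) || cand$score > best$score + 1e-9 ||
            (abs(cand$score - best$score) < 1e-9 &&
               a$start_q[cand$idx[1]] < a$start_q[best$idx[1]])) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    blocks[[length(blocks) + 1]] <- best
    alive[best$idx] <- FALSE
  }
  blocks
}

# random chaining instance: two ranked gene sets on one chromosome pair plus
# n anchors with continuous scores (ties measure-zero)
random_anchor_instance <- function(n, rank_space = 3L * n, seed = 1) {
  withr::with_seed(seed, {
    rq <- sample.int(rank_space, n, replace = FALSE) - 1L
    rs <- sample.int(rank_space, n, replace = FALSE) - 1L
    data.frame(
      gene_q = sprintf("q%03d", rq),
      gene_s = sprintf("s%03d", rs),
      rank_q = rq, rank_s = rs,
      start_q = rq * 1000L, start_s = rs * 1000L,
      score = runif(n, 50, 100), stringsAsFactors = FALSE)
  })
}

# wrap a raw instance into gene tables + anchor table usable by the package
instance_gene_tables <- function(a) {
  mk <- function(ids, ranks, starts, chrom, genome) {
    df <- data.frame(gene_id = ids, chrom = chrom, start = starts,
                     end = starts + 500L, strand = "+",
                     genome_label = genome, subgenome = "none",
                     rank = ranks, stringsAsFactors = FALSE)
    df[!duplicated(df$gene_id), ]
  }
  gq <- mk(a$gene_q, a$rank_q, a$start_q, "chrQ", "gq")
  gs <- mk(a$gene_s, a$rank_s, a$start_s, "chrS", "gs")
  list(genes_q = gq, genes_s = gs,
       anchors = data.frame(gene_q = a$gene_q, gene_s = a$gene_s,
                            pident = 95, evalue = 1e-50, score = a$score,
                            stringsAsFactors = FALSE))
}

blocks_as_sets <- function(blocks) {
  if (nrow(blocks) == 0) return(list())
  sets <- lapply(seq_len(nrow(blocks)), function(i) {
    m <- blocks$anchors[[i]]
    list(orientation = blocks$orientation[i],
         pairs = sort(paste(m$gene_q, m$gene_s)))
  })
  sets[order(vapply(sets, function(s) s$pairs[1], ""))]
}

oracle_as_sets <- function(oblocks, a) {
  sets <- lapply(oblocks, function(b) {
    list(orientation = b$orientation,
         pairs = sort(paste(a$gene_q[b$idx], a$gene_s[b$idx])))
  })
  sets[order(vapply(sets, function(s) s$pairs[1], ""))]
}
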