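# Collinear-block chaining over gene-rank space.
#
# Anchors (homologous gene pairs) are chained per chromosome pair by dynamic
# programming in rank coordinates, separately for forward and inverted
# orientation; blocks must contain at least `match_size` anchors, the minimum
# number of gene pairs required to call a collinearity block.

#' Attach gene coordinates and ranks to anchor pairs
#'
#' @param anchors data.frame from [read_blast_tab()].
#' @param genes_q,genes_s gene tables from [read_gff3()] for the query and
#'   subject genomes (may be the same table for self-comparison).
#' @return anchors with `chrom_q`, `rank_q`, `start_q`, `end_q` and the
#'   corresponding subject columns; anchors whose genes are unknown raise an
#'   error.
#' @export
anchor_coords <- function(anchors, genes_q, genes_s) {
  iq <- match(anchors$gene_q, genes_q$gene_id)
  is <- match(anchors$gene_s, genes_s$gene_id)
  if (anyNA(iq) || anyNA(is)) {
    bad <- c(anchors$gene_q[is.na(iq)], anchors$gene_s[is.na(is)])
    stop("anchors reference unknown genes, e.g. ", bad[1])
  }
  cbind(anchors,
        data.frame(chrom_q = genes_q$chrom[iq], rank_q = genes_q$rank[iq],
                   start_q = genes_q$start[iq], end_q = genes_q$end[iq],
                   chrom_s = genes_s$chrom[is], rank_s = genes_s$rank[is],
                   start_s = genes_s$start[is], end_s = genes_s$end[is],
                   stringsAsFactors = FALSE))
}

#' Limit hits per query and collapse tandem arrays
#'
#' Keeps at most `top_n` subject partners per query gene (best bit score
#' first), then collapses tandem arrays -- runs of consecutive gene ranks on
#' one chromosome all hitting the same partner gene -- to their best-scoring
#' representative, on both the query and the subject side.
#'
#' @param anchors data.frame from [read_blast_tab()].
#' @param genes_q,genes_s gene tables.
#' @param top_n subject genes retained per query gene (default 5, the usual
#'   alignment-report limit).
#' @return filtered anchor data.frame (without coordinate columns).
#' @export
dedupe_anchors <- function(anchors, genes_q, genes_s, top_n = 5) {
  if (nrow(anchors) == 0) return(anchors)
  a <- anchor_coords(anchors, genes_q, genes_s)
  a <- a[order(a$gene_q, -a$score), , drop = FALSE]
  keep <- stats::ave(seq_len(nrow(a)), a$gene_q, FUN = seq_along) <= top_n
  a <- a[keep, , drop = FALSE]
  collapse <- function(a, rank_col, chrom_col, partner_col) {
    a <- a[order(a[[partner_col]], a[[chrom_col]], a[[rank_col]]), , drop = FALSE]
    n <- nrow(a)
    if (n <= 1) return(a)
    new_run <- c(TRUE, !(a[[partner_col]][-1] == a[[partner_col]][-n] &
                         a[[chrom_col]][-1] == a[[chrom_col]][-n] &
                         a[[rank_col]][-1] == a[[rank_col]][-n] + 1L))
    run <- cumsum(new_run)
    keep <- vapply(split(seq_len(n), run),
                   function(i) i[which.max(a$score[i])], integer(1))
    a[sort(keep), , drop = FALSE]
  }
  a <- collapse(a, "rank_q", "chrom_q", "gene_s")
  a <- collapse(a, "rank_s", "chrom_s", "gene_q")
  rownames(a) <- NULL
  a[, setdiff(names(a), c("chrom_q", "rank_q", "start_q", "end_q",
                          "chrom_s", "rank_s", "start_s", "end_s"))]
}

# Best-scoring chain among anchors of one chromosome pair, one orientation.
# Chain score = sum of anchor scores minus 1 per skipped gene rank on either
# axis; both rank gaps must be <= max_gap. Returns NULL or a list with the
# member indices (in input order) and the chain score.
best_chain_dp <- function(rq, rs, score, start_q, start_s, max_gap, match_size,
                          inverted = FALSE) {
  n <- length(rq)
  if (n < match_size) return(NULL)
  ts <- if (inverted) -rs else rs
  ord <- order(rq, ts)
  rqo <- rq[ord]; tso <- ts[ord]; sco <- score[ord]
  m <- match_size
  NEG <- -Inf
  dp <- matrix(NEG, n, m)        # dp[i,k]: best chain ending at i, k anchors (k=m: >=m)
  par_i <- matrix(0L, n, m); par_k <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    dp[i, 1] <- sco[i]
    if (i == 1) next
    j <- seq_len(i - 1)
    gq <- rqo[i] - rqo[j] - 1L
    gs <- tso[i] - tso[j] - 1L
    ok <- which(gq >= 0L & gs >= 0L & gq <= max_gap & gs <= max_gap &
                rqo[j] < rqo[i] & tso[j] < tso[i])
    if (!length(ok)) next
    pen <- gq[ok] + gs[ok]
    for (k in 2:m) {
      cand <- dp[ok, k - 1] - pen
      if (k == m) cand <- pmax(cand, dp[ok, m] - pen)
      b <- which.max(cand)
      if (cand[b] > NEG) {
        dp[i, k] <- sco[i] + cand[b]
        par_i[i, k] <- ok[b]
        pk <- k - 1L
        if (k == m && dp[ok[b], m] - pen[b] >= dp[ok[b], m - 1] - pen[b] &&
            is.finite(dp[ok[b], m])) pk <- m
        par_k[i, k] <- pk
      }
    }
  }
  ends <- which(is.finite(dp[, m]))
  if (!length(ends)) return(NULL)
  best_sc <- max(dp[ends, m])
  cands <- ends[dp[ends, m] == best_sc]
  # trace back each tied candidate; tie-break on leftmost query then subject start
  trace <- function(i) {
    k <- m; path <- integer(0)
    while (i > 0L) {
      path <- c(i, path)
      ni <- par_i[i, max(k, 1L)]; nk <- par_k[i, max(k, 1L)]
      if (k == 1L) break
      i <- ni; k <- nk
    }
    path
  }
  paths <- lapply(cands, trace)
  firsts <- vapply(paths, `[`, 0L, 1L)
  key <- order(start_q[ord][firsts], start_s[ord][firsts])
  path <- paths[[key[1]]]
  list(idx = ord[path], score = best_sc)
}

#' Chain anchors into orientation-signed collinear blocks
#'
#' Dynamic-programming chaining over anchor rank space, per chromosome pair.
#' A chain extends only while both rank gaps are at most `max_gap_genes`;
#' forward and inverted orientations are chained separately; chains shorter
#' than `match_size` anchors are discarded. Blocks are extracted greedily
#' (best-scoring chain first, ties broken by leftmost query start) so each
#' anchor belongs to at most one block.
#'
#' @param anchors data.frame of anchor pairs (after [dedupe_anchors()]).
#' @param genes_q,genes_s gene tables.
#' @param match_size minimum number of gene pairs per block (default 8).
#' @param max_gap_genes maximum number of skipped gene ranks between
#'   consecutive anchors (default 25, the common default of collinearity
#'   chaining tools run with default parameters).
#' @return data.frame of blocks: `block_id`, `genome_q`, `genome_s`,
#'   `chrom_q`, `chrom_s`, `orientation` (`forward`/`inverted`), `n_anchors`,
#'   `score`, spans `start_q`, `end_q`, `start_s`, `end_s`, and a list-column
#'   `anchors` holding the member anchor table (with ranks).
#' @export
chain_collinear_blocks <- function(anchors, genes_q, genes_s, match_size = 8,
                                   max_gap_genes = 25) {
  if (match_size < 2) stop("match_size must be >= 2")
  if (nrow(anchors) == 0) return(empty_blocks())
  a <- anchor_coords(anchors, genes_q, genes_s)
  a$genome_q <- genes_q$genome_label[match(a$gene_q, genes_q$gene_id)]
  a$genome_s <- genes_s$genome_label[match(a$gene_s, genes_s$gene_id)]
  out <- list()
  for (pair in split(a, paste(a$chrom_q, a$chrom_s, sep = "\r"))) {
    alive <- rep(TRUE, nrow(pair))
    repeat {
      idx <- which(alive)
      if (length(idx) < match_size) break
      p <- pair[idx, ]
      cf <- best_chain_dp(p$rank_q, p$rank_s, p$score, p$start_q, p$start_s,
                          max_gap_genes, match_size, inverted = FALSE)
      ci <- best_chain_dp(p$rank_q, p$rank_s, p$score, p$start_q, p$start_s,
                          max_gap_genes, match_size, inverted = TRUE)
      pick <- NULL; orientation <- NULL
      better <- function(x, y) {
        # x strictly preferred over y
        if (is.null(y)) return(TRUE)
        if (x$score != y$score) return(x$score > y$score)
        p$start_q[x$idx[1]] < p$start_q[y$idx[1]]
      }
      if (!is.null(cf) && better(cf, ci)) { pick <- cf; orientation <- "forward" }
      else if (!is.null(ci)) { pick <- ci; orientation <- "inverted" }
      if (is.null(pick)) break
      mem <- p[pick$idx, ]
      out[[length(out) + 1]] <- data.frame(
        genome_q = mem$genome_q[1], genome_s = mem$genome_s[1],
        chrom_q = mem$chrom_q[1], chrom_s = mem$chrom_s[1],
        orientation = orientation, n_anchors = nrow(mem), score = pick$score,
        start_q = min(mem$start_q), end_q = max(mem$end_q),
        start_s = min(mem$start_s), end_s = max(mem$end_s),
        rank_q_min = min(mem$rank_q), rank_q_max = max(mem$rank_q),
        rank_s_min = min(mem$rank_s), rank_s_max = max(mem$rank_s),
        stringsAsFactors = FALSE)
      out[[length(out)]]$anchors <- list(mem[, c("gene_q", "gene_s", "rank_q",
                                                 "rank_s", "score")])
      alive[idx[pick$idx]] <- FALSE
    }
  }
  if (!length(out)) return(empty_blocks())
  blocks <- do.call(rbind, out)
  blocks <- blocks[order(blocks$chrom_q, blocks$start_q, blocks$chrom_s,
                         blocks$start_s), , drop = FALSE]
  blocks$block_id <- sprintf("blk%04d", seq_len(nrow(blocks)))
  rownames(blocks) <- NULL
  blocks[, c("block_id", setdiff(names(blocks), "block_id"))]
}

empty_blocks <- function() {
  df <- data.frame(block_id = character(), genome_q = character(),
                   genome_s = character(), chrom_q = character(),
                   chrom_s = character(), orientation = character(),
                   n_anchors = integer(), score = numeric(),
                   start_q = integer(), end_q = integer(),
                   start_s = integer(), end_s = integer(),
                   rank_q_min = integer(), rank_q_max = integer(),
                   rank_s_min = integer(), rank_s_max = integer(),
                   stringsAsFactors = FALSE)
  df$anchors <- list()
  df
}

#' Percentage of genes lying in collinear blocks
#'
#' @param n_collinear distinct genes in blocks of a comparison.
#' @param n_total total genes considered for that comparison.
#' @return percentage (100 * n_collinear / n_total); `NA` if `n_total` is 0.
#' @export
collinear_fraction <- function(n_collinear, n_total) {
  ifelse(n_total > 0, 100 * n_collinear / n_total, NA_real_)
}

#' Summarize collinear gene fractions per genome comparison
#'
#' Counts the distinct genes (query and subject side pooled) that are members
#' of at least one collinear block, per genome pair, and expresses them as a
#' percentage of the supplied totals.
#'
#' @param blocks block table from [chain_collinear_blocks()] (several
#'   comparisons may be concatenated with `rbind`).
#' @param totals named numeric vector of total gene counts, named by
#'   `"<genome_q> vs <genome_s>"`.
#' @return data.frame with `comparison`, `n_collinear`, `n_total`, `pct`.
#' @export
collinearity_summary <- function(blocks, totals) {
  comp_of <- function(b) paste(b$genome_q, "vs", b$genome_s)
  if (nrow(blocks) == 0) {
    return(data.frame(comparison = names(totals),
                      n_collinear = 0L, n_total = as.numeric(totals),
                      pct = collinear_fraction(0, as.numeric(totals)),
                      stringsAsFactors = FALSE))
  }
  blocks$comparison <- comp_of(blocks)
  rows <- lapply(split(seq_len(nrow(blocks)), blocks$comparison), function(i) {
    genes <- unique(unlist(lapply(blocks$anchors[i],
                                  function(m) c(m$gene_q, m$gene_s))))
    data.frame(comparison = blocks$comparison[i[1]],
               n_collinear = length(genes), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  for (nm in setdiff(names(totals), out$comparison)) {
    out <- rbind(out, data.frame(comparison = nm, n_collinear = 0L))
  }
  out$n_total <- as.numeric(totals[out$comparison])
  out$pct <- collinear_fraction(out$n_collinear, out$n_total)
  rownames(out) <- NULL
  out
}

#' Write a collinear block table to TSV
#'
#' One row per block with the member anchors serialized as a comma-separated
#' `gene_q:gene_s` list.
#'
#' @param blocks block table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blocks_tsv <- function(blocks, path) {
  flat <- blocks[, setdiff(names(blocks), "anchors")]
  flat$anchor_pairs <- vapply(blocks$anchors, function(m) {
    if (is.null(m) || nrow(m) == 0) return("")
    paste(paste0(m$gene_q, ":", m$gene_s), collapse = ",")
  }, "")
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
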