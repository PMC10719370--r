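# Rearrangement calling from collinear blocks.
#
# Translocations: a region collinear with a non-homoeologous chromosome and
# lacking synteny with its own diploid relative in that region. Inversions:
# maximal runs of inverted-orientation blocks between homoeologs. Segmental
# duplications: a region whose anchors map to two disjoint partner regions.

new_event <- function(kind, chrom1, start1, end1, chrom2 = NA, start2 = NA,
                      end2 = NA, n_genes = NA_integer_, scope = NA_character_,
                      note = "", evidence = "") {
  span <- (end1 - start1) + ifelse(is.na(start2), 0, end2 - start2)
  data.frame(kind = kind, chrom1 = chrom1, start1 = start1, end1 = end1,
             chrom2 = as.character(chrom2), start2 = start2, end2 = end2,
             n_genes = as.integer(n_genes), span_bp = span, scope = scope,
             note = note, evidence = evidence, stringsAsFactors = FALSE)
}

empty_events <- function() {
  new_event(character(0), character(0), integer(0), integer(0),
            chrom2 = character(0), start2 = integer(0), end2 = integer(0),
            n_genes = integer(0), scope = character(0), note = character(0),
            evidence = character(0))
}

finish_events <- function(events, major_span = 1e6, major_genes = 100) {
  if (!nrow(events)) {
    events$major <- logical(0)
    events$event_id <- character(0)
    return(events)
  }
  events$major <- events$span_bp > major_span & events$n_genes > major_genes
  events <- events[order(events$kind, events$chrom1, events$start1), , drop = FALSE]
  events$event_id <- sprintf("ev%03d", seq_len(nrow(events)))
  rownames(events) <- NULL
  events[, c("event_id", setdiff(names(events), "event_id"))]
}

block_genes <- function(blocks, rows, side = c("both", "q", "s")) {
  side <- match.arg(side)
  unique(unlist(lapply(blocks$anchors[rows], function(m) {
    switch(side, both = c(m$gene_q, m$gene_s), q = m$gene_q, s = m$gene_s)
  })))
}

homoeologous_rows <- function(blocks) {
  !is.na(homoeolog_of(blocks$chrom_q)) &
    homoeolog_of(blocks$chrom_q) == blocks$chrom_s
}

#' Detect inversions between homoeologous chromosomes
#'
#' Within each homoeologous chromosome pair, blocks are ordered along the
#' query chromosome and every maximal run of inverted-orientation blocks is
#' emitted as one inversion whose two intervals are the run's spans on the two
#' homoeologs. Which homoeolog physically carries the inversion cannot be
#' decided from self-synteny alone; read evidence (see
#' [locate_breakpoints()]) resolves that.
#'
#' @param blocks_self block table for the within-tetraploid (subgenome A vs
#'   subgenome B) comparison.
#' @param major_span,major_genes thresholds for the `major` flag (an event is
#'   major when longer than `major_span` bp and containing more than
#'   `major_genes` genes).
#' @return event data.frame (kind `inversion`).
#' @export
detect_inversions <- function(blocks_self, major_span = 1e6, major_genes = 100) {
  b <- blocks_self[homoeologous_rows(blocks_self), , drop = FALSE]
  events <- empty_events()
  for (grp in split(seq_len(nrow(b)), paste(b$chrom_q[seq_len(nrow(b))],
                                            b$chrom_s[seq_len(nrow(b))]))) {
    grp <- grp[order(b$start_q[grp])]
    inv <- b$orientation[grp] == "inverted"
    if (!any(inv)) next
    r <- rle(inv)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      rows <- grp[starts[k]:ends[k]]
      genes <- block_genes(b, rows)
      events <- rbind(events, new_event(
        "inversion",
        chrom1 = b$chrom_q[rows[1]], start1 = min(b$start_q[rows]),
        end1 = max(b$end_q[rows]),
        chrom2 = b$chrom_s[rows[1]], start2 = min(b$start_s[rows]),
        end2 = max(b$end_s[rows]),
        n_genes = length(genes), scope = "intra_subgenome",
        evidence = paste(b$block_id[rows], collapse = ",")))
    }
  }
  finish_events(events, major_span, major_genes)
}

# Fraction of a (chrom, start, end) region covered by blocks whose partner is
# the same-index chromosome of the expected diploid relative.
diploid_cover <- function(chrom, start, end, blocks_dip) {
  if (is.null(blocks_dip) || !nrow(blocks_dip)) return(NA_real_)
  hit <- blocks_dip$chrom_q == chrom &
    chrom_index(blocks_dip$chrom_s) == chrom_index(chrom)
  if (!any(hit)) return(0)
  ov <- pmin(blocks_dip$end_q[hit], end) - pmax(blocks_dip$start_q[hit], start)
  sum(pmax(ov, 0)) / max(end - start, 1)
}

#' Detect translocations from collinearity breaks plus diploid synteny
#'
#' A region of a tetraploid chromosome that is collinear with a
#' non-homoeologous chromosome of the other subgenome, and that lacks synteny
#' with its own diploid relative in the same region, is called a
#' translocation: its sequence arrived from the homoeolog of the chromosome it
#' is collinear with. When both exchanged regions of one chromosome pair are
#' found the two calls merge into a single reciprocal translocation. If the
#' relevant diploid comparison is missing the call is still emitted, flagged
#' `diploid-unconfirmed`, using both sides of the collinearity break.
#'
#' @param blocks_self within-tetraploid (A vs B) block table.
#' @param blocks_vs_diploids named list of block tables for the
#'   tetraploid-vs-diploid comparisons, names `"A"` and `"B"` (tetraploid as
#'   query); either may be `NULL`.
#' @param max_diploid_cover a side counts as lacking diploid synteny when the
#'   fraction of it covered by blocks against the same-index diploid
#'   chromosome is at most this value (default 0.2).
#' @param major_span,major_genes `major`-flag thresholds.
#' @return event data.frame (kinds `translocation`, `reciprocal_translocation`).
#' @export
detect_translocations <- function(blocks_self, blocks_vs_diploids = list(),
                                  max_diploid_cover = 0.2,
                                  major_span = 1e6, major_genes = 100) {
  b <- blocks_self[!homoeologous_rows(blocks_self) &
                     blocks_self$chrom_q != blocks_self$chrom_s, , drop = FALSE]
  events <- empty_events()
  cand <- list()
  for (i in seq_len(nrow(b))) {
    sides <- data.frame(
      chrom = c(b$chrom_q[i], b$chrom_s[i]),
      start = c(b$start_q[i], b$start_s[i]),
      end = c(b$end_q[i], b$end_s[i]),
      other = c(b$chrom_s[i], b$chrom_q[i]),
      side = c("q", "s"), stringsAsFactors = FALSE)
    confirmed <- unconfirmed <- FALSE
    for (j in 1:2) {
      sg <- subgenome_of(sides$chrom[j])
      cov <- diploid_cover(sides$chrom[j], sides$start[j], sides$end[j],
                           blocks_vs_diploids[[sg]])
      if (is.na(cov)) { unconfirmed <- TRUE; next }
      if (cov <= max_diploid_cover) {
        confirmed <- TRUE
        cand[[length(cand) + 1]] <- data.frame(
          chrom = sides$chrom[j], start = sides$start[j], end = sides$end[j],
          donor = homoeolog_of(sides$other[j]), side = sides$side[j],
          block = b$block_id[i], n_genes = length(block_genes(b, i, sides$side[j])),
          stringsAsFactors = FALSE)
      }
    }
    if (!confirmed && unconfirmed) {
      events <- rbind(events, new_event(
        "translocation", b$chrom_q[i], b$start_q[i], b$end_q[i],
        b$chrom_s[i], b$start_s[i], b$end_s[i],
        n_genes = length(block_genes(b, i)),
        scope = ifelse(subgenome_of(b$chrom_q[i]) == subgenome_of(b$chrom_s[i]),
                       "intra_subgenome", "inter_subgenome"),
        note = "diploid-unconfirmed", evidence = b$block_id[i]))
    }
  }
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    pair_key <- vapply(seq_len(nrow(cand)), function(i) {
      paste(sort(c(cand$chrom[i], cand$donor[i])), collapse = "|")
    }, "")
    for (grp in split(seq_len(nrow(cand)), pair_key)) {
      chroms <- unique(cand$chrom[grp])
      scope <- ifelse(length(unique(subgenome_of(c(cand$chrom[grp],
                                                   cand$donor[grp])))) == 1,
                      "intra_subgenome", "inter_subgenome")
      if (length(chroms) >= 2) {
        g1 <- grp[cand$chrom[grp] == chroms[1]]
        g2 <- grp[cand$chrom[grp] == chroms[2]]
        events <- rbind(events, new_event(
          "reciprocal_translocation",
          chroms[1], min(cand$start[g1]), max(cand$end[g1]),
          chroms[2], min(cand$start[g2]), max(cand$end[g2]),
          n_genes = sum(cand$n_genes[grp]), scope = scope,
          evidence = paste(cand$block[grp], collapse = ",")))
      } else {
        events <- rbind(events, new_event(
          "translocation",
          chroms[1], min(cand$start[grp]), max(cand$end[grp]),
          n_genes = sum(cand$n_genes[grp]), scope = scope,
          evidence = paste(cand$block[grp], collapse = ",")))
      }
    }
  }
  finish_events(events, major_span, major_genes)
}

# Map a query-rank window through a block's anchors to the subject side,
# returning NULL when fewer than min_n anchors fall in the window.
project_partner <- function(block_anchors, lo, hi, min_n) {
  m <- block_anchors[block_anchors$rank_q >= lo & block_anchors$rank_q <= hi, ,
                     drop = FALSE]
  if (nrow(m) < min_n) return(NULL)
  list(rank_min = min(m$rank_s), rank_max = max(m$rank_s), genes = m$gene_s,
       n = nrow(m))
}

swap_block_axes <- function(blocks) {
  sw <- blocks
  sw[, c("chrom_q", "start_q", "end_q", "rank_q_min", "rank_q_max",
         "chrom_s", "start_s", "end_s", "rank_s_min", "rank_s_max")] <-
    blocks[, c("chrom_s", "start_s", "end_s", "rank_s_min", "rank_s_max",
               "chrom_q", "start_q", "end_q", "rank_q_min", "rank_q_max")]
  sw$anchors <- lapply(blocks$anchors, function(m) {
    data.frame(gene_q = m$gene_s, gene_s = m$gene_q, rank_q = m$rank_s,
               rank_s = m$rank_q, score = m$score, stringsAsFactors = FALSE)
  })
  sw
}

#' Detect segmental duplications from duplicated synteny blocks
#'
#' A chromosome region whose anchors participate in two blocks with disjoint
#' partner regions is a duplicated block of genes with conserved order: the
#' two partner regions are the duplicate copies. Both axes of the block table
#' are scanned, and copies on one chromosome versus two give the
#' intra-/inter-chromosomal label.
#'
#' @param blocks_self block table within one genome.
#' @param genes gene table used to convert partner gene sets to coordinates.
#' @param min_dup_genes minimum anchors each block must contribute inside the
#'   shared region (default 8, matching the block `match_size`).
#' @param major_span,major_genes `major`-flag thresholds.
#' @return event data.frame (kind `segmental_duplication`).
#' @export
detect_segmental_duplications <- function(blocks_self, genes, min_dup_genes = 8,
                                          major_span = 1e6, major_genes = 100) {
  events <- empty_events()
  seen <- character(0)
  scan <- function(b, events) {
    if (nrow(b) < 2) return(events)
    for (i in seq_len(nrow(b) - 1)) {
      for (j in (i + 1):nrow(b)) {
        if (b$chrom_q[i] != b$chrom_q[j]) next
        lo <- max(b$rank_q_min[i], b$rank_q_min[j])
        hi <- min(b$rank_q_max[i], b$rank_q_max[j])
        if (lo > hi) next
        p1 <- project_partner(b$anchors[[i]], lo, hi, min_dup_genes)
        p2 <- project_partner(b$anchors[[j]], lo, hi, min_dup_genes)
        if (is.null(p1) || is.null(p2)) next
        same_chrom <- b$chrom_s[i] == b$chrom_s[j]
        disjoint <- !same_chrom ||
          p1$rank_max < p2$rank_min || p2$rank_max < p1$rank_min
        if (!disjoint) next
        span_of <- function(p) {
          gi <- match(p$genes, genes$gene_id)
          c(min(genes$start[gi]), max(genes$end[gi]))
        }
        s1 <- span_of(p1); s2 <- span_of(p2)
        key <- paste(b$chrom_s[i], s1[1], b$chrom_s[j], s2[1])
        if (key %in% seen) next
        seen <<- c(seen, key)
        events <- rbind(events, new_event(
          "segmental_duplication",
          b$chrom_s[i], s1[1], s1[2], b$chrom_s[j], s2[1], s2[2],
          n_genes = length(unique(c(p1$genes, p2$genes))),
          scope = "intra_subgenome",
          note = ifelse(same_chrom, "intra_chromosomal", "inter_chromosomal"),
          evidence = paste(b$block_id[c(i, j)], collapse = ",")))
      }
    }
    events
  }
  events <- scan(blocks_self, events)
  events <- scan(swap_block_axes(blocks_self), events)
  finish_events(events, major_span, major_genes)
}

#' Call every rearrangement class from one block set
#'
#' Convenience wrapper running [detect_translocations()],
#' [detect_inversions()] and [detect_segmental_duplications()] on the same
#' within-tetraploid block table and renumbering the pooled events.
#'
#' @param blocks_self within-tetraploid (A vs B) block table.
#' @param blocks_vs_diploids named list of tetraploid-vs-diploid block tables
#'   (names `"A"`, `"B"`).
#' @param genes tetraploid gene table.
#' @param min_dup_genes,max_diploid_cover,major_span,major_genes passed to the
#'   individual detectors.
#' @return pooled event data.frame.
#' @export
call_rearrangements <- function(blocks_self, blocks_vs_diploids = list(),
                                genes, min_dup_genes = 8,
                                max_diploid_cover = 0.2, major_span = 1e6,
                                major_genes = 100) {
  ev <- rbind(
    detect_translocations(blocks_self, blocks_vs_diploids, max_diploid_cover,
                          major_span, major_genes),
    detect_inversions(blocks_self, major_span, major_genes),
    detect_segmental_duplications(blocks_self, genes, min_dup_genes,
                                  major_span, major_genes))
  finish_events(ev[, setdiff(names(ev), c("event_id", "major"))],
                major_span, major_genes)
}

#' Subgenome-resolved rearrangement accounting
#'
#' Event intervals are pooled per subgenome and overlapping intervals merged
#' (union) before base pairs are summed, so overlapping calls are not counted
#' twice. Gene counts are the genes falling inside the merged rearranged
#' regions.
#'
#' @param events event table (rbind of the `detect_*` outputs).
#' @param subgenome_sizes named numeric vector of subgenome sizes in bp
#'   (names `"A"`, `"B"`, ...).
#' @param genes optional gene table; when given, per-subgenome rearranged gene
#'   counts and percentages are reported.
#' @return list with `by_subgenome` (data.frame: subgenome, bp, pct_bp,
#'   n_genes, pct_genes), `total_bp`, and `pct_intra_subgenome` (fraction of
#'   event bp whose scope is intra-subgenome, as a percentage).
#' @export
rearrangement_totals <- function(events, subgenome_sizes, genes = NULL) {
  ivs <- rbind(
    data.frame(chrom = events$chrom1, start = events$start1, end = events$end1,
               stringsAsFactors = FALSE),
    data.frame(chrom = events$chrom2, start = events$start2, end = events$end2,
               stringsAsFactors = FALSE))
  ivs <- ivs[!is.na(ivs$chrom) & !is.na(ivs$start), , drop = FALSE]
  ivs$subgenome <- subgenome_of(ivs$chrom)
  rows <- lapply(names(subgenome_sizes), function(sg) {
    sub <- ivs[ivs$subgenome == sg, , drop = FALSE]
    if (nrow(sub)) {
      gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
        sub$chrom, IRanges::IRanges(sub$start + 1, sub$end)))
      bp <- sum(GenomicRanges::width(gr))
    } else {
      gr <- GenomicRanges::GRanges(); bp <- 0
    }
    n_genes <- pct_genes <- NA_real_
    if (!is.null(genes)) {
      gsub <- genes[subgenome_of(genes$chrom) == sg, , drop = FALSE]
      if (nrow(gsub)) {
        ggr <- GenomicRanges::GRanges(gsub$chrom,
                                      IRanges::IRanges(gsub$start + 1, gsub$end))
        n_genes <- sum(IRanges::overlapsAny(ggr, gr))
        pct_genes <- 100 * n_genes / nrow(gsub)
      }
    }
    data.frame(subgenome = sg, bp = bp,
               pct_bp = 100 * bp / subgenome_sizes[[sg]],
               n_genes = n_genes, pct_genes = pct_genes,
               stringsAsFactors = FALSE)
  })
  by_sg <- do.call(rbind, rows)
  intra <- sum(events$span_bp[events$scope == "intra_subgenome"], na.rm = TRUE)
  all_bp <- sum(events$span_bp, na.rm = TRUE)
  list(by_subgenome = by_sg,
       total_bp = sum(by_sg$bp),
       pct_intra_subgenome = if (all_bp > 0) 100 * intra / all_bp else NA_real_)
}

#' Scan diploid read-mapping rate tracks for homoeologous exchanges
#'
#' Operationalizes the inverted-diploid-mapping signature of a reciprocal
#' homoeologous exchange: windows where the mapping rate of the expected
#' diploid relative falls to at most half its chromosome-wide mean while the
#' alternative diploid's rate is at least half of its own mean. Qualifying
#' windows are merged (bridging single-window dropouts) and short runs
#' discarded.
#'
#' @param track data.frame with `chrom`, `start`, `end`, `rate_expected`,
#'   `rate_alt` (per window).
#' @param min_windows minimum run length in windows (default 2).
#' @param bridge maximum run interruption, in windows, merged over (default 1).
#' @return data.frame of candidate regions: `chrom`, `start`, `end`,
#'   `n_windows`.
#' @export
detect_mapping_swaps <- function(track, min_windows = 2, bridge = 1) {
  out <- list()
  for (sub in split(track, track$chrom)) {
    sub <- sub[order(sub$start), , drop = FALSE]
    hit <- sub$rate_expected <= 0.5 * mean(sub$rate_expected) &
      sub$rate_alt >= 0.5 * mean(sub$rate_alt)
    if (!any(hit)) next
    idx <- which(hit)
    brk <- c(0, which(diff(idx) > bridge + 1), length(idx))
    for (k in seq_len(length(brk) - 1)) {
      run <- idx[(brk[k] + 1):brk[k + 1]]
      if (length(run) < min_windows) next
      out[[length(out) + 1]] <- data.frame(
        chrom = sub$chrom[1], start = sub$start[min(run)],
        end = sub$end[max(run)], n_windows = length(run),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_windows = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Write events as TSV
#' @param events event table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write event intervals as BED (0-based half-open, one line per interval)
#' @param events event table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events_bed <- function(events, path) {
  b1 <- data.frame(events$chrom1, events$start1, events$end1,
                   paste0(events$event_id, ":", events$kind))
  b2 <- data.frame(events$chrom2, events$start2, events$end2,
                   paste0(events$event_id, ":", events$kind))
  names(b2) <- names(b1)
  bed <- rbind(b1, b2)
  bed <- bed[!is.na(bed[[1]]) & !is.na(bed[[2]]), , drop = FALSE]
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
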