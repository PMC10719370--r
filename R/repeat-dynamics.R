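# Subgenome-resolved repeat accounting: per-family bp and copy numbers,
# TE-space attribution of subgenome size differences, LTR family enrichment
# classification, windowed density tracks, and dynamics versus the diploid
# relatives.

LTR_SUPERFAMILIES <- c("Gypsy", "Copia", "TRIM_LARD")

#' Per-family repeat statistics by partition
#'
#' Copy number is the count of annotated elements; base pairs are summed after
#' merging overlapping copies of the same family (union; policy `"sum"` skips
#' the merge). Partitions are the subgenomes of each genome plus a `whole`
#' rollup per genome; with the merge applied per chromosome, subgenome totals
#' sum exactly to the whole-genome total.
#'
#' @param copies repeat copy table from [read_gff3()] (kind `"repeat"`).
#' @param bp_policy `"merge"` (default) or `"sum"`.
#' @return data.frame: `genome_label`, `partition`, `family`, `superfamily`,
#'   `n_copies`, `total_bp`, `n_complete`.
#' @export
summarize_repeats <- function(copies, bp_policy = c("merge", "sum")) {
  bp_policy <- match.arg(bp_policy)
  if (nrow(copies) == 0) {
    return(data.frame(genome_label = character(), partition = character(),
                      family = character(), superfamily = character(),
                      n_copies = integer(), total_bp = numeric(),
                      n_complete = integer(), stringsAsFactors = FALSE))
  }
  one <- function(sub, partition) {
    rows <- lapply(split(seq_len(nrow(sub)), sub$family), function(i) {
      bp <- if (bp_policy == "merge") {
        gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
          sub$chrom[i], IRanges::IRanges(sub$start[i] + 1, sub$end[i])))
        sum(GenomicRanges::width(gr))
      } else {
        sum(sub$end[i] - sub$start[i])
      }
      data.frame(genome_label = sub$genome_label[i[1]], partition = partition,
                 family = sub$family[i[1]], superfamily = sub$superfamily[i[1]],
                 n_copies = length(i), total_bp = as.numeric(bp),
                 n_complete = sum(sub$complete[i]), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  out <- list()
  for (gsub in split(copies, copies$genome_label)) {
    for (sg in unique(gsub$subgenome)) {
      out[[length(out) + 1]] <- one(gsub[gsub$subgenome == sg, ], sg)
    }
    out[[length(out) + 1]] <- one(gsub, "whole")
  }
  res <- do.call(rbind, out)
  res <- res[order(res$genome_label, res$partition, res$superfamily, res$family), ]
  rownames(res) <- NULL
  res
}

#' Roll family statistics up to superfamilies
#'
#' @param stats output of [summarize_repeats()].
#' @return data.frame aggregated over `superfamily` within each
#'   `genome_label` x `partition`.
#' @export
rollup_superfamilies <- function(stats) {
  agg <- aggregate(cbind(n_copies, total_bp, n_complete) ~
                     genome_label + partition + superfamily,
                   data = stats, FUN = sum)
  agg[order(agg$genome_label, agg$partition, agg$superfamily), ]
}

#' Attribute a subgenome size difference to TE space
#'
#' The TE-space difference is the absolute difference of total repeat bp
#' between the two subgenomes; its percentage of the assembly size difference
#' says how much of the size asymmetry repeats explain. Per-superfamily
#' contributions are the absolute per-superfamily bp differences expressed as
#' a percentage of the TE-space difference.
#'
#' @param stats_a,stats_b family-level statistics (rows of
#'   [summarize_repeats()]) for subgenomes A and B.
#' @param size_diff_bp assembly size difference between the subgenomes in bp.
#' @return list with `te_diff_bp`, `pct_explained`, and `by_superfamily`
#'   (data.frame: `superfamily`, `diff_bp`, `pct_of_te_diff`).
#' @export
te_space_attribution <- function(stats_a, stats_b, size_diff_bp) {
  tot_a <- sum(stats_a$total_bp); tot_b <- sum(stats_b$total_bp)
  te_diff <- abs(tot_b - tot_a)
  pct <- if (size_diff_bp == 0) NA_real_ else 100 * te_diff / size_diff_bp
  sfa <- tapply(stats_a$total_bp, stats_a$superfamily, sum)
  sfb <- tapply(stats_b$total_bp, stats_b$superfamily, sum)
  sfs <- sort(union(names(sfa), names(sfb)))
  gv <- function(x, nm) ifelse(nm %in% names(x), as.numeric(x[nm]), 0)
  diff_bp <- abs(gv(sfb, sfs) - gv(sfa, sfs))
  by_sf <- data.frame(superfamily = sfs, diff_bp = diff_bp,
                      pct_of_te_diff = if (te_diff > 0) 100 * diff_bp / te_diff
                                       else rep(NA_real_, length(sfs)),
                      stringsAsFactors = FALSE)
  list(te_diff_bp = te_diff, pct_explained = pct, by_superfamily = by_sf)
}

#' Classify LTR family enrichment between subgenomes
#'
#' A family is subgenome-enriched when the log2 ratio of its B to A copy
#' numbers is at least 1 in magnitude (minimum two-fold change, boundary
#' inclusive); families present in only one subgenome are `*_specific`; a
#' family is `highly_repeated` when its whole-genome copy number exceeds the
#' average per-family LTR copy number (computed from the input unless
#' `avg_copy_threshold` is given, since the average is data-specific).
#'
#' @param stats family statistics from [summarize_repeats()] for one genome,
#'   containing partitions `"A"`, `"B"` and `"whole"`.
#' @param avg_copy_threshold override for the highly-repeated copy-number
#'   threshold.
#' @param ltr_superfamilies superfamilies treated as LTR (default Gypsy,
#'   Copia, TRIM_LARD).
#' @param complete_only restrict to families with at least one
#'   complete-structure copy (default TRUE, mirroring the restriction to
#'   families with a complete LTR sequence structure).
#' @return data.frame: `family`, `superfamily`, `copies_A`, `copies_B`,
#'   `log2fc`, `class`, `highly_repeated`, sorted by `log2fc` within
#'   superfamily.
#' @export
ltr_family_enrichment <- function(stats, avg_copy_threshold = NULL,
                                  ltr_superfamilies = LTR_SUPERFAMILIES,
                                  complete_only = TRUE) {
  ltr <- stats[stats$superfamily %in% ltr_superfamilies, , drop = FALSE]
  whole <- ltr[ltr$partition == "whole", , drop = FALSE]
  if (complete_only) whole <- whole[whole$n_complete > 0, , drop = FALSE]
  if (is.null(avg_copy_threshold)) {
    avg_copy_threshold <- mean(ltr$n_copies[ltr$partition == "whole"])
  }
  cp <- function(part, fam) {
    i <- which(ltr$partition == part & ltr$family == fam)
    if (length(i)) sum(ltr$n_copies[i]) else 0L
  }
  rows <- lapply(seq_len(nrow(whole)), function(k) {
    fam <- whole$family[k]
    a <- cp("A", fam); b <- cp("B", fam)
    if (a == 0 && b == 0) return(NULL)
    if (a == 0) { lfc <- Inf; cls <- "B_specific" }
    else if (b == 0) { lfc <- -Inf; cls <- "A_specific" }
    else {
      lfc <- log2(b / a)
      cls <- if (lfc >= 1) "B_enriched"
             else if (lfc <= -1) "A_enriched"
             else "not_enriched"
    }
    data.frame(family = fam, superfamily = whole$superfamily[k],
               copies_A = a, copies_B = b, log2fc = lfc, class = cls,
               highly_repeated = whole$n_copies[k] > avg_copy_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(family = character(), superfamily = character(),
                      copies_A = integer(), copies_B = integer(),
                      log2fc = numeric(), class = character(),
                      highly_repeated = logical(), stringsAsFactors = FALSE))
  }
  out <- out[order(out$superfamily, out$log2fc), ]
  rownames(out) <- NULL
  out
}

#' Windowed feature-density track
#'
#' Counts features per fixed-size window along each chromosome (a feature is
#' assigned to the window containing its start; the last partial window is
#' kept). Chromosomes present in `chrom_lengths` but devoid of features get
#' all-zero tracks.
#'
#' @param features data.frame with `chrom` and `start` columns (genes or
#'   repeat copies).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param window_bp window size (default 1 Mb).
#' @return BED-like data.frame: `chrom`, `start`, `end`, `count`.
#' @export
window_density <- function(features, chrom_lengths, window_bp = 1e6) {
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    n_win <- max(1L, as.integer(ceiling(len / window_bp)))
    starts <- (seq_len(n_win) - 1) * window_bp
    cnt <- rep(0L, n_win)
    st <- features$start[features$chrom == ch]
    if (length(st)) {
      w <- pmin(floor(st / window_bp) + 1L, n_win)
      tb <- table(w)
      cnt[as.integer(names(tb))] <- as.integer(tb)
    }
    data.frame(chrom = ch, start = starts, end = pmin(starts + window_bp, len),
               count = cnt, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Superfamily copy-number and bp dynamics versus a diploid relative
#'
#' Deltas are subgenome minus diploid per superfamily; negative copy deltas
#' are contractions (fractionation-driven losses in the polyploid), positive
#' ones expansions. The summary reports which share of the total absolute
#' copy-number change is reduction versus expansion.
#'
#' @param stats_subgenome,stats_diploid family statistics
#'   ([summarize_repeats()] rows) for one subgenome and its diploid relative.
#' @return list with `by_superfamily` (data.frame: `superfamily`,
#'   `delta_copies`, `delta_bp`, `label` in expansion/contraction/stable/
#'   unshared) and `summary` (`pct_reduction`, `pct_expansion`,
#'   `net_bp_change`).
#' @export
dynamics_vs_diploid <- function(stats_subgenome, stats_diploid) {
  agg <- function(s) {
    list(cp = tapply(s$n_copies, s$superfamily, sum),
         bp = tapply(s$total_bp, s$superfamily, sum))
  }
  a <- agg(stats_subgenome); d <- agg(stats_diploid)
  sfs <- sort(union(names(a$cp), names(d$cp)))
  gv <- function(x, nm) ifelse(nm %in% names(x), as.numeric(x[nm]), NA_real_)
  sub_cp <- gv(a$cp, sfs); dip_cp <- gv(d$cp, sfs)
  sub_bp <- gv(a$bp, sfs); dip_bp <- gv(d$bp, sfs)
  unshared <- is.na(sub_cp) | is.na(dip_cp)
  delta_cp <- ifelse(unshared, NA_real_, sub_cp - dip_cp)
  delta_bp <- ifelse(unshared, NA_real_, sub_bp - dip_bp)
  label <- ifelse(unshared, "unshared",
           ifelse(delta_cp > 0, "expansion",
           ifelse(delta_cp < 0, "contraction", "stable")))
  tot_abs <- sum(abs(delta_cp), na.rm = TRUE)
  red <- sum(-delta_cp[!is.na(delta_cp) & delta_cp < 0])
  list(by_superfamily = data.frame(
         superfamily = sfs, delta_copies = delta_cp, delta_bp = delta_bp,
         label = label, stringsAsFactors = FALSE),
       summary = list(
         pct_reduction = if (tot_abs > 0) 100 * red / tot_abs else NA_real_,
         pct_expansion = if (tot_abs > 0) 100 * (tot_abs - red) / tot_abs else NA_real_,
         net_bp_change = sum(delta_bp, na.rm = TRUE)))
}

#' Genic-space fractions of an assembly and of an estimated genome size
#'
#' @param coding_bp total coding-region length in bp.
#' @param assembly_bp total assembly size in bp.
#' @param genome_size_bp independently estimated genome size in bp (optional).
#' @return data.frame with `denominator`, `bp`, `pct`.
#' @export
coding_space_summary <- function(coding_bp, assembly_bp, genome_size_bp = NA) {
  data.frame(denominator = c("assembly", "genome_estimate"),
             bp = c(assembly_bp, genome_size_bp),
             pct = 100 * coding_bp / c(assembly_bp, genome_size_bp),
             stringsAsFactors = FALSE)
}
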