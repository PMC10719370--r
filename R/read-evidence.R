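# Inversion breakpoint location and panel genotyping from paired-end
# alignment signatures. The reference is assumed to CARRY the inversion, so
# discordant pairs joining the two breakpoint regions (with an insert-size
# gate around the inversion span) indicate that an accession does NOT carry
# it, while reads spanning both breakpoints indicate that it does.

#' Construct a breakpoint pair for a large inversion
#'
#' @param chrom chromosome name.
#' @param pos_left,pos_right breakpoint positions (0-based), `pos_left <
#'   pos_right`.
#' @param window half-width of the counting window around each breakpoint
#'   (default 500 bp, i.e. windows of about 1 kb as used for screening
#'   panels).
#' @param insert_min,insert_max insert-size gate for discordant pairs; by
#'   default the gate is the inversion span plus/minus `gate_slack`, which
#'   scales with the event rather than the genome.
#' @param gate_slack default half-width of the insert gate (default 1500 bp).
#' @return list of class `breakpoint_pair`.
#' @export
breakpoint_pair <- function(chrom, pos_left, pos_right, window = 500,
                            insert_min = NULL, insert_max = NULL,
                            gate_slack = 1500) {
  if (pos_left >= pos_right) stop("pos_left must be < pos_right")
  span <- pos_right - pos_left
  if (is.null(insert_min)) insert_min <- span - gate_slack
  if (is.null(insert_max)) insert_max <- span + gate_slack
  if (!(insert_min < span && span < insert_max)) {
    stop("insert gate must contain the breakpoint span")
  }
  structure(list(chrom = chrom, pos_left = pos_left, pos_right = pos_right,
                 window_left = c(pos_left - window, pos_left + window),
                 window_right = c(pos_right - window, pos_right + window),
                 insert_min = insert_min, insert_max = insert_max,
                 span = span),
            class = "breakpoint_pair")
}

#' @export
print.breakpoint_pair <- function(x, ...) {
  cat(sprintf("breakpoint pair %s:%d / %d (span %d bp, insert gate [%d, %d])\n",
              x$chrom, x$pos_left, x$pos_right, x$span,
              as.integer(x$insert_min), as.integer(x$insert_max)))
  invisible(x)
}

# mate intervals of a pair table restricted to one chromosome, long format
mate_intervals <- function(pairs, chrom) {
  rbind(
    data.frame(pos = pairs$pos1[pairs$chrom1 == chrom],
               end = pairs$end1[pairs$chrom1 == chrom]),
    data.frame(pos = pairs$pos2[pairs$chrom2 == chrom],
               end = pairs$end2[pairs$chrom2 == chrom]))
}

#' Locate inversion breakpoints within candidate regions
#'
#' Within each candidate region (typically the <50 kb vicinity of a synteny
#' or genetic-map break), the breakpoint is placed at the position maximizing
#' (depth of the coverage interruption, i.e. the region's maximum coverage
#' minus the coverage at the position) x (1 + number of discordant mate
#' starts within 1 kb): where the sharp coverage interruption co-locates with
#' a cluster of mates whose partners map to the other candidate region.
#'
#' @param pairs alignment pair table ([read_sam()]), typically pooled over
#'   non-carrier accessions.
#' @param region_left,region_right candidate intervals `c(start, end)` on
#'   `chrom`.
#' @param chrom chromosome name.
#' @param window window half-width passed to [breakpoint_pair()].
#' @param cluster_bp discordant mates count toward a position when within
#'   this distance (default 1000).
#' @param ... further arguments to [breakpoint_pair()] (e.g. the insert gate).
#' @return a [breakpoint_pair()].
#' @export
locate_breakpoints <- function(pairs, region_left, region_right, chrom,
                               window = 500, cluster_bp = 1000, ...) {
  on_chrom <- pairs$chrom1 == chrom & pairs$chrom2 == chrom
  disc <- pairs[on_chrom &
                  pairs$pos1 >= region_left[1] & pairs$pos1 < region_left[2] &
                  pairs$pos2 >= region_right[1] & pairs$pos2 < region_right[2], ,
                drop = FALSE]
  if (nrow(disc) == 0) stop("no breakpoint signal: no discordant pairs join the candidate regions")
  reads <- mate_intervals(pairs, chrom)
  pick <- function(region, mate_pos) {
    lo <- region[1]; hi <- region[2]
    cov <- rep(0L, hi - lo + 2L)
    rr <- reads[reads$end > lo - 1 & reads$pos < hi + 1, , drop = FALSE]
    if (nrow(rr)) {
      s <- pmax(rr$pos, lo - 1L) - (lo - 1L) + 1L
      e <- pmin(rr$end, hi + 1L) - (lo - 1L) + 1L
      for (i in seq_along(s)) {
        cov[s[i]] <- cov[s[i]] + 1L
        if (e[i] <= length(cov)) cov[e[i]] <- cov[e[i]] - 1L
      }
      cov <- cumsum(cov)
    }
    pos <- lo:hi
    depth_drop <- max(cov) - cov[pos - lo + 2L]
    near <- vapply(pos, function(p) sum(abs(mate_pos - p) <= cluster_bp), 0L)
    score <- as.numeric(depth_drop) * (1 + near)
    pos[which.max(score)]
  }
  pl <- pick(region_left, disc$pos1)
  pr <- pick(region_right, disc$pos2)
  breakpoint_pair(chrom, pl, pr, window = window, ...)
}

#' Count discordant read pairs joining two breakpoint windows
#'
#' Counts pairs with one mate's alignment start inside the left window, the
#' other mate's start inside the right window, and a recomputed insert size
#' inside the gate. Each pair counts once.
#'
#' @param pairs alignment pair table.
#' @param bp a [breakpoint_pair()].
#' @return integer count.
#' @export
count_discordant_pairs <- function(pairs, bp) {
  p <- pairs[pairs$chrom1 == bp$chrom & pairs$chrom2 == bp$chrom &
               !is.na(pairs$insert), , drop = FALSE]
  in_win <- function(x, w) x >= w[1] & x <= w[2]
  hit <- ((in_win(p$pos1, bp$window_left) & in_win(p$pos2, bp$window_right)) |
          (in_win(p$pos2, bp$window_left) & in_win(p$pos1, bp$window_right))) &
    p$insert >= bp$insert_min & p$insert <= bp$insert_max
  sum(hit)
}

count_spanning_reads <- function(pairs, chrom, pos) {
  reads <- mate_intervals(pairs, chrom)
  # strict containment: at least one aligned base on each side of the breakpoint
  sum(reads$pos < pos & reads$end > pos + 1)
}

#' Genotype a known inversion in one accession
#'
#' Follows the screening rule for a reference that carries the inversion:
#' `absent` when at least one insert-gated discordant pair joins the two
#' breakpoint windows; `present` when there are no discordant pairs and at
#' least one read spans each breakpoint position; `inconclusive` when there
#' are no discordant pairs but a breakpoint lacks spanning reads. Accessions
#' below `min_genome_coverage` fold-coverage are excluded (`call` is `NA`).
#'
#' @param pairs alignment pair table for the accession.
#' @param bp a [breakpoint_pair()].
#' @param accession accession identifier.
#' @param genome_length genome size in bp used for mean depth; defaults to the
#'   sum of the SAM header sequence lengths attached to `pairs`.
#' @param min_genome_coverage minimum fold-coverage to genotype (default 5).
#' @return one-row data.frame: `accession`, `n_discordant`, `n_span_left`,
#'   `n_span_right`, `mean_depth`, `call`, `excluded`, `reason`.
#' @export
genotype_inversion <- function(pairs, bp, accession = "accession",
                               genome_length = NULL, min_genome_coverage = 5) {
  if (is.null(genome_length)) {
    sl <- attr(pairs, "seqlengths")
    if (is.null(sl) || !length(sl)) stop("genome_length is required when pairs carry no seqlengths")
    genome_length <- sum(as.numeric(sl))
  }
  depth <- sum(as.numeric(pairs$end1 - pairs$pos1) +
                 as.numeric(pairs$end2 - pairs$pos2)) / genome_length
  nd <- count_discordant_pairs(pairs, bp)
  nl <- count_spanning_reads(pairs, bp$chrom, bp$pos_left)
  nr <- count_spanning_reads(pairs, bp$chrom, bp$pos_right)
  if (depth < min_genome_coverage) {
    call <- NA_character_; excl <- TRUE
    reason <- sprintf("coverage %.2fx below %gx", depth, min_genome_coverage)
  } else {
    excl <- FALSE; reason <- ""
    call <- if (nd >= 1) "absent"
            else if (nl >= 1 && nr >= 1) "present"
            else "inconclusive"
  }
  data.frame(accession = accession, n_discordant = nd, n_span_left = nl,
             n_span_right = nr, mean_depth = depth, call = call,
             excluded = excl, reason = reason, stringsAsFactors = FALSE)
}

#' Genotype an inversion across a panel of SAM files
#'
#' @param sam_paths named character vector of SAM files (names = accession
#'   ids).
#' @param bp a [breakpoint_pair()].
#' @param min_mapq mapping-quality filter applied pairwise (default 20).
#' @param ... further arguments to [genotype_inversion()].
#' @return data.frame with one row per accession.
#' @export
genotype_panel <- function(sam_paths, bp, min_mapq = 20, ...) {
  if (is.null(names(sam_paths))) names(sam_paths) <- basename(sam_paths)
  calls <- lapply(names(sam_paths), function(acc) {
    genotype_inversion(read_sam(sam_paths[[acc]], min_mapq = min_mapq), bp,
                       accession = acc, ...)
  })
  do.call(rbind, calls)
}

#' Ecotype-by-genotype summary table
#'
#' Counts calls per ecotype with percentages of each ecotype's genotyped
#' total, in the layout used to report an inversion's distribution across a
#' germplasm panel. Excluded accessions are dropped from the denominators.
#'
#' @param calls call table from [genotype_panel()] (or rbind of
#'   [genotype_inversion()] rows).
#' @param ecotypes named character vector `accession -> ecotype`, or a
#'   data.frame with columns `accession` and `ecotype`.
#' @return data.frame with `ecotype`, `call`, `n`, `pct`.
#' @export
genotype_summary <- function(calls, ecotypes) {
  if (is.data.frame(ecotypes)) {
    ecotypes <- setNames(ecotypes$ecotype, ecotypes$accession)
  }
  if (!all(calls$accession %in% names(ecotypes))) {
    stop("unlabeled accession(s): ",
         paste(head(setdiff(calls$accession, names(ecotypes))), collapse = ", "))
  }
  kept <- calls[!calls$excluded, , drop = FALSE]
  if (!nrow(kept)) {
    return(data.frame(ecotype = character(), call = character(), n = integer(),
                      pct = numeric(), stringsAsFactors = FALSE))
  }
  kept$ecotype <- unname(ecotypes[kept$accession])
  lv <- c("present", "absent", "inconclusive")
  grid <- expand.grid(call = lv, ecotype = sort(unique(kept$ecotype)),
                      stringsAsFactors = FALSE)
  grid$n <- mapply(function(cl, ec) sum(kept$call == cl & kept$ecotype == ec),
                   grid$call, grid$ecotype)
  tot <- tapply(grid$n, grid$ecotype, sum)
  grid$pct <- 100 * grid$n / as.numeric(tot[grid$ecotype])
  grid[, c("ecotype", "call", "n", "pct")]
}
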