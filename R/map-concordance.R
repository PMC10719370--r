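# Genetic-vs-physical map concordance: place linkage-map markers on an
# assembly by exact flank-sequence search, then scan each chromosome for
# intervals where genetic and physical marker order disagree (candidate
# rearrangement breakpoints).

#' Place genetic-map markers on an assembly by flank search
#'
#' Each marker's flank sequence (by convention `2 * offset` bp centred on the
#' marker, e.g. 250 bp upstream plus 250 bp downstream) is searched against
#' the assembly on both strands. Only a unique best hit places the marker, at
#' the match start plus `offset`; markers with no hit, tied hits, or flanks
#' shorter than `min_flank` stay unplaced with a reason.
#'
#' @param flanks `Biostrings::DNAStringSet` named by marker id.
#' @param assembly `Biostrings::DNAStringSet` of chromosome sequences.
#' @param markers data.frame with `marker`, `linkage_group`, `cm`.
#' @param offset distance from flank start to the marker position (default
#'   250).
#' @param min_flank minimum flank length searched (default 100).
#' @return data.frame: `marker`, `linkage_group`, `cm`, `chrom` (or `NA`),
#'   `pos` (0-based, or `NA`), `hit_quality`, `reason`.
#' @export
place_markers <- function(flanks, assembly, markers, offset = 250,
                          min_flank = 100) {
  if (length(assembly) == 0) stop("empty assembly")
  if (is.null(names(flanks))) stop("flanks must be named by marker id")
  rows <- lapply(markers$marker, function(mk) {
    base <- data.frame(marker = mk,
                       linkage_group = markers$linkage_group[markers$marker == mk][1],
                       cm = markers$cm[markers$marker == mk][1],
                       chrom = NA_character_, pos = NA_integer_,
                       hit_quality = NA_real_, reason = "",
                       stringsAsFactors = FALSE)
    if (!mk %in% names(flanks)) { base$reason <- "no_flank"; return(base) }
    fl <- flanks[[mk]]
    if (length(fl) < min_flank) { base$reason <- "too_short"; return(base) }
    hits <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") fl else Biostrings::reverseComplement(fl)
      m <- Biostrings::vmatchPattern(pat, assembly)
      for (ci in seq_along(m)) {
        st <- Biostrings::startIndex(m)[[ci]]
        if (!is.null(st) && length(st)) {
          for (s in st) hits[[length(hits) + 1]] <-
            list(chrom = names(assembly)[ci], start = s - 1L, strand = strand)
        }
      }
    }
    if (length(hits) == 0) { base$reason <- "no_hit"; return(base) }
    if (length(hits) > 1) { base$reason <- "ambiguous"; return(base) }
    h <- hits[[1]]
    base$chrom <- h$chrom
    base$pos <- if (h$strand == "+") h$start + offset
                else h$start + (length(fl) - 1L - offset)
    base$hit_quality <- 1
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Import marker placements from a precomputed BLAST tabular search
#'
#' For assemblies too large for exact in-memory search, accepts the 12-column
#' tabular output of a flank-vs-assembly search and applies the same
#' single-top-hit rule: the best bit-score hit places the marker, a tie for
#' best leaves it unplaced as ambiguous.
#'
#' @param path BLAST tabular file (qseqid = marker id, sseqid = chromosome).
#' @param markers data.frame with `marker`, `linkage_group`, `cm`.
#' @param offset distance from flank start to the marker position.
#' @return same layout as [place_markers()].
#' @export
place_markers_blast <- function(path, markers, offset = 250) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 12) stop("expected 12-column BLAST tabular input")
  names(df) <- c("marker", "chrom", "pident", "length", "mismatch", "gapopen",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  rows <- lapply(markers$marker, function(mk) {
    base <- data.frame(marker = mk,
                       linkage_group = markers$linkage_group[markers$marker == mk][1],
                       cm = markers$cm[markers$marker == mk][1],
                       chrom = NA_character_, pos = NA_integer_,
                       hit_quality = NA_real_, reason = "",
                       stringsAsFactors = FALSE)
    h <- df[df$marker == mk, , drop = FALSE]
    if (!nrow(h)) { base$reason <- "no_hit"; return(base) }
    best <- h[h$bitscore == max(h$bitscore), , drop = FALSE]
    if (nrow(best) > 1) { base$reason <- "ambiguous"; return(base) }
    base$chrom <- best$chrom
    base$pos <- min(best$sstart, best$send) - 1L + offset
    base$hit_quality <- best$bitscore
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect breaks between genetic and physical marker order
#'
#' Markers on each chromosome are sorted by physical position; the chromosome
#' is first orientation-normalized (the cM axis is flipped when its global
#' Spearman correlation with bp is negative, so a genome-wide strand flip is
#' not a break). A sliding window of `window` markers is then rank-correlated
#' (cM vs bp) and a break is reported wherever the windowed correlation sign
#' changes between consecutive windows; the break interval is the physical
#' gap spanned by the markers driving the transition.
#'
#' @param placements placements from [place_markers()]; unplaced markers are
#'   ignored.
#' @param window sliding-window size in markers (default 5).
#' @param min_markers chromosomes with fewer placed markers are skipped with a
#'   warning (default 10).
#' @return data.frame: `chrom`, `start`, `end`, `marker_left`, `marker_right`.
#' @export
detect_map_breaks <- function(placements, window = 5, min_markers = 10) {
  pl <- placements[!is.na(placements$pos), , drop = FALSE]
  out <- list()
  for (sub in split(pl, pl$chrom)) {
    if (nrow(sub) < min_markers) {
      warning(sprintf("chromosome %s skipped: only %d placed markers",
                      sub$chrom[1], nrow(sub)))
      next
    }
    sub <- sub[order(sub$pos), , drop = FALSE]
    rho_all <- suppressWarnings(cor(sub$cm, sub$pos, method = "spearman"))
    cm <- if (!is.na(rho_all) && rho_all < 0) max(sub$cm) - sub$cm else sub$cm
    n <- nrow(sub)
    nw <- n - window + 1L
    rho <- vapply(seq_len(nw), function(i) {
      r <- suppressWarnings(cor(cm[i:(i + window - 1L)],
                                sub$pos[i:(i + window - 1L)],
                                method = "spearman"))
      if (is.na(r)) 0 else r
    }, numeric(1))
    s <- sign(rho)
    # carry the previous sign through flat (zero) windows
    for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
    flips <- which(s[-1] != 0 & s[-length(s)] != 0 & s[-1] != s[-length(s)])
    # a single transition zone can flip the windowed sign on consecutive
    # windows; keep one break per zone (zones of a real inversion sit at
    # least the inverted run length minus the window apart)
    if (length(flips) > 1) flips <- flips[c(TRUE, diff(flips) > 2)]
    for (k in flips) {
      # sign changed between windows k and k+1: the transition is driven by
      # markers k .. k+window, so the break lies in that physical span
      lo <- max(1L, k - 1L); hi <- min(n, k + window)
      out[[length(out) + 1]] <- data.frame(
        chrom = sub$chrom[1], start = sub$pos[lo], end = sub$pos[hi],
        marker_left = sub$marker[lo], marker_right = sub$marker[hi],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      marker_left = character(), marker_right = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
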