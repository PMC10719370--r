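#' @importFrom stats rnorm runif rbeta setNames aggregate cor sd
#' @importFrom utils read.delim write.table head tail
NULL

# Internal coordinates are 0-based half-open everywhere; conversion happens only
# at file boundaries (GFF3 and SAM are 1-based inclusive on disk).

#' Infer a subgenome label from a chromosome name
#'
#' Chromosome names following the `<prefix><index><A|B>` convention (e.g.
#' `Cq3B`) map to subgenome `"A"` or `"B"`; anything else maps to `"none"`.
#' An explicit named map overrides the convention.
#'
#' @param chrom character vector of chromosome names.
#' @param subgenome_map optional named character vector `chrom -> subgenome`.
#' @return character vector of `"A"`, `"B"` or `"none"`.
#' @export
subgenome_of <- function(chrom, subgenome_map = NULL) {
  out <- ifelse(grepl("[0-9]A$", chrom), "A",
         ifelse(grepl("[0-9]B$", chrom), "B", "none"))
  if (!is.null(subgenome_map)) {
    hit <- chrom %in% names(subgenome_map)
    out[hit] <- unname(subgenome_map[chrom[hit]])
  }
  out
}

#' Homoeologous partner of a chromosome
#'
#' Swaps the trailing subgenome letter (`Cq1A` <-> `Cq1B`). Names without a
#' trailing A/B return `NA`.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector of partner names.
#' @export
homoeolog_of <- function(chrom) {
  out <- rep(NA_character_, length(chrom))
  a <- grepl("[0-9]A$", chrom); b <- grepl("[0-9]B$", chrom)
  out[a] <- sub("A$", "B", chrom[a])
  out[b] <- sub("B$", "A", chrom[b])
  out
}

#' Index of a chromosome within its (sub)genome
#'
#' Extracts the trailing integer before an optional subgenome letter, so
#' `Cq12B` and `Su12` both give 12. Used to pair a tetraploid chromosome with
#' its diploid-relative counterpart.
#'
#' @param chrom character vector of chromosome names.
#' @return integer vector.
#' @export
chrom_index <- function(chrom) {
  as.integer(sub("^.*?([0-9]+)[AB]?$", "\\1", chrom))
}

assign_ranks <- function(df) {
  # 0-based ordinal position of each feature along its chromosome, by start
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  df$rank <- stats::ave(df$start, df$chrom, FUN = seq_along) - 1L
  df$rank <- as.integer(df$rank)
  rownames(df) <- NULL
  df
}

precheck_gff3 <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  if (!length(body)) return(invisible(lines))
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nfield != 9L]
  if (length(bad)) {
    stop(sprintf("malformed GFF3 line %d in '%s': expected 9 tab-separated fields, found %d",
                 bad[1], path, nfield[which(body == bad[1])]))
  }
  f45 <- strsplit(lines[body], "\t", fixed = TRUE)
  st <- suppressWarnings(as.numeric(vapply(f45, `[`, "", 4L)))
  en <- suppressWarnings(as.numeric(vapply(f45, `[`, "", 5L)))
  rev <- which(!is.na(st) & !is.na(en) & en < st)
  if (length(rev)) {
    stop(sprintf("invalid GFF3 line %d in '%s': end (%d) < start (%d)",
                 body[rev[1]], path, as.integer(en[rev[1]]), as.integer(st[rev[1]])))
  }
  invisible(lines)
}

#' Read gene or repeat annotations from GFF3
#'
#' Coordinates are converted from GFF3's 1-based inclusive convention to the
#' package-internal 0-based half-open convention. For `kind = "gene"` only
#' features of type `gene` are kept and gene ranks (0-based order along each
#' chromosome) are assigned; for `kind = "repeat"` the `Family`, `Superfamily`
#' and `Complete` attributes are read.
#'
#' @param path GFF3 file.
#' @param kind `"gene"` or `"repeat"`.
#' @param genome_label label stored with every record (e.g. `"tetraploid"`).
#' @param subgenome_map optional named map `chrom -> subgenome` overriding the
#'   trailing-letter naming convention.
#' @return a data.frame of gene records (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `genome_label`, `subgenome`, `rank`) or repeat copies
#'   (`family`, `superfamily`, `chrom`, `start`, `end`, `complete`,
#'   `genome_label`, `subgenome`).
#' @export
read_gff3 <- function(path, kind = c("gene", "repeat"), genome_label = "genome",
                      subgenome_map = NULL) {
  kind <- match.arg(kind)
  precheck_gff3(path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) {
    return(if (kind == "gene") empty_genes(genome_label) else empty_repeats(genome_label))
  }
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  if (kind == "gene") {
    keep <- type == "gene"
    id <- as.character(mc$ID)
    if (all(is.na(id[keep]))) stop("gene GFF3 lacks ID attributes: ", path)
    df <- data.frame(
      gene_id = id[keep], chrom = chrom[keep],
      start = start0[keep], end = end0[keep],
      strand = as.character(GenomicRanges::strand(gr))[keep],
      genome_label = genome_label,
      subgenome = subgenome_of(chrom[keep], subgenome_map),
      stringsAsFactors = FALSE)
    if (anyDuplicated(df$gene_id)) stop("duplicate gene IDs in ", path)
    assign_ranks(df)
  } else {
    fam <- if ("Family" %in% names(mc)) as.character(mc$Family) else type
    sup <- if ("Superfamily" %in% names(mc)) as.character(mc$Superfamily) else NA_character_
    comp <- if ("Complete" %in% names(mc)) as.character(mc$Complete) %in% c("true", "TRUE", "1") else FALSE
    df <- data.frame(
      family = fam, superfamily = sup, chrom = chrom,
      start = start0, end = end0, complete = comp,
      genome_label = genome_label,
      subgenome = subgenome_of(chrom, subgenome_map),
      stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$start), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
}

empty_genes <- function(genome_label = "genome") {
  data.frame(gene_id = character(), chrom = character(), start = integer(),
             end = integer(), strand = character(), genome_label = character(),
             subgenome = character(), rank = integer(), stringsAsFactors = FALSE)
}

empty_repeats <- function(genome_label = "genome") {
  data.frame(family = character(), superfamily = character(), chrom = character(),
             start = integer(), end = integer(), complete = logical(),
             genome_label = character(), subgenome = character(),
             stringsAsFactors = FALSE)
}

#' Write gene or repeat records to GFF3
#'
#' The inverse of [read_gff3()]: internal 0-based half-open coordinates are
#' converted back to 1-based inclusive on disk, so write-then-read round-trips.
#'
#' @param records data.frame as returned by [read_gff3()].
#' @param path output file.
#' @param kind `"gene"` or `"repeat"`.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(records, path, kind = c("gene", "repeat")) {
  kind <- match.arg(kind)
  if (nrow(records) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  if (kind == "gene") {
    gr <- GenomicRanges::GRanges(records$chrom,
      IRanges::IRanges(records$start + 1L, records$end),
      strand = records$strand)
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- records$gene_id
  } else {
    gr <- GenomicRanges::GRanges(records$chrom,
      IRanges::IRanges(records$start + 1L, records$end), strand = "+")
    S4Vectors::mcols(gr)$type <- "repeat_region"
    S4Vectors::mcols(gr)$ID <- sprintf("rep%06d", seq_len(nrow(records)))
    S4Vectors::mcols(gr)$Family <- records$family
    S4Vectors::mcols(gr)$Superfamily <- records$superfamily
    S4Vectors::mcols(gr)$Complete <- ifelse(records$complete, "true", "false")
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read homologous gene pairs from BLAST tabular output
#'
#' Expects the standard 12-column `-outfmt 6` layout (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore). Rows above
#' the e-value threshold and self-pairs are dropped.
#'
#' @param path tab-separated file.
#' @param max_evalue keep rows with `evalue <= max_evalue` (default `1e-10`).
#' @return data.frame with columns `gene_q`, `gene_s`, `pident`, `evalue`,
#'   `score` (bit score).
#' @export
read_blast_tab <- function(path, max_evalue = 1e-10) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(empty_anchors())
  if (ncol(df) != 12) {
    stop(sprintf("BLAST tabular parse error in '%s': expected 12 columns, found %d",
                 path, ncol(df)))
  }
  names(df) <- c("gene_q", "gene_s", "pident", "length", "mismatch", "gapopen",
                 "qstart", "qend", "sstart", "send", "evalue", "score")
  df <- df[df$evalue <= max_evalue & df$gene_q != df$gene_s, , drop = FALSE]
  rownames(df) <- NULL
  df[, c("gene_q", "gene_s", "pident", "evalue", "score")]
}

empty_anchors <- function() {
  data.frame(gene_q = character(), gene_s = character(), pident = numeric(),
             evalue = numeric(), score = numeric(), stringsAsFactors = FALSE)
}

#' Write anchor pairs as 12-column BLAST tabular
#'
#' @param anchors data.frame with `gene_q`, `gene_s`, `score`, `evalue`
#'   (and optionally `pident`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(anchors, path) {
  pid <- if ("pident" %in% names(anchors)) anchors$pident else rep(95, nrow(anchors))
  out <- data.frame(anchors$gene_q, anchors$gene_s, pid, 300L, 5L, 0L, 1L, 300L,
                    1L, 300L, anchors$evalue, anchors$score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

cigar_ref_width <- function(cigar) {
  out <- integer(length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)      # fast path for all-match CIGARs
  out[simple] <- as.integer(sub("M$", "", cigar[simple]))
  for (i in which(!simple)) {
    cg <- cigar[i]
    if (cg == "*") next
    parts <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", parts))
    op <- sub("^[0-9]+", "", parts)
    # reference-consuming ops: M, D, N, =, X
    out[i] <- sum(n[op %in% c("M", "D", "N", "=", "X")])
  }
  out
}

#' Read paired-end alignments from a SAM file
#'
#' Mates are matched by read name; pairs where either mate has mapping quality
#' below `min_mapq` are excluded (per-read quality filtering applied pairwise).
#' The insert size is recomputed from the mate coordinates as the outer span
#' (rightmost mapped base of the rightmost mate minus leftmost mapped base of
#' the leftmost mate) rather than trusting the TLEN field, and is `NA` for
#' pairs whose mates map to different chromosomes. Unpaired reads at end of
#' file are dropped with a warning. BAM input can be converted upstream with
#' `samtools view -h`.
#'
#' @param path SAM file with `@SQ` header lines.
#' @param min_mapq minimum mapping quality for both mates (default 20).
#' @return data.frame with one row per pair: `read_id`, `chrom1`, `pos1`,
#'   `end1`, `mapq1`, `chrom2`, `pos2`, `end2`, `mapq2`, `insert`, `proper`.
#'   Positions are 0-based half-open, mate 1 is the leftmost mate. The header
#'   sequence lengths are attached as attribute `seqlengths`.
#' @export
read_sam <- function(path, min_mapq = 20) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  seqlens <- integer(0)
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    seqlens <- setNames(ln, sn)
  }
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(body)) {
    out <- empty_pairs()
    attr(out, "seqlengths") <- seqlens
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  qname <- vapply(f, `[`, "", 1L)
  flag <- as.integer(vapply(f, `[`, "", 2L))
  chrom <- vapply(f, `[`, "", 3L)
  pos <- as.integer(vapply(f, `[`, "", 4L)) - 1L   # SAM is 1-based
  mapq <- as.integer(vapply(f, `[`, "", 5L))
  cig <- vapply(f, `[`, "", 6L)
  mapped <- bitwAnd(flag, 4L) == 0L & chrom != "*"
  qname <- qname[mapped]; flag <- flag[mapped]; chrom <- chrom[mapped]
  pos <- pos[mapped]; mapq <- mapq[mapped]; cig <- cig[mapped]
  endp <- pos + cigar_ref_width(cig)
  first <- bitwAnd(flag, 64L) != 0L
  proper <- bitwAnd(flag, 2L) != 0L
  tab <- table(qname)
  paired_ids <- names(tab)[tab == 2L]
  if (length(paired_ids) < length(tab)) {
    warning(sprintf("%d reads without a mapped mate dropped from '%s'",
                    sum(tab != 2L), path))
  }
  keep <- qname %in% paired_ids
  if (!any(keep)) {
    out <- empty_pairs()
    attr(out, "seqlengths") <- seqlens
    return(out)
  }
  idx <- which(keep)
  ord <- idx[order(qname[idx], !first[idx])]
  i1 <- ord[seq(1, length(ord), by = 2)]
  i2 <- ord[seq(2, length(ord), by = 2)]
  # orient so mate 1 is the leftmost (or lexicographically first chromosome)
  swap <- chrom[i1] > chrom[i2] | (chrom[i1] == chrom[i2] & pos[i1] > pos[i2])
  a <- ifelse(swap, i2, i1); b <- ifelse(swap, i1, i2)
  df <- data.frame(
    read_id = qname[a],
    chrom1 = chrom[a], pos1 = pos[a], end1 = endp[a], mapq1 = mapq[a],
    chrom2 = chrom[b], pos2 = pos[b], end2 = endp[b], mapq2 = mapq[b],
    stringsAsFactors = FALSE)
  df$insert <- ifelse(df$chrom1 == df$chrom2,
                      pmax(df$end1, df$end2) - pmin(df$pos1, df$pos2), NA_integer_)
  df$proper <- proper[a] & proper[b]
  df <- df[df$mapq1 >= min_mapq & df$mapq2 >= min_mapq, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "seqlengths") <- seqlens
  df
}

empty_pairs <- function() {
  data.frame(read_id = character(), chrom1 = character(), pos1 = integer(),
             end1 = integer(), mapq1 = integer(), chrom2 = character(),
             pos2 = integer(), end2 = integer(), mapq2 = integer(),
             insert = integer(), proper = logical(), stringsAsFactors = FALSE)
}

#' Write paired alignments as SAM
#'
#' Emits two records per pair with minimal flags (paired, first/second in
#' pair, proper-pair bit for `proper` pairs), `*` sequence/quality and an
#' all-match CIGAR derived from the stored intervals. Inverse of [read_sam()]
#' for the fields that reader retains.
#'
#' @param pairs data.frame in the layout returned by [read_sam()].
#' @param path output file.
#' @param seqlengths named integer vector for the `@SQ` header; defaults to the
#'   `seqlengths` attribute of `pairs`.
#' @param mapq mapping quality to write when `pairs` lacks mapq columns.
#' @return `path`, invisibly.
#' @export
write_sam <- function(pairs, path, seqlengths = attr(pairs, "seqlengths"),
                      mapq = 60L) {
  if (is.null(seqlengths) || !length(seqlengths)) {
    stop("write_sam needs seqlengths for the @SQ header")
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), as.integer(seqlengths)))
  if (nrow(pairs) == 0) { writeLines(hdr, path); return(invisible(path)) }
  m1 <- if ("mapq1" %in% names(pairs)) pairs$mapq1 else rep(mapq, nrow(pairs))
  m2 <- if ("mapq2" %in% names(pairs)) pairs$mapq2 else rep(mapq, nrow(pairs))
  proper <- if ("proper" %in% names(pairs)) pairs$proper else rep(TRUE, nrow(pairs))
  f1 <- 1L + 64L + ifelse(proper, 2L, 0L) + 32L            # mate reverse strand
  f2 <- 1L + 128L + ifelse(proper, 2L, 0L) + 16L           # reverse strand
  rn2 <- ifelse(pairs$chrom2 == pairs$chrom1, "=", pairs$chrom2)
  rn1 <- ifelse(pairs$chrom1 == pairs$chrom2, "=", pairs$chrom1)
  rec1 <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t0\t*\t*",
                  pairs$read_id, f1, pairs$chrom1, pairs$pos1 + 1L, m1,
                  pairs$end1 - pairs$pos1, rn2, pairs$pos2 + 1L)
  rec2 <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t0\t*\t*",
                  pairs$read_id, f2, pairs$chrom2, pairs$pos2 + 1L, m2,
                  pairs$end2 - pairs$pos2, rn1, pairs$pos1 + 1L)
  writeLines(c(hdr, as.vector(rbind(rec1, rec2))), path)
  invisible(path)
}

#' Read a genetic-map marker table
#'
#' @param path TSV with columns `marker`, `linkage_group`, `cm`.
#' @return data.frame with those columns.
#' @export
read_marker_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("marker", "linkage_group", "cm")
  if (!all(need %in% names(df))) {
    stop("marker table must have columns: ", paste(need, collapse = ", "))
  }
  df
}
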