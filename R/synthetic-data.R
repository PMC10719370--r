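# Synthetic allotetraploid generator: two subgenomes of ordered gene arrays
# descended from two diploid gene orders, with planted rearrangements,
# subgenome-biased TE families, simulated paired-end alignments for accession
# panels, and machine-readable truth. Everything is driven by one global seed
# with per-component derived substreams, so each output is reproducible
# independently of generation order.

with_seed0 <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  code
}

substream <- function(seed, offset) (seed * 1009 + offset) %% 2147483647

#' Default planted rearrangements for the demo allotetraploid
#'
#' One reciprocal translocation (terminal 40-gene swap between the first two
#' B-subgenome chromosomes), one 52-gene pericentromeric inversion on the
#' third B chromosome, and one 12-gene tandem segmental duplication.
#'
#' @return list of event specifications.
#' @export
sim_default_events <- function() {
  list(
    list(kind = "reciprocal_translocation", chrom1 = "Cq1B", chrom2 = "Cq2B",
         n_genes = 40L),
    list(kind = "inversion", chrom = "Cq3B", start_gene = 75L, n_genes = 52L),
    list(kind = "segmental_duplication", chrom = "Cq2B", start_gene = 50L,
         n_genes = 12L))
}

#' Default TE family panel with planted subgenome biases
#'
#' Copy numbers are chosen so the truth classes span B-enriched, A-enriched,
#' subgenome-specific and not-enriched families across the LTR superfamilies,
#' with reduced copy numbers in the subgenomes relative to the diploids for
#' some families (fractionation) and expansions for others.
#'
#' @return data.frame of family specifications.
#' @export
sim_default_te_families <- function() {
  data.frame(
    family = c("GypsyFam1", "GypsyFam2", "CopiaFam1", "CopiaFam2",
               "TrimFam1", "SineFam1"),
    superfamily = c("Gypsy", "Gypsy", "Copia", "Copia", "TRIM_LARD", "SINE"),
    complete = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    copies_A = c(40L, 120L, 15L, 80L, 0L, 30L),
    copies_B = c(160L, 50L, 60L, 85L, 45L, 30L),
    copies_dipA = c(50L, 130L, 20L, 80L, 5L, 30L),
    copies_dipB = c(80L, 60L, 70L, 90L, 50L, 30L),
    mean_length = c(5000L, 5000L, 4000L, 4000L, 1500L, 300L),
    stringsAsFactors = FALSE)
}

#' Default accession panel for inversion genotyping
#'
#' @param n_carriers,n_noncarriers panel composition (default 10 + 10).
#' @param depth fold-coverage per accession (default 10).
#' @return data.frame: `accession`, `ecotype`, `carries_inversion`, `depth`.
#' @export
sim_default_panel <- function(n_carriers = 10, n_noncarriers = 10, depth = 10) {
  n <- n_carriers + n_noncarriers
  data.frame(
    accession = sprintf("acc%02d", seq_len(n)),
    ecotype = c(rep("coastal", n_carriers), rep("highland", n_noncarriers)),
    carries_inversion = c(rep(TRUE, n_carriers), rep(FALSE, n_noncarriers)),
    depth = depth, stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param seed global seed; all outputs are deterministic given it.
#' @param n_chrom chromosomes per subgenome (default 3).
#' @param genes_per_chrom genes per chromosome (default 200).
#' @param gene_length gene length in bp (default 1000).
#' @param chrom_length chromosome length in bp (default
#'   `2 * genes_per_chrom * gene_length`).
#' @param events planted rearrangements ([sim_default_events()]).
#' @param te_families TE family panel ([sim_default_te_families()]).
#' @param panel accession panel ([sim_default_panel()]).
#' @param read_length,insert_mean,insert_sd paired-end library geometry
#'   (defaults 100 / 400 / 40 bp).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_chrom = 3, genes_per_chrom = 200,
                       gene_length = 1000, chrom_length = NULL,
                       events = sim_default_events(),
                       te_families = sim_default_te_families(),
                       panel = sim_default_panel(),
                       read_length = 100, insert_mean = 400, insert_sd = 40) {
  if (is.null(chrom_length)) chrom_length <- 2L * genes_per_chrom * gene_length
  if (any(panel$depth <= 0)) stop("config error: depths must be > 0")
  if (insert_mean <= 2 * read_length) {
    stop("config error: insert_mean must exceed 2 * read_length")
  }
  for (ev in events) {
    chroms <- if (ev$kind == "reciprocal_translocation") c(ev$chrom1, ev$chrom2)
              else ev$chrom
    idx <- chrom_index(chroms)
    if (any(is.na(idx)) || any(idx < 1) || any(idx > n_chrom)) {
      stop("config error: event chromosome outside the simulated genome: ",
           paste(chroms, collapse = ", "))
    }
    if (!is.null(ev$start_gene) &&
        ev$start_gene + ev$n_genes - 1 > genes_per_chrom) {
      stop("config error: event exceeds chromosome bounds on ", chroms[1])
    }
    if (ev$n_genes > genes_per_chrom) {
      stop("config error: event larger than a chromosome")
    }
  }
  structure(list(seed = seed, n_chrom = n_chrom,
                 genes_per_chrom = genes_per_chrom, gene_length = gene_length,
                 chrom_length = chrom_length, events = events,
                 te_families = te_families, panel = panel,
                 read_length = read_length, insert_mean = insert_mean,
                 insert_sd = insert_sd),
            class = "sim_config")
}

# telomere-biased gene start layout (softened arcsine warp of a jittered
# grid: ~1.7x higher gene density at the chromosome ends than the middle),
# with a non-overlap pass; falls back to even spacing in the degenerate
# packed case
layout_positions <- function(n, L, gene_length) {
  u <- sort((seq_len(n) - 0.5) / n + runif(n, -0.3 / n, 0.3 / n))
  u <- pmin(pmax(u, 1e-6), 1 - 1e-6)
  pos <- round((0.7 * u + 0.3 * (1 - cos(pi * u)) / 2) * (L - gene_length))
  for (i in seq_len(n)[-1]) {
    if (pos[i] < pos[i - 1] + gene_length + 2) pos[i] <- pos[i - 1] + gene_length + 2
  }
  if (pos[n] + gene_length > L) {
    pos <- round(seq(0, L - gene_length, length.out = n))
  }
  as.integer(pos)
}

order_frame <- function(c_idx, n_genes) {
  data.frame(identity = sprintf("anc%dg%03d", c_idx, seq_len(n_genes)),
             strand = "+", tag = "", stringsAsFactors = FALSE)
}

apply_events <- function(orders, events) {
  for (k in seq_along(events)) {
    ev <- events[[k]]
    tag <- sprintf("ev%d", k)
    if (ev$kind == "reciprocal_translocation") {
      o1 <- orders[[ev$chrom1]]; o2 <- orders[[ev$chrom2]]
      n <- ev$n_genes
      i1 <- (nrow(o1) - n + 1):nrow(o1); i2 <- (nrow(o2) - n + 1):nrow(o2)
      seg1 <- o1[i1, ]; seg2 <- o2[i2, ]
      seg1$tag <- seg2$tag <- tag
      orders[[ev$chrom1]] <- rbind(o1[-i1, ], seg2)
      orders[[ev$chrom2]] <- rbind(o2[-i2, ], seg1)
    } else if (ev$kind == "inversion") {
      o <- orders[[ev$chrom]]
      i <- ev$start_gene:(ev$start_gene + ev$n_genes - 1)
      seg <- o[rev(i), ]
      seg$strand <- ifelse(seg$strand == "+", "-", "+")
      seg$tag <- tag
      o[i, ] <- seg
      orders[[ev$chrom]] <- o
    } else if (ev$kind == "segmental_duplication") {
      o <- orders[[ev$chrom]]
      i <- ev$start_gene:(ev$start_gene + ev$n_genes - 1)
      copy <- o[i, ]
      o$tag[i] <- paste0(tag, "a")
      copy$tag <- paste0(tag, "b")
      orders[[ev$chrom]] <- rbind(o[1:max(i), ], copy,
                                  if (max(i) < nrow(o)) o[(max(i) + 1):nrow(o), ])
    } else stop("unknown event kind: ", ev$kind)
  }
  orders
}

random_chrom_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate the synthetic allotetraploid and its diploid relatives
#'
#' Builds two diploid gene orders, derives the tetraploid subgenomes from
#' them, applies the planted rearrangements to the tetraploid, lays out gene
#' coordinates with density biased toward the telomeres, places TE copies
#' with centromere-proximal density bias, emits homologous gene pairs (shared
#' ancestral identity) as BLAST-tabular anchor tables, and records exact
#' truth intervals for every planted event.
#'
#' @param config a [sim_config()].
#' @param out_dir if non-`NULL`, GFF3/FASTA/BLAST/TSV files are written there.
#' @param sequences generate chromosome sequences (needed for FASTA output and
#'   marker flanks; default `TRUE`).
#' @return list with `genes` (tables for `tetraploid`, `diploidA`,
#'   `diploidB`), `anchors` (`self`, `A`, `B` for the within-tetraploid and
#'   versus-diploid comparisons), `repeats` (all genomes pooled),
#'   `chrom_lengths`, `sequences` (list of `DNAStringSet` or `NULL`), `truth`
#'   (`events`, `families`), `paths` (when written) and `config`.
#' @export
simulate_genomes <- function(config, out_dir = NULL, sequences = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  n_chrom <- config$n_chrom; npc <- config$genes_per_chrom
  gl <- config$gene_length; L <- config$chrom_length
  # ancestral orders shared by diploids and subgenomes
  anc <- lapply(seq_len(n_chrom), order_frame, n_genes = npc)
  dip_chrom <- list(A = sprintf("Pa%d", seq_len(n_chrom)),
                    B = sprintf("Su%d", seq_len(n_chrom)))
  tet_chrom <- list(A = sprintf("Cq%dA", seq_len(n_chrom)),
                    B = sprintf("Cq%dB", seq_len(n_chrom)))
  tet_orders <- c(setNames(anc, tet_chrom$A), setNames(anc, tet_chrom$B))
  tet_orders <- apply_events(tet_orders, config$events)

  build_genes <- function(chrom_names, orders, id_prefixes, genome_label, off) {
    tabs <- lapply(seq_along(chrom_names), function(ci) {
      o <- orders[[ci]]
      pos <- with_seed0(substream(config$seed, off + ci),
                        layout_positions(nrow(o), L, gl))
      data.frame(gene_id = sprintf("%s_g%03d", id_prefixes[ci], seq_len(nrow(o))),
                 chrom = chrom_names[ci], start = pos, end = pos + gl,
                 strand = o$strand, genome_label = genome_label,
                 subgenome = subgenome_of(chrom_names[ci]),
                 identity = o$identity, tag = o$tag, stringsAsFactors = FALSE)
    })
    assign_ranks(do.call(rbind, tabs))
  }
  genes_dipA <- build_genes(dip_chrom$A, anc, dip_chrom$A, "diploidA", 100)
  genes_dipB <- build_genes(dip_chrom$B, anc, dip_chrom$B, "diploidB", 200)
  tet_names <- c(tet_chrom$A, tet_chrom$B)
  genes_tet <- build_genes(tet_names, tet_orders[tet_names], tet_names,
                           "tetraploid", 300)

  # anchors join genes sharing ancestral identity
  make_anchors <- function(gq, gs, off) {
    m <- merge(gq[, c("gene_id", "identity")], gs[, c("gene_id", "identity")],
               by = "identity", suffixes = c("_q", "_s"))
    m <- m[order(m$gene_id_q, m$gene_id_s), , drop = FALSE]
    with_seed0(substream(config$seed, off), data.frame(
      gene_q = m$gene_id_q, gene_s = m$gene_id_s,
      pident = round(90 + runif(nrow(m)) * 9, 2), evalue = 1e-50,
      score = round(100 + runif(nrow(m)) * 10, 3), stringsAsFactors = FALSE))
  }
  tetA <- genes_tet[genes_tet$subgenome == "A", ]
  tetB <- genes_tet[genes_tet$subgenome == "B", ]
  anchors <- list(self = make_anchors(tetA, tetB, 400),
                  A = make_anchors(tetA, genes_dipA, 401),
                  B = make_anchors(tetB, genes_dipB, 402))

  # TE copies with centromere-proximal placement bias
  place_tes <- function(chroms, copies_col, genome_label, off) {
    fam <- config$te_families
    rows <- lapply(seq_len(nrow(fam)), function(fi) {
      n <- fam[[copies_col]][fi]
      if (n == 0) return(NULL)
      with_seed0(substream(config$seed, off * 1000 + fi), {
        len <- pmax(50L, as.integer(round(rnorm(n, fam$mean_length[fi],
                                                0.1 * fam$mean_length[fi]))))
        ch <- chroms[sample.int(length(chroms), n, replace = TRUE)]
        st <- as.integer(floor(rbeta(n, 2, 2) * (L - len)))
        data.frame(family = fam$family[fi], superfamily = fam$superfamily[fi],
                   chrom = ch, start = st, end = st + len,
                   complete = fam$complete[fi], genome_label = genome_label,
                   subgenome = subgenome_of(ch), stringsAsFactors = FALSE)
      })
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) empty_repeats() else out[order(out$chrom, out$start), ]
  }
  repeats <- rbind(place_tes(tet_chrom$A, "copies_A", "tetraploid", 5),
                   place_tes(tet_chrom$B, "copies_B", "tetraploid", 6),
                   place_tes(dip_chrom$A, "copies_dipA", "diploidA", 7),
                   place_tes(dip_chrom$B, "copies_dipB", "diploidB", 8))
  rownames(repeats) <- NULL

  # truth intervals from event tags, in final tetraploid coordinates
  tag_span <- function(tg, chrom = NULL) {
    sel <- genes_tet$tag == tg
    if (!is.null(chrom)) sel <- sel & genes_tet$chrom == chrom
    g <- genes_tet[sel, , drop = FALSE]
    list(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
         n = nrow(g))
  }
  truth_events <- do.call(rbind, lapply(seq_along(config$events), function(k) {
    ev <- config$events[[k]]; tag <- sprintf("ev%d", k)
    if (ev$kind == "reciprocal_translocation") {
      s1 <- tag_span(tag, ev$chrom1); s2 <- tag_span(tag, ev$chrom2)
      data.frame(kind = ev$kind, chrom1 = s1$chrom, start1 = s1$start,
                 end1 = s1$end, chrom2 = s2$chrom, start2 = s2$start,
                 end2 = s2$end, n_genes = s1$n + s2$n, stringsAsFactors = FALSE)
    } else if (ev$kind == "inversion") {
      s <- tag_span(tag)
      data.frame(kind = ev$kind, chrom1 = s$chrom, start1 = s$start,
                 end1 = s$end, chrom2 = NA, start2 = NA, end2 = NA,
                 n_genes = s$n, stringsAsFactors = FALSE)
    } else {
      s1 <- tag_span(paste0(tag, "a")); s2 <- tag_span(paste0(tag, "b"))
      data.frame(kind = ev$kind, chrom1 = s1$chrom, start1 = s1$start,
                 end1 = s1$end, chrom2 = s2$chrom, start2 = s2$start,
                 end2 = s2$end, n_genes = s1$n + s2$n, stringsAsFactors = FALSE)
    }
  }))
  fam <- config$te_families
  truth_families <- data.frame(
    family = fam$family,
    class = ifelse(fam$copies_A == 0 & fam$copies_B > 0, "B_specific",
            ifelse(fam$copies_B == 0 & fam$copies_A > 0, "A_specific",
            ifelse(fam$copies_A > 0 & fam$copies_B > 0 &
                     log2(fam$copies_B / fam$copies_A) >= 1, "B_enriched",
            ifelse(fam$copies_A > 0 & fam$copies_B > 0 &
                     log2(fam$copies_B / fam$copies_A) <= -1, "A_enriched",
            "not_enriched")))), stringsAsFactors = FALSE)

  all_chroms <- c(tet_names, dip_chrom$A, dip_chrom$B)
  chrom_lengths <- setNames(rep(L, length(all_chroms)), all_chroms)
  seqs <- NULL
  if (sequences) {
    seqs <- lapply(list(tetraploid = tet_names, diploidA = dip_chrom$A,
                        diploidB = dip_chrom$B), function(chs) {
      s <- vapply(seq_along(chs), function(i) {
        with_seed0(substream(config$seed, 9000 + match(chs[i], all_chroms)),
                   random_chrom_seq(L))
      }, "")
      Biostrings::DNAStringSet(setNames(s, chs))
    })
  }

  drop_aux <- function(g) g[, setdiff(names(g), c("identity", "tag"))]
  out <- list(genes = list(tetraploid = drop_aux(genes_tet),
                           diploidA = drop_aux(genes_dipA),
                           diploidB = drop_aux(genes_dipB)),
              genes_full = genes_tet,
              anchors = anchors, repeats = repeats,
              chrom_lengths = chrom_lengths, sequences = seqs,
              truth = list(events = truth_events, families = truth_families),
              paths = NULL, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- list()
    for (g in names(out$genes)) {
      p[[paste0("genes_", g)]] <- file.path(out_dir, paste0(g, ".gff3"))
      write_gff3(out$genes[[g]], p[[paste0("genes_", g)]], kind = "gene")
    }
    for (g in unique(repeats$genome_label)) {
      p[[paste0("repeats_", g)]] <- file.path(out_dir, paste0(g, ".repeats.gff3"))
      write_gff3(repeats[repeats$genome_label == g, ],
                 p[[paste0("repeats_", g)]], kind = "repeat")
    }
    for (a in names(anchors)) {
      p[[paste0("anchors_", a)]] <- file.path(out_dir,
                                              paste0("anchors_", a, ".blast.tsv"))
      write_blast_tab(anchors[[a]], p[[paste0("anchors_", a)]])
    }
    if (!is.null(seqs)) {
      for (g in names(seqs)) {
        p[[paste0("fasta_", g)]] <- file.path(out_dir, paste0(g, ".fa"))
        Biostrings::writeXStringSet(seqs[[g]], p[[paste0("fasta_", g)]])
      }
    }
    p$truth_events <- file.path(out_dir, "truth_events.tsv")
    write.table(truth_events, p$truth_events, sep = "\t", quote = FALSE,
                row.names = FALSE)
    p$truth_families <- file.path(out_dir, "truth_families.tsv")
    write.table(truth_families, p$truth_families, sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$paths <- p
  }
  out
}

project_to_reference <- function(s, e, L_bp, R_bp) {
  # accession interval [s, e) on a genome whose [L_bp, R_bp) segment is
  # inverted relative to the reference; reads crossing a breakpoint are
  # unmappable end-to-end and dropped (NA)
  inside <- s >= L_bp & e <= R_bp
  outside <- e <= L_bp | s >= R_bp
  ns <- ifelse(inside, L_bp + R_bp - e, ifelse(outside, s, NA))
  ne <- ifelse(inside, L_bp + R_bp - s, ifelse(outside, e, NA))
  list(start = ns, end = ne)
}

#' Simulate panel alignments around a large inversion
#'
#' The reference carries the inversion. Carrier accessions therefore produce
#' concordant pairs across both breakpoints; non-carriers are modeled by
#' re-inverting the segment and re-projecting mate coordinates, so fragments
#' straddling a breakpoint become discordant pairs with one mate near each
#' breakpoint and a recomputed insert close to the inversion span, while
#' reads crossing a breakpoint itself are dropped (no spanning reads).
#'
#' @param config a [sim_config()]; `panel`, `read_length`, `insert_mean`,
#'   `insert_sd` and `chrom_length` are used.
#' @param breakpoints list with `chrom`, `pos_left`, `pos_right` (0-based,
#'   inside the chromosome).
#' @param out_dir if non-`NULL`, one SAM per accession is written there.
#' @return list with `pairs` (named list of alignment-pair tables carrying
#'   `seqlengths`), `truth` (accession, expected class), `breakpoints`,
#'   `paths`.
#' @export
simulate_panel_alignments <- function(config, breakpoints, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$chrom_length; rl <- config$read_length
  Lb <- breakpoints$pos_left; Rb <- breakpoints$pos_right
  if (Lb < 0 || Rb > L || Lb >= Rb) stop("breakpoints outside the reference chromosome")
  sl <- setNames(L, breakpoints$chrom)
  pairs <- list(); paths <- list()
  for (k in seq_len(nrow(config$panel))) {
    acc <- config$panel$accession[k]
    depth <- config$panel$depth[k]
    n_pairs <- max(1L, as.integer(round(depth * L / (2 * rl))))
    df <- with_seed0(substream(config$seed, 20000 + k), {
      ins <- pmax(as.integer(round(rnorm(n_pairs, config$insert_mean,
                                         config$insert_sd))), 2L * rl + 2L)
      a <- as.integer(floor(runif(n_pairs) * (L - ins)))
      s1 <- a; e1 <- a + rl
      s2 <- a + ins - rl; e2 <- a + ins
      if (!config$panel$carries_inversion[k]) {
        p1 <- project_to_reference(s1, e1, Lb, Rb)
        p2 <- project_to_reference(s2, e2, Lb, Rb)
        keep <- !is.na(p1$start) & !is.na(p2$start)
        proper <- keep & ((e1 <= Lb | s1 >= Rb) == (e2 <= Lb | s2 >= Rb))
        s1 <- p1$start; e1 <- p1$end; s2 <- p2$start; e2 <- p2$end
      } else {
        keep <- rep(TRUE, n_pairs); proper <- keep
      }
      swap <- !is.na(s1) & !is.na(s2) & s1 > s2
      t1 <- s1; s1 <- ifelse(swap, s2, s1); s2 <- ifelse(swap, t1, s2)
      t1 <- e1; e1 <- ifelse(swap, e2, e1); e2 <- ifelse(swap, t1, e2)
      df <- data.frame(
        read_id = sprintf("%s_p%06d", acc, seq_len(n_pairs)),
        chrom1 = breakpoints$chrom, pos1 = s1, end1 = e1, mapq1 = 60L,
        chrom2 = breakpoints$chrom, pos2 = s2, end2 = e2, mapq2 = 60L,
        stringsAsFactors = FALSE)[keep, , drop = FALSE]
      df$insert <- pmax(df$end1, df$end2) - pmin(df$pos1, df$pos2)
      df$proper <- proper[keep]
      rownames(df) <- NULL
      df
    })
    attr(df, "seqlengths") <- sl
    pairs[[acc]] <- df
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      paths[[acc]] <- file.path(out_dir, paste0(acc, ".sam"))
      write_sam(df, paths[[acc]], seqlengths = sl)
    }
  }
  truth <- data.frame(
    accession = config$panel$accession,
    ecotype = config$panel$ecotype,
    class = ifelse(config$panel$carries_inversion, "present", "absent"),
    stringsAsFactors = FALSE)
  list(pairs = pairs, truth = truth, breakpoints = breakpoints,
       paths = if (length(paths)) unlist(paths) else NULL)
}

#' Simulate windowed diploid read-mapping rate tracks
#'
#' Emulates the mapping of the two diploid relatives' reads onto one
#' tetraploid chromosome, summarized as per-window mapping rates: the
#' expected relative maps at a high baseline and the alternative relative at
#' a low one, except inside a planted homoeologous-exchange region, where the
#' expected rate drops well below half the chromosome-wide mean and the
#' alternative rate rises. Gaussian noise is added per window and clipped to
#' the unit interval.
#'
#' @param n_windows number of windows (default 100).
#' @param swapped 1-based window index range of the planted exchange, e.g.
#'   `c(45, 55)`; `NULL` for none.
#' @param noise_sd per-window noise standard deviation (default 0).
#' @param seed seed for the noise.
#' @param chrom chromosome name.
#' @param window_bp window width in bp (default 1e6).
#' @param baseline_expected,baseline_alt baseline mapping rates (defaults
#'   0.9 / 0.1).
#' @param swap_factor multiplier on the expected rate inside the swap
#'   (default 0.4, placing the planted drop below the half-mean detection
#'   threshold).
#' @param alt_swap alternative-diploid rate inside the swap (default 0.8).
#' @return track data.frame (`chrom`, `start`, `end`, `rate_expected`,
#'   `rate_alt`) with the planted interval attached as attribute `truth`.
#' @export
simulate_diploid_readmap <- function(n_windows = 100, swapped = c(45, 55),
                                     noise_sd = 0, seed = 1, chrom = "Cq6B",
                                     window_bp = 1e6,
                                     baseline_expected = 0.9,
                                     baseline_alt = 0.1,
                                     swap_factor = 0.4, alt_swap = 0.8) {
  expected <- rep(baseline_expected, n_windows)
  alt <- rep(baseline_alt, n_windows)
  if (!is.null(swapped)) {
    idx <- swapped[1]:swapped[2]
    expected[idx] <- baseline_expected * swap_factor
    alt[idx] <- alt_swap
  }
  if (noise_sd > 0) {
    with_seed0(substream(seed, 31), {
      expected <- pmin(pmax(expected + rnorm(n_windows, 0, noise_sd), 0), 1)
      alt <- pmin(pmax(alt + rnorm(n_windows, 0, noise_sd), 0), 1)
    })
  }
  starts <- (seq_len(n_windows) - 1) * window_bp
  track <- data.frame(chrom = chrom, start = starts, end = starts + window_bp,
                      rate_expected = expected, rate_alt = alt,
                      stringsAsFactors = FALSE)
  if (!is.null(swapped)) {
    attr(track, "truth") <- data.frame(
      chrom = chrom, start = (swapped[1] - 1) * window_bp,
      end = swapped[2] * window_bp, stringsAsFactors = FALSE)
  }
  track
}

#' Simulate a genetic-map marker set over a planted inversion
#'
#' Markers are taken at evenly spaced genes along one tetraploid chromosome;
#' their genetic positions (cM) follow the ancestral (pre-inversion) gene
#' order, as a map built from non-carrier germplasm would, while flanks are
#' extracted from the reference assembly that carries the inversion. Markers
#' inside the planted inversion therefore disagree in order between the
#' genetic and physical axes.
#'
#' @param genomes output of [simulate_genomes()] (with sequences).
#' @param chrom chromosome to sample (default the planted inversion's).
#' @param n_markers number of markers (default 40).
#' @param cm_per_gene genetic spacing per ancestral gene index (default 0.5).
#' @param offset flank half-width (default 250).
#' @return list with `markers` (marker, linkage_group, cm), `flanks`
#'   (`DNAStringSet`), `truth` (the planted inversion interval on `chrom`, or
#'   `NULL`).
#' @export
simulate_marker_map <- function(genomes, chrom = NULL, n_markers = 40,
                                cm_per_gene = 0.5, offset = 250) {
  if (is.null(genomes$sequences)) stop("simulate_genomes() must be run with sequences = TRUE")
  ev <- genomes$truth$events
  if (is.null(chrom)) {
    inv <- ev[ev$kind == "inversion", , drop = FALSE]
    if (!nrow(inv)) stop("no planted inversion; pass chrom explicitly")
    chrom <- inv$chrom1[1]
  }
  g <- genomes$genes_full[genomes$genes_full$chrom == chrom, , drop = FALSE]
  g <- g[order(g$start), , drop = FALSE]
  pick <- unique(as.integer(round(seq(1, nrow(g), length.out = n_markers))))
  g <- g[pick, , drop = FALSE]
  anc_idx <- as.integer(sub("^anc[0-9]+g", "", g$identity))
  seq_chr <- genomes$sequences$tetraploid[[chrom]]
  pos <- as.integer(g$start + (g$end - g$start) %/% 2)
  ok <- pos - offset >= 0 & pos + offset <= length(seq_chr)
  g <- g[ok, , drop = FALSE]; pos <- pos[ok]; anc_idx <- anc_idx[ok]
  ids <- sprintf("mk_%s_%03d", chrom, seq_along(pos))
  fl <- Biostrings::DNAStringSet(lapply(pos, function(p) {
    Biostrings::subseq(seq_chr, p - offset + 1, p + offset)
  }))
  names(fl) <- ids
  markers <- data.frame(marker = ids,
                        linkage_group = paste0("LG", chrom_index(chrom)),
                        cm = anc_idx * cm_per_gene, stringsAsFactors = FALSE)
  inv <- ev[ev$kind == "inversion" & ev$chrom1 == chrom, , drop = FALSE]
  list(markers = markers, flanks = fl,
       truth = if (nrow(inv)) inv[1, c("chrom1", "start1", "end1")] else NULL)
}
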