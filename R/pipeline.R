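# End-to-end pipeline wiring: simulate (optional) -> collinearity ->
# rearrangements -> read evidence -> repeat dynamics -> map concordance,
# exchanging only documented file formats so real data can replace any
# synthetic input.

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are ignored.
#' Numeric-looking values are converted, `true`/`false` become logicals.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("config parse error at line: ", lines[which(bad)[1]])
  vals <- lapply(kv, function(x) {
    v <- x[2]
    if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  setNames(vals, vapply(kv, `[`, "", 1L))
}

default_pipeline_config <- function() {
  list(simulate = TRUE, seed = 1, out_dir = "polyrearrange_out",
       match_size = 8, max_gap_genes = 25, major_span = 1e6,
       major_genes = 100, min_coverage = 5, window_bp = 1e6,
       bp_window = 500, panel_size = 6, panel_depth = 10)
}

log_msg <- function(...) message("[polyrearrange] ", sprintf(...))

#' Run the full pipeline
#'
#' In `simulate` mode a synthetic allotetraploid is generated first and every
#' downstream stage consumes the files it wrote, exercising the documented
#' formats end to end; with `simulate = false` the configuration must name
#' the input files (`tetraploid_gff3`, `diploidA_gff3`, `diploidB_gff3`,
#' `anchors_self`, `anchors_A`, `anchors_B`, optionally `repeats_gff3`,
#' `panel_tsv`). Writes block, event, call, repeat and marker tables plus a
#' markdown summary report under `out_dir`.
#'
#' @param config named list (see [read_pipeline_config()]); missing keys take
#'   defaults.
#' @param dry_run print the stage plan and exit without executing.
#' @return (invisibly) list with the main stage outputs and `report_path`.
#' @export
run_all <- function(config = list(), dry_run = FALSE) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  stages <- c("simulate"[isTRUE(cfg$simulate)], "collinearity",
              "rearrangements", "read_evidence", "repeat_dynamics",
              "map_concordance", "report")
  if (dry_run) {
    cat("stage plan:", paste(stages, collapse = " -> "), "\n")
    return(invisible(NULL))
  }
  path_keys <- c("tetraploid_gff3", "diploidA_gff3", "diploidB_gff3",
                 "anchors_self", "anchors_A", "anchors_B", "repeats_gff3",
                 "panel_tsv")
  if (!isTRUE(cfg$simulate)) {
    need <- c("tetraploid_gff3", "diploidA_gff3", "diploidB_gff3", "anchors_self")
    for (k in need) {
      if (is.null(cfg[[k]])) stop("config error: missing required input ", k)
    }
    for (k in intersect(path_keys, names(cfg))) {
      if (!file.exists(cfg[[k]])) stop("config error: input does not exist: ", cfg[[k]])
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    p <- file.path(cfg$out_dir, name)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  sim <- NULL
  if (isTRUE(cfg$simulate)) {
    log_msg("stage simulate: seed %d", as.integer(cfg$seed))
    scfg <- sim_config(seed = as.integer(cfg$seed),
                       panel = sim_default_panel(
                         n_carriers = cfg$panel_size %/% 2,
                         n_noncarriers = cfg$panel_size - cfg$panel_size %/% 2,
                         depth = cfg$panel_depth))
    sim <- simulate_genomes(scfg, out_dir = file.path(cfg$out_dir, "sim"))
    cfg$tetraploid_gff3 <- sim$paths$genes_tetraploid
    cfg$diploidA_gff3 <- sim$paths$genes_diploidA
    cfg$diploidB_gff3 <- sim$paths$genes_diploidB
    cfg$anchors_self <- sim$paths$anchors_self
    cfg$anchors_A <- sim$paths$anchors_A
    cfg$anchors_B <- sim$paths$anchors_B
    cfg$repeats_gff3 <- sim$paths$repeats_tetraploid
  }

  log_msg("stage collinearity: match_size %d", as.integer(cfg$match_size))
  tet <- read_gff3(cfg$tetraploid_gff3, "gene", genome_label = "tetraploid")
  dipA <- read_gff3(cfg$diploidA_gff3, "gene", genome_label = "diploidA")
  dipB <- read_gff3(cfg$diploidB_gff3, "gene", genome_label = "diploidB")
  tetA <- tet[tet$subgenome == "A", ]; tetB <- tet[tet$subgenome == "B", ]
  chain <- function(anchors_path, gq, gs) {
    a <- dedupe_anchors(read_blast_tab(anchors_path), gq, gs)
    chain_collinear_blocks(a, gq, gs, match_size = as.integer(cfg$match_size),
                           max_gap_genes = as.integer(cfg$max_gap_genes))
  }
  blocks_self <- chain(cfg$anchors_self, tetA, tetB)
  blocks_dip <- list(
    A = if (!is.null(cfg$anchors_A)) chain(cfg$anchors_A, tetA, dipA),
    B = if (!is.null(cfg$anchors_B)) chain(cfg$anchors_B, tetB, dipB))
  totals <- c("tetraploid vs tetraploid" = nrow(tetA) + nrow(tetB))
  coll_sum <- collinearity_summary(blocks_self, totals)
  tsv(coll_sum, "collinearity_summary.tsv")
  write_blocks_tsv(blocks_self, file.path(cfg$out_dir, "blocks_self.tsv"))

  log_msg("stage rearrangements")
  events <- call_rearrangements(blocks_self, blocks_dip, tet,
                                min_dup_genes = as.integer(cfg$match_size),
                                major_span = cfg$major_span,
                                major_genes = cfg$major_genes)
  sg_sizes <- tapply(rep(if (!is.null(sim)) sim$config$chrom_length else
    max(tet$end), length(unique(tet$chrom))),
    subgenome_of(unique(tet$chrom)), sum)
  totals_tab <- rearrangement_totals(events, as.list(sg_sizes), genes = tet)
  tsv(events, "events.tsv")
  write_events_bed(events, file.path(cfg$out_dir, "events.bed"))
  tsv(totals_tab$by_subgenome, "rearrangement_totals.tsv")

  log_msg("stage read_evidence")
  calls <- gsum <- NULL
  if (!is.null(sim)) {
    L <- sim$config$chrom_length
    bpt <- list(chrom = "Cq3B", pos_left = as.integer(0.25 * L),
                pos_right = as.integer(0.75 * L))
    panel <- simulate_panel_alignments(sim$config, bpt,
                                       out_dir = file.path(cfg$out_dir, "sim"))
    bp <- breakpoint_pair(bpt$chrom, bpt$pos_left, bpt$pos_right,
                          window = cfg$bp_window)
    calls <- genotype_panel(panel$paths, bp,
                            min_genome_coverage = cfg$min_coverage)
    gsum <- genotype_summary(calls, setNames(panel$truth$ecotype,
                                             panel$truth$accession))
    tsv(calls, "inversion_calls.tsv")
    tsv(gsum, "genotype_summary.tsv")
  } else if (!is.null(cfg$panel_tsv)) {
    panel_tab <- read.delim(cfg$panel_tsv, stringsAsFactors = FALSE)
    bp <- breakpoint_pair(cfg$bp_chrom, cfg$bp_left, cfg$bp_right,
                          window = cfg$bp_window,
                          insert_min = cfg$insert_min,
                          insert_max = cfg$insert_max)
    calls <- genotype_panel(setNames(panel_tab$path, panel_tab$accession), bp,
                            min_genome_coverage = cfg$min_coverage)
    gsum <- genotype_summary(calls, setNames(panel_tab$ecotype,
                                             panel_tab$accession))
    tsv(calls, "inversion_calls.tsv")
    tsv(gsum, "genotype_summary.tsv")
  } else log_msg("read_evidence skipped: no panel input")

  log_msg("stage repeat_dynamics")
  rep_stats <- enr <- NULL
  if (!is.null(cfg$repeats_gff3)) {
    reps <- read_gff3(cfg$repeats_gff3, "repeat", genome_label = "tetraploid")
    rep_stats <- summarize_repeats(reps)
    enr <- ltr_family_enrichment(rep_stats)
    dens <- window_density(reps, setNames(
      rep(if (!is.null(sim)) sim$config$chrom_length else max(tet$end),
          length(unique(tet$chrom))), unique(tet$chrom)),
      window_bp = cfg$window_bp)
    tsv(rep_stats, "repeat_family_stats.tsv")
    tsv(enr, "ltr_enrichment.tsv")
    p <- file.path(cfg$out_dir, "repeat_density.bed")
    write.table(dens, p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else log_msg("repeat_dynamics skipped: no repeat annotation")

  log_msg("stage map_concordance")
  breaks <- NULL
  if (!is.null(sim) && !is.null(sim$sequences)) {
    mm <- simulate_marker_map(sim)
    plc <- place_markers(mm$flanks, sim$sequences$tetraploid, mm$markers)
    breaks <- detect_map_breaks(plc)
    tsv(plc, "marker_placements.tsv")
    tsv(breaks, "map_breaks.tsv")
  } else log_msg("map_concordance skipped: no marker input")

  log_msg("stage report")
  rp <- file.path(cfg$out_dir, "report.md")
  fmt_tab <- function(df) {
    if (is.null(df) || !nrow(df)) return("(none)")
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) round(x, 3))
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, paste, collapse = " | "))
  }
  lines <- c("# polyrearrange report", "",
             sprintf("seed: %d", as.integer(cfg$seed)), "",
             "## Collinearity", fmt_tab(coll_sum), "",
             "## Rearrangement events",
             fmt_tab(events[, c("event_id", "kind", "chrom1", "start1", "end1",
                                "chrom2", "n_genes", "span_bp", "major")]), "",
             "## Rearranged bp by subgenome", fmt_tab(totals_tab$by_subgenome), "",
             "## Inversion genotypes", fmt_tab(gsum), "",
             "## Genetic-vs-physical map breaks", fmt_tab(breaks), "")
  writeLines(lines, rp)
  log_msg("report written to %s", rp)
  invisible(list(blocks_self = blocks_self, events = events,
                 totals = totals_tab, calls = calls, genotype_summary = gsum,
                 repeat_stats = rep_stats, enrichment = enr,
                 map_breaks = breaks, report_path = rp))
}
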