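# Marker placement by flank search and genetic-vs-physical break detection.

random_assembly <- function(lens, seed = 1) {
  withr::with_seed(seed, {
    Biostrings::DNAStringSet(setNames(vapply(lens, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, ""), names(lens)))
  })
}

marker_set <- function(n, L = 1e6, seed = 1, invert_middle = FALSE) {
  # evenly spaced physical positions; cM follows the same order unless the
  # middle third of the marker order is inverted
  pos <- as.integer(round(seq(0.05, 0.95, length.out = n) * L))
  cm <- seq_len(n) * 1.5
  if (invert_middle) {
    third <- (n %/% 3 + 1):(2 * (n %/% 3))
    cm[third] <- rev(cm[third])
  }
  data.frame(marker = sprintf("m%03d", seq_len(n)), linkage_group = "LG1",
             cm = cm, chrom = "Cq1A", pos = pos, hit_quality = 1, reason = "",
             stringsAsFactors = FALSE)
}

test_that("unique exact flanks place markers at match start plus offset", {
  asm <- random_assembly(c(Cq1A = 50000L), seed = 5)
  pos <- c(10000L, 25000L, 40000L)
  fl <- Biostrings::DNAStringSet(lapply(pos, function(p) {
    Biostrings::subseq(asm[[1]], p - 250 + 1, p + 250)
  }))
  names(fl) <- sprintf("mk%02d", seq_along(pos))
  markers <- data.frame(marker = names(fl), linkage_group = "LG1",
                        cm = seq_along(pos), stringsAsFactors = FALSE)
  plc <- place_markers(fl, asm, markers)
  expect_equal(plc$pos, pos)
  expect_equal(plc$chrom, rep("Cq1A", 3))
})

test_that("absent, duplicated and short flanks stay unplaced with reasons", {
  asm <- random_assembly(c(Cq1A = 20000L), seed = 6)
  # plant an exact duplicate of a 500-mer
  dup <- Biostrings::subseq(asm[[1]], 1001, 1500)
  seqs <- paste0(as.character(asm[[1]]), as.character(dup))
  asm2 <- Biostrings::DNAStringSet(setNames(seqs, "Cq1A"))
  fl <- Biostrings::DNAStringSet(c(
    absent = paste(rep("ACGT", 125), collapse = ""),
    dup = as.character(dup),
    short = "ACGTACGT"))
  markers <- data.frame(marker = names(fl), linkage_group = "LG1", cm = 1:3,
                        stringsAsFactors = FALSE)
  plc <- place_markers(fl, asm2, markers)
  expect_equal(plc$reason, c("no_hit", "ambiguous", "too_short"))
  expect_true(all(is.na(plc$pos)))
  expect_error(place_markers(fl, Biostrings::DNAStringSet(), markers), "empty")
})

test_that("monotone and globally reversed maps yield no breaks", {
  mono <- marker_set(30)
  expect_equal(nrow(detect_map_breaks(mono)), 0)
  flipped <- mono
  flipped$cm <- max(mono$cm) - mono$cm  # whole-chromosome orientation flip
  expect_equal(nrow(detect_map_breaks(flipped)), 0)
})

test_that("an inverted middle third produces exactly two breaks containing the endpoints", {
  n <- 30
  pl <- marker_set(n, invert_middle = TRUE)
  br <- detect_map_breaks(pl)
  expect_equal(nrow(br), 2)
  third <- (n %/% 3 + 1):(2 * (n %/% 3))
  true_left <- mean(pl$pos[c(min(third) - 1, min(third))])
  true_right <- mean(pl$pos[c(max(third), max(third) + 1)])
  expect_true(br$start[1] <= true_left && true_left <= br$end[1])
  expect_true(br$start[2] <= true_right && true_right <= br$end[2])
})

test_that("break detection is invariant to reversing either map axis", {
  n <- 30
  pl <- marker_set(n, invert_middle = TRUE)
  br <- detect_map_breaks(pl)
  # genetic axis reversed
  g <- pl; g$cm <- max(pl$cm) - pl$cm
  expect_equal(nrow(detect_map_breaks(g)), nrow(br))
  # physical axis reversed: breaks mirror
  L <- 1e6
  p <- pl; p$pos <- L - pl$pos
  brp <- detect_map_breaks(p)
  expect_equal(nrow(brp), nrow(br))
  mirrored <- sort(c(L - br$start, L - br$end))
  got <- sort(c(brp$start, brp$end))
  expect_equal(got, mirrored)
})

test_that("planted inversions always fall inside reported break intervals", {
  for (seed in 1:100) {
    n <- 24 + seed %% 12
    pl <- marker_set(n, seed = seed, invert_middle = TRUE)
    # jitter physical positions without reordering markers
    pl$pos <- pl$pos + withr::with_seed(seed, as.integer(runif(n, -5000, 5000)))
    br <- detect_map_breaks(pl)
    third <- (n %/% 3 + 1):(2 * (n %/% 3))
    true_left <- mean(pl$pos[c(min(third) - 1, min(third))])
    true_right <- mean(pl$pos[c(max(third), max(third) + 1)])
    expect_true(any(br$start <= true_left & true_left <= br$end),
                info = paste("seed", seed))
    expect_true(any(br$start <= true_right & true_right <= br$end),
                info = paste("seed", seed))
  }
})

test_that("chromosomes with too few markers are skipped with a warning", {
  pl <- marker_set(6)
  expect_warning(br <- detect_map_breaks(pl), "skipped")
  expect_equal(nrow(br), 0)
})

test_that("BLAST-import placement applies the single-top-hit rule", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "m1\tCq1A\t100\t500\t0\t0\t1\t500\t1001\t1500\t0\t990",
    "m2\tCq1A\t100\t500\t0\t0\t1\t500\t2001\t2500\t0\t990",
    "m2\tCq1B\t100\t500\t0\t0\t1\t500\t5001\t5500\t0\t990",
    "m3\tCq1A\t95\t500\t5\t0\t1\t500\t9001\t9500\t0\t700",
    "m3\tCq1B\t90\t500\t9\t0\t1\t500\t7001\t7500\t0\t500"), p)
  markers <- data.frame(marker = c("m1", "m2", "m3"), linkage_group = "LG1",
                        cm = 1:3, stringsAsFactors = FALSE)
  plc <- place_markers_blast(p, markers)
  expect_equal(plc$pos[plc$marker == "m1"], 1000L + 250L)
  expect_equal(plc$reason[plc$marker == "m2"], "ambiguous")  # tied best hits
  expect_equal(plc$chrom[plc$marker == "m3"], "Cq1A")        # best bit score
})
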