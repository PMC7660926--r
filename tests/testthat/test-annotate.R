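freq_tsv <- function(rows) {
  paste(c("variant\tallele_count\tallele_number\tfrequency", rows),
        collapse = "\n")
}

test_that("frequency tables load, validate and report rejects", {
  tab <- load_frequency_table(freq_tsv(c(
    "K508R\t20\t100000\t2.0e-4",
    "R362C\t5\t100000\t5e-05")))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$frequency[tab$variant == "K508R"], 2e-4)
  # inconsistent frequency is rejected with a reason, not dropped silently
  bad <- load_frequency_table(freq_tsv(c(
    "K508R\t20\t100000\t2.0e-4",
    "V400I\t10\t100000\t9.9e-4",
    "ZZ9XX\t1\t100000\t1e-5")))
  expect_equal(nrow(bad), 1L)
  rejects <- attr(bad, "rejects")
  expect_equal(nrow(rejects), 2L)
  expect_match(rejects$reason[rejects$variant == "V400I"], "inconsistent")
  # empty file with header
  empty <- load_frequency_table(freq_tsv(character(0)))
  expect_equal(nrow(empty), 0L)
  expect_error(load_frequency_table("variant\tfrequency\nK508R\t0.1"),
               "lacks column")
})

test_that("clinical labels normalise to the closed category set", {
  tsv <- paste("variant\tcategory", "K508R\tLike. benign",
               "ΔK508\tPathogenic", "R362C\tVUS", sep = "\n")
  tab <- load_label_table(tsv)
  expect_setequal(tab$category, c("likely_benign", "pathogenic", "VUS"))
  expect_error(load_label_table("variant\tcategory\nK508R\tmaybe"),
               "unknown clinical category")
})

test_that("classify_stability applies thresholds with inclusive boundary", {
  expect_equal(classify_stability(0.02), "neutral")
  expect_equal(classify_stability(5.0), "destabilized")
  expect_equal(classify_stability(3.0), "destabilized") # inclusive boundary
  expect_equal(classify_stability(2.999), "intermediate")
  expect_equal(classify_stability(0.999), "neutral")
  expect_equal(classify_stability(1.0), "intermediate")
  expect_error(classify_stability(1, neutral_max = 4, destabilized_min = 3),
               "neutral_max")
  # monotone non-decreasing in ddG
  x <- sort(runif(50, -2, 6))
  cls <- classify_stability(x)
  lev <- c(neutral = 1L, intermediate = 2L, destabilized = 3L)
  expect_true(all(diff(lev[cls]) >= 0))
})

test_that("build_fishtail outer-joins on the ddG side", {
  truth <- data.frame(variant = c("V400I", "ΔK508", "K508R"),
                      ddg_kcal = c(0.7, 5.0, 0.02))
  recs <- records_from_truth(
    data.frame(variant = truth$variant, ddg_kcal = truth$ddg_kcal))
  # no annotations at all
  bare <- build_fishtail(recs)
  expect_equal(nrow(bare), 3L)
  expect_true(all(is.na(bare$frequency)))
  expect_true(all(is.na(bare$category)))
  # partial annotation + unmatched reporting
  freq <- load_frequency_table(freq_tsv("V400I\t240\t200000\t1.2e-3"))
  labels <- load_label_table(
    "variant\tcategory\nV400I\tConflicting\nA999G\tBenign")
  fish <- build_fishtail(recs, freq, labels)
  expect_equal(nrow(fish), 3L)
  row <- fish[fish$variant == "V400I", ]
  expect_equal(row$frequency, 1.2e-3)
  expect_equal(row$category, "conflicting")
  expect_equal(row$stability_class, "neutral")
  expect_equal(fish$stability_class[fish$variant == "ΔK508"], "destabilized")
  expect_true("A999G" %in% attr(fish, "unmatched"))
  # sorted by position then variant
  expect_equal(fish$position, sort(fish$position))
  # duplicate annotations are an error naming the variant
  dupfreq <- load_frequency_table(freq_tsv(c("V400I\t2\t100\t0.02",
                                             "V400I\t3\t100\t0.03")))
  expect_error(build_fishtail(recs, dupfreq), "V400I")
})

test_that("heatmap matrices have exact shape and content", {
  h <- tiny_helix(5, "LKAIE")
  cfg <- protocol_config(n_models = 2L, n_traj = 1L, master_seed = 2L)
  scan <- saturation_scan(h, scorer_spec(), cfg)
  hm <- heatmap_matrix(scan$records, 1, 5)
  expect_equal(dim(hm$matrix), c(21L, 5L))
  expect_equal(rownames(hm$matrix)[1], "del")
  # identity cells exactly zero
  seqv <- structure_sequence(h)
  for (pos in 1:5)
    expect_identical(hm$matrix[unname(seqv[as.character(pos)]),
                               as.character(pos)], 0)
  # deletion cells equal the deletion records
  del_rec <- Filter(function(r) r$variant$kind == "deletion" &&
                      r$variant$position == 3L, scan$records)[[1]]
  expect_equal(hm$matrix["del", "3"], del_rec$ddg_kcal)
  # a 490-520 style window has 31 columns even when sparsely filled
  wide <- scan$records[[1]]
  wide$variant$position <- 500L
  hm2 <- heatmap_matrix(list(wide), 490, 520)
  expect_equal(ncol(hm2$matrix), 31L)
  expect_equal(sum(!is.na(hm2$matrix)), 1L)
  expect_error(heatmap_matrix(scan$records, 100, 120), "no ddG records")
  # TSV export round-trips shape
  f <- withr::local_tempfile()
  write_heatmap(hm, f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_equal(dim(back), c(21L, 6L))
})

test_that("motif scanning matches the published site patterns", {
  # TRAF-motif AARS at author position 236, via offset
  seqn <- paste0(strrep("G", 10), "AARS", strrep("G", 5))
  hits <- scan_usp7_motifs(seqn, offset = 225L)
  traf <- hits[hits$motif == "TRAF", ]
  expect_true(any(traf$start == 236L & traf$match == "AARS"))
  # UBL1/2 pattern catches the KVKVLFK site
  hits2 <- scan_usp7_motifs("AAKVKVLFKAA")
  expect_true(any(hits2$motif == "UBL12" & hits2$match == "KVKVLFK" &
                    hits2$start == 3L))
  expect_equal(nrow(scan_usp7_motifs("")), 0L)
  expect_error(scan_usp7_motifs("AAAA", c(bad = "[PA")), "unclosed")
  expect_error(scan_usp7_motifs("AAAA", c(bad = "P?S")), "invalid pattern")
})

test_that("motif scan agrees with a regex oracle on random sequences", {
  oracle_hits <- function(seqn, pattern) {
    rex <- gsub("x", ".", pattern, fixed = TRUE)
    m <- gregexpr(paste0("(?=", rex, ")"), seqn, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  set.seed(41)
  pats <- c(TRAF = "[PA]xxS", UBL12 = "KxKxxxK", W = "W")
  for (i in 1:100) {
    seqn <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                           "L", "M", "N", "P", "Q", "R", "S", "T", "V",
                           "W", "Y"), sample(10:60, 1), replace = TRUE),
                  collapse = "")
    got <- scan_usp7_motifs(seqn, pats)
    for (nm in names(pats)) {
      expect_equal(sort(got$start[got$motif == nm]),
                   sort(oracle_hits(seqn, pats[[nm]])),
                   info = paste(nm, seqn))
    }
  }
})
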