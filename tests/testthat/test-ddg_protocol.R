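test_that("protocol defaults are the published constants", {
  cfg <- protocol_config()
  expect_equal(cfg$n_iter_missense, 3L)
  expect_equal(cfg$n_models, 25L)
  expect_equal(cfg$n_traj, 2L)
  expect_equal(cfg$baseline_percentile, 10)
  expect_equal(cfg$kcal_divisor, 2.9)
  expect_error(protocol_config(baseline_percentile = 0), "percentile")
  expect_error(protocol_config(kcal_divisor = -1), "divisor")
})

test_that("median_score matches its definition and a brute-force oracle", {
  expect_equal(median_score(c(1, 2, 3, 4)), 2.5)
  expect_equal(median_score(5), 5)
  expect_error(median_score(numeric(0)), "empty")
  set.seed(21)
  for (i in 1:200) {
    x <- rnorm(sample.int(60, 1))
    expect_equal(median_score(x), stats::median(x))
  }
})

test_that("percentile_value follows the stated interpolation rules", {
  # linear interpolation on 1..100: rank h = 0.1*(100-1)+1 = 10.9
  expect_equal(percentile_value(1:100, 10), 10.9)
  # independent oracle: manual type-7 formula on random draws
  oracle <- function(x, p) {
    s <- sort(x); n <- length(s)
    h <- (n - 1) * p / 100 + 1
    lo <- floor(h)
    s[lo] + (h - lo) * (s[min(lo + 1, n)] - s[lo])
  }
  set.seed(33)
  for (i in 1:100) {
    x <- runif(sample(3:80, 1), -50, 50)
    p <- runif(1, 1, 99)
    expect_equal(percentile_value(x, p), oracle(x, p), tolerance = 1e-12)
  }
  expect_equal(percentile_value(1:100, 10, "lower"), 10)
  # "nearest": type-3 nearest-even rule at the boundary
  expect_equal(percentile_value(1:100, 10, "nearest"),
               unname(quantile(1:100, 0.1, type = 3)))
})

test_that("identity variants short-circuit to exactly zero", {
  h <- tiny_helix(5, "LKAIE")
  rec <- missense_ddg(h, parse_variant("K2K"), scorer_spec(), fast_cfg())
  expect_identical(rec$ddg_kcal, 0)
  expect_identical(rec$raw_stat, 0)
  expect_length(rec$raw_scores_wt, 3L)
})

test_that("missense ddG is the scaled mean difference with full provenance", {
  h <- tiny_helix(5, "LKAIE")
  cfg <- fast_cfg()
  rec <- missense_ddg(h, parse_variant("L1D"), scorer_spec(), cfg)
  expect_length(rec$raw_scores_wt, 3L)
  expect_length(rec$raw_scores_var, 3L)
  expect_equal(rec$raw_stat,
               mean(rec$raw_scores_var) - mean(rec$raw_scores_wt))
  expect_equal(rec$ddg_kcal * cfg$kcal_divisor, rec$raw_stat,
               tolerance = 1e-9)
  # the 5.8 / 2.9 = 2.0 scaling relation, checked through a stub
  stub <- queue_stub(c(rep(0, 3), rep(5.8, 3)))
  rec2 <- missense_ddg(h, parse_variant("L1D"), stub, fast_cfg())
  expect_equal(rec2$raw_stat, 5.8)
  expect_equal(rec2$ddg_kcal, 2.0)
})

test_that("deletion_raw_dg is the median of the injected ensemble scores", {
  h <- tiny_helix(6)
  cfg <- protocol_config(n_models = 2L, n_traj = 2L, master_seed = 1L)
  dg <- deletion_raw_dg(h, parse_variant("delA3"), queue_stub(c(1, 2, 3, 4)),
                        cfg)
  expect_equal(as.numeric(dg), 2.5)
  expect_equal(attr(dg, "scores"), c(1, 2, 3, 4))
  cfg1 <- protocol_config(n_models = 1L, n_traj = 1L, master_seed = 1L)
  expect_equal(as.numeric(deletion_raw_dg(h, parse_variant("delA3"),
                                          queue_stub(5), cfg1)), 5)
})

test_that("deletion_scan subtracts the right baseline from an injected dG grid", {
  h <- make_ideal_helix(20, strrep("A", 20))
  cfg <- protocol_config(n_models = 1L, n_traj = 1L, master_seed = 1L)
  # stub: every model's score is the deleted author position, so the dG
  # distribution is exactly 1..20
  scan <- deletion_scan(h, deleted_position_stub(20L), cfg)
  expect_equal(scan$dg_distribution, as.numeric(1:20))
  # oracle: type-7 10th percentile of 1..20 = 1 + 0.1*19 = 2.9
  expect_equal(scan$baseline, 2.9)
  dd <- vapply(scan$records, `[[`, numeric(1), "ddg_kcal")
  expect_equal(dd, (1:20 - 2.9) / 2.9, tolerance = 1e-12)
  # negative count bounded by the baseline percentile
  expect_lte(sum(dd < 0), ceiling(0.1 * 20))
})

test_that("degenerate deletion scans error", {
  h <- tiny_helix(5, "LKAIE")
  one <- slice_domain(h, "A", 2, 2)
  expect_error(deletion_scan(one, scorer_spec(), fast_cfg()),
               "at least 2 resolved")
  flat <- deletion_scan(make_ideal_helix(6, strrep("A", 6)),
                        queue_stub(7), fast_cfg())
  expect_equal(flat$baseline, 7)
  expect_true(all(vapply(flat$records, `[[`, numeric(1), "ddg_kcal") == 0))
})

test_that("strictly negative deletion ddGs never exceed the percentile mass", {
  set.seed(17)
  for (i in 1:50) {
    x <- rnorm(sample(5:60, 1), sd = 10)
    base <- percentile_value(x, 10)
    expect_lte(sum(x < base), ceiling(0.1 * length(x)))
  }
})

test_that("saturation_scan emits the full schema deterministically", {
  h <- tiny_helix(5, "LKAIE")
  cfg <- protocol_config(n_models = 2L, n_traj = 1L, master_seed = 8L)
  scan <- saturation_scan(h, scorer_spec(), cfg)
  tb <- scan$table
  expect_equal(nrow(tb), 5L * 21L)
  expect_equal(sum(tb$variant == "del"), 5L)
  expect_setequal(names(tb),
                  c("position", "wt_aa", "variant", "ddg_kcal",
                    "is_reference", "backend", "n_scores", "baseline",
                    "master_seed"))
  expect_true(all(tb$ddg_kcal[tb$is_reference] == 0))
  expect_equal(unique(tb$n_scores[tb$variant == "del"]), 2L)
  # byte-identical reruns
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_scan_tsv(scan, f1)
  write_scan_tsv(saturation_scan(h, scorer_spec(), cfg), f2)
  expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
  # scaling audit across every record
  for (r in scan$records) {
    b <- if (is.na(r$baseline)) 0 else r$baseline
    expect_equal(r$ddg_kcal * cfg$kcal_divisor, r$raw_stat - b,
                 tolerance = 1e-9)
  }
})

test_that("destabilising changes carry positive sign on the bundle", {
  b <- the_bundle()
  s <- b$structure
  seqv <- structure_sequence(s)
  cfg <- fast_cfg()
  buried <- b$classes$resno[b$classes$class == "buried"][1:2]
  for (pos in buried) {
    v <- new_variant("missense", pos, unname(seqv[as.character(pos)]), "D")
    expect_gt(missense_ddg(s, v, scorer_spec(), cfg)$ddg_kcal, 0)
  }
})
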