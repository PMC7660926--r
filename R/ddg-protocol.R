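## ddg_protocol: the aggregation protocols that turn raw scores into ddG.
##
## Missense: score variant and wild type n_iter times each (relax-then-
## score with derived seeds), ddG = (mean variant - mean wild type) /
## kcal_divisor. Sign convention: positive = destabilising.
##
## Deletion: build an ensemble of n_models gap-closed models, relax each in
## n_traj independent trajectories, take the median of all n_models x
## n_traj scores as the deletion's raw dG; across a whole domain subtract
## the baseline_percentile of the dG distribution and divide by
## kcal_divisor. The defaults (3 iterations; 25 models x 2 trajectories =
## 50 scores; 10th percentile; divisor 2.9) reproduce the published
## protocol exactly.

#' Protocol configuration
#'
#' Defaults are the published protocol constants; every output record
#' serialises the configuration it was produced under.
#'
#' @param n_iter_missense scoring iterations per amino-acid identity
#'   (default 3).
#' @param n_models deletion ensemble size (default 25).
#' @param n_traj relax trajectories per model (default 2).
#' @param baseline_percentile percentile of the deletion dG distribution
#'   subtracted as baseline, in (0, 100) (default 10).
#' @param kcal_divisor divisor bringing internal units to a kcal/mol scale
#'   (default 2.9; appropriate for the published external force field, a
#'   plain configuration constant for any other backend).
#' @param percentile_method `"linear_interpolation"` (default), `"lower"`
#'   or `"nearest"`.
#' @param master_seed integer seed all child seeds derive from.
#' @param closure_window deletion closure half-width in residues.
#' @param jitter_sigma_model per-model jitter, Angstrom.
#' @return an object of class `ddg_protocol_config`.
#' @export
protocol_config <- function(n_iter_missense = 3L, n_models = 25L,
                            n_traj = 2L, baseline_percentile = 10,
                            kcal_divisor = 2.9,
                            percentile_method = c("linear_interpolation",
                                                  "lower", "nearest"),
                            master_seed = 1L,
                            closure_window = 3L,
                            jitter_sigma_model = 0.3) {
  percentile_method <- match.arg(percentile_method)
  if (baseline_percentile <= 0 || baseline_percentile >= 100)
    stop("baseline_percentile must be in (0, 100)")
  if (kcal_divisor <= 0) stop("kcal_divisor must be > 0")
  structure(list(n_iter_missense = as.integer(n_iter_missense),
                 n_models = as.integer(n_models),
                 n_traj = as.integer(n_traj),
                 baseline_percentile = baseline_percentile,
                 kcal_divisor = kcal_divisor,
                 percentile_method = percentile_method,
                 master_seed = as.integer(master_seed),
                 closure_window = as.integer(closure_window),
                 jitter_sigma_model = jitter_sigma_model),
            class = "ddg_protocol_config")
}

#' Percentile of a numeric vector under a stated rule
#'
#' @param x numeric vector.
#' @param p percentile in (0, 100).
#' @param method `"linear_interpolation"` (the common type-7 rule),
#'   `"lower"` (type 1) or `"nearest"` (type 3).
#' @return a single numeric value.
#' @export
#' @examples
#' percentile_value(1:100, 10) # 10.9
percentile_value <- function(x, p,
                             method = c("linear_interpolation", "lower",
                                        "nearest")) {
  method <- match.arg(method)
  type <- switch(method, linear_interpolation = 7L, lower = 1L,
                 nearest = 3L)
  unname(stats::quantile(x, probs = p / 100, type = type, names = FALSE))
}

#' Median with the explicit even-count rule
#'
#' Sorts and returns the middle value, or the mean of the two middle
#' values for an even count.
#'
#' @param x numeric vector of scores.
#' @return a single numeric value.
#' @export
median_score <- function(x) {
  if (!length(x)) stop("median of an empty score list is undefined")
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

#' Template residue volumes for missense scoring
#' @noRd
template_volumes_of <- function(s) {
  rt <- residue_table(s)
  stats::setNames(unname(RESIDUE_VOLUME[rt$aa]),
                  paste0(rt$chain, ":", rt$resno))
}

#' One relax-then-score iteration total
#' @noRd
iteration_score <- function(s, spec, seed) {
  relax_structure(s, spec, seed = seed)$score$total
}

new_ddg_record <- function(variant, ddg_kcal, raw_stat, raw_scores_wt,
                           raw_scores_var, baseline, spec, cfg) {
  structure(list(variant = variant, ddg_kcal = ddg_kcal,
                 raw_stat = raw_stat, raw_scores_wt = raw_scores_wt,
                 raw_scores_var = raw_scores_var, baseline = baseline,
                 scorer = list(backend = spec$backend,
                               version_tag = spec$version_tag),
                 config = cfg),
            class = "ddg_record")
}

#' @export
print.ddg_record <- function(x, ...) {
  cat(sprintf("<ddg_record> %s: ddG = %.3f kcal/mol (%d score(s), %s)\n",
              format_variant(x$variant), x$ddg_kcal,
              length(x$raw_scores_var), x$scorer$backend))
  invisible(x)
}

#' Missense ddG for one variant
#'
#' Builds the substituted structure ([mutate_structure()]; Cbeta-stub side
#' chain on the built-in path), scores variant and wild type
#' `cfg$n_iter_missense` times each with seeds derived from the master
#' seed, and reports `(mean variant - mean wild type) / kcal_divisor`.
#' Identity variants (alt == wt, the wild-type reference) short-circuit to
#' exactly 0.
#'
#' @param s template `ddg_structure`.
#' @param v missense `ddg_variant`.
#' @param spec a `ddg_scorer_spec`.
#' @param cfg a `ddg_protocol_config`.
#' @param wt_scores optional precomputed wild-type iteration scores for
#'   this position (used by [saturation_scan()] to share them across the
#'   20 identities).
#' @return a `ddg_record`.
#' @export
missense_ddg <- function(s, v, spec = scorer_spec(),
                         cfg = protocol_config(), wt_scores = NULL) {
  stopifnot(inherits(v, "ddg_variant"), inherits(cfg, "ddg_protocol_config"))
  if (v$kind != "missense") stop("missense_ddg() takes missense variants")
  check_variant_against(v, s)
  spec_use <- spec
  if (spec$backend == "builtin" &&
      is.null(spec$params$template_volumes))
    spec_use$params$template_volumes <- template_volumes_of(s)
  n <- cfg$n_iter_missense
  if (is.null(wt_scores))
    wt_scores <- vapply(seq_len(n), function(i)
      iteration_score(s, spec_use,
                      derive_seed(cfg$master_seed, "wt", v$position, i)),
      numeric(1))
  if (identical(v$alt, v$wt)) {
    return(new_ddg_record(v, 0, 0, wt_scores, wt_scores, NA_real_,
                          spec, cfg))
  }
  label <- format_variant(v, "ascii")
  mut <- mutate_structure(s, v)
  var_scores <- vapply(seq_len(n), function(i)
    iteration_score(mut, spec_use, derive_seed(cfg$master_seed, label, i)),
    numeric(1))
  raw_stat <- mean(var_scores) - mean(wt_scores)
  new_ddg_record(v, raw_stat / cfg$kcal_divisor, raw_stat, wt_scores,
                 var_scores, NA_real_, spec, cfg)
}

#' Raw deletion dG for one variant
#'
#' Builds the gap-closed ensemble (`cfg$n_models` members), relaxes each in
#' `cfg$n_traj` independent trajectories, and returns the median of all
#' `n_models x n_traj` scores.
#'
#' @inheritParams missense_ddg
#' @param v deletion `ddg_variant`.
#' @return numeric median dG with attributes `scores` (the full vector in
#'   (model, trajectory) order) and `terminal`.
#' @export
deletion_raw_dg <- function(s, v, spec = scorer_spec(),
                            cfg = protocol_config()) {
  stopifnot(inherits(v, "ddg_variant"), inherits(cfg, "ddg_protocol_config"))
  if (v$kind != "deletion") stop("deletion_raw_dg() takes deletion variants")
  ens <- build_deletion_models(s, v, n_models = cfg$n_models,
                               seed = cfg$master_seed,
                               window = cfg$closure_window,
                               jitter_sigma = cfg$jitter_sigma_model)
  scores <- relax_ensemble(ens, spec, n_traj = cfg$n_traj,
                           seed = cfg$master_seed)
  structure(median_score(scores), scores = scores, terminal = ens$terminal)
}

#' Deletion scan of a whole domain
#'
#' Computes the raw deletion dG at every resolved position, subtracts the
#' configured percentile of that dG distribution as baseline, and scales
#' by the kcal divisor: `ddg_kcal = (dG - baseline) / kcal_divisor`.
#'
#' @inheritParams missense_ddg
#' @return an object of class `ddg_deletion_scan`: list with `records`
#'   (one `ddg_record` per position), `baseline` and `dg_distribution`.
#' @export
deletion_scan <- function(s, spec = scorer_spec(),
                          cfg = protocol_config()) {
  rt <- residue_table(s)
  res <- rt[rt$resolved, , drop = FALSE]
  if (nrow(res) < 2L)
    stop("deletion baseline undefined: need at least 2 resolved positions")
  raws <- lapply(seq_len(nrow(res)), function(i) {
    v <- new_variant("deletion", res$resno[i], res$aa[i])
    list(v = v, dg = deletion_raw_dg(s, v, spec, cfg))
  })
  dgs <- vapply(raws, function(r) as.numeric(r$dg), numeric(1))
  baseline <- percentile_value(dgs, cfg$baseline_percentile,
                               cfg$percentile_method)
  records <- lapply(raws, function(r) {
    raw <- as.numeric(r$dg)
    new_ddg_record(r$v, (raw - baseline) / cfg$kcal_divisor, raw,
                   numeric(0), attr(r$dg, "scores"), baseline, spec, cfg)
  })
  structure(list(records = records, baseline = baseline,
                 dg_distribution = dgs),
            class = "ddg_deletion_scan")
}

#' @export
print.ddg_deletion_scan <- function(x, ...) {
  cat(sprintf(
    "<ddg_deletion_scan> %d positions; baseline %.3f; ddG range %.2f..%.2f\n",
    length(x$records), x$baseline,
    min(vapply(x$records, `[[`, numeric(1), "ddg_kcal")),
    max(vapply(x$records, `[[`, numeric(1), "ddg_kcal"))))
  invisible(x)
}

#' Full saturation scan: every substitution and every deletion
#'
#' Runs [missense_ddg()] for all 20 amino-acid identities at every resolved
#' position (wild-type iteration scores shared within a position) and
#' [deletion_scan()] over the whole domain, and assembles the results in a
#' tidy table. Deterministic under a fixed `cfg$master_seed`.
#'
#' @inheritParams missense_ddg
#' @return an object of class `ddg_saturation_scan`: list with `table`
#'   (data.frame: `position`, `wt_aa`, `variant` (alt letter or `"del"`),
#'   `ddg_kcal`, `is_reference`, `backend`, `n_scores`, `baseline`,
#'   `master_seed`), `records` and `deletion_scan`.
#' @export
saturation_scan <- function(s, spec = scorer_spec(),
                            cfg = protocol_config()) {
  vs <- enumerate_saturation(s)
  spec_use <- spec
  if (spec$backend == "builtin" &&
      is.null(spec$params$template_volumes))
    spec_use$params$template_volumes <- template_volumes_of(s)
  positions <- unique(vs$position)
  wt_cache <- new.env(parent = emptyenv())
  wt_for <- function(pos) {
    key <- as.character(pos)
    if (!is.null(wt_cache[[key]])) return(wt_cache[[key]])
    sc <- vapply(seq_len(cfg$n_iter_missense), function(i)
      iteration_score(s, spec_use,
                      derive_seed(cfg$master_seed, "wt", pos, i)),
      numeric(1))
    wt_cache[[key]] <- sc
    sc
  }
  mis_rows <- vs[vs$kind == "missense", , drop = FALSE]
  mis_records <- lapply(seq_len(nrow(mis_rows)), function(i) {
    v <- variant_from_row(mis_rows[i, ])
    missense_ddg(s, v, spec, cfg, wt_scores = wt_for(v$position))
  })
  del <- deletion_scan(s, spec, cfg)
  del_by_pos <- stats::setNames(del$records,
                                vapply(del$records, function(r)
                                  as.character(r$variant$position),
                                  character(1)))
  records <- vector("list", nrow(vs))
  rows <- vector("list", nrow(vs))
  mi <- 0L
  for (i in seq_len(nrow(vs))) {
    if (vs$kind[i] == "missense") {
      mi <- mi + 1L
      rec <- mis_records[[mi]]
    } else {
      rec <- del_by_pos[[as.character(vs$position[i])]]
    }
    records[[i]] <- rec
    rows[[i]] <- data.frame(
      position = vs$position[i], wt_aa = vs$wt[i],
      variant = if (vs$kind[i] == "deletion") "del" else vs$alt[i],
      ddg_kcal = rec$ddg_kcal,
      is_reference = isTRUE(vs$is_reference[i]),
      backend = spec$backend,
      n_scores = length(rec$raw_scores_var),
      baseline = if (is.na(rec$baseline)) NA_real_ else rec$baseline,
      master_seed = cfg$master_seed,
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), records = records,
                 deletion_scan = del, config = cfg,
                 scorer = list(backend = spec$backend,
                               version_tag = spec$version_tag)),
            class = "ddg_saturation_scan")
}

#' @export
print.ddg_saturation_scan <- function(x, ...) {
  tb <- x$table
  cat(sprintf(
    "<ddg_saturation_scan> %d positions, %d records (%d deletions)\n",
    length(unique(tb$position)), nrow(tb), sum(tb$variant == "del")))
  invisible(x)
}

#' Write a saturation-scan table as TSV
#'
#' Byte-deterministic for a fixed scan (fixed EOLs, fixed numeric
#' formatting); the header embeds a hash of the serialized configuration.
#'
#' @param scan a `ddg_saturation_scan` (or bare data.frame in its schema).
#' @param path output file.
#' @return invisibly the path.
#' @export
write_scan_tsv <- function(scan, path) {
  tb <- if (inherits(scan, "ddg_saturation_scan")) scan$table else scan
  cfg_line <- if (inherits(scan, "ddg_saturation_scan"))
    sprintf("# config_hash=%s backend=%s",
            string_hash(paste(deparse(scan$config), collapse = "")),
            scan$scorer$backend) else "# config_hash=NA"
  write_tsv_det(tb, path, header_lines = cfg_line)
}
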