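## energy: the pluggable scoring layer.
##
## The aggregation protocol (iterated scoring, ensembles, medians,
## percentile baselines) is the scientific content of this package; the
## all-atom force field it was published with is an external tool that is
## deliberately NOT re-implemented. Two backends satisfy the same contract:
##   * "builtin"  - a deterministic coarse-grained potential (clash +
##                  burial mismatch + backbone strain + volume mismatch)
##                  good enough to give the protocol realistic signal at
##                  desk scale. Its numbers are NOT comparable to published
##                  all-atom values.
##   * "external" - an adapter that writes a PDB, invokes a configured
##                  relax/score command and parses its score table.
## A third backend, "stub", lets tests inject score sequences.

#' Default constants of the built-in coarse-grained scorer
#' @noRd
builtin_defaults <- function() {
  list(
    r_clash = 2.8,            # A; non-bonded heavy-atom clash threshold
    k_clash = 10,             # clash spring constant, units A^-2
    contact_cutoff = 7.0,     # A; Cbeta-Cbeta contact radius
    c_sat = 8,                # contact count treated as fully buried
    ideal_ca_dist = 3.8,      # A; trans-peptide Calpha virtual bond
    ideal_ca_angle = 91 * pi / 180, # rad; alpha-helical Calpha virtual angle
    k_len = 1, k_ang = 1,     # backbone-strain weights
    k_vol = 0.001,            # volume-mismatch weight (A^3)^-2
    burial_exposure_max = 0.25, # exposure below which a site counts buried
    w_clash = 1, w_burial = 1, w_strain = 1, w_volume = 1,
    jitter_sigma = 0.08,      # A; relax perturbation
    step_sigma = 0.15,        # A; relax proposal step
    max_steps = 60,           # relax proposal budget
    tol = 1e-4)               # relax relative-improvement stop
}

#' Construct a scorer specification
#'
#' @param backend `"builtin"` (default), `"external"` (adapter around a
#'   configured command-line tool) or `"stub"` (tests; `params$fn(structure,
#'   seed)` supplies totals).
#' @param params named list overriding backend constants; see the package
#'   vignette for the built-in scorer's terms and defaults. For the external
#'   backend supply at least `command` (a template containing `{input}`) and
#'   optionally `nstruct`.
#' @param version_tag string recorded in every result for provenance.
#' @return an object of class `ddg_scorer_spec`.
#' @export
scorer_spec <- function(backend = c("builtin", "external", "stub"),
                        params = list(), version_tag = NULL) {
  backend <- match.arg(backend)
  if (backend == "builtin") {
    p <- builtin_defaults()
    unknown <- setdiff(names(params), c(names(p), "template_volumes",
                                        "mobile_atoms"))
    if (length(unknown))
      stop("unknown builtin scorer parameter(s): ",
           paste(unknown, collapse = ", "))
    p[names(params)] <- params
  } else if (backend == "stub") {
    if (!is.function(params$fn))
      stop("stub backend requires params$fn(structure, seed)")
    p <- params
  } else {
    p <- params
  }
  structure(list(backend = backend, params = p,
                 version_tag = version_tag %||%
                   paste0(backend, "-scorer-0.1.0")),
            class = "ddg_scorer_spec")
}

## ---- built-in scorer internals ------------------------------------------

#' Precompute everything the inner scoring loop needs
#' @noRd
build_score_ctx <- function(s, spec) {
  stopifnot(inherits(s, "ddg_structure"))
  a <- s$atoms
  rt <- residue_table(s)
  res_ok <- rt$resolved
  if (!all(res_ok))
    stop("unresolved backbone: ",
         paste(rt$resno[!res_ok], collapse = ", "))
  rkey <- paste(rt$chain, rt$resno, rt$icode, sep = "\r")
  akey <- paste(a$chain, a$resno, a$icode, sep = "\r")
  ord <- match(akey, rkey)          # residue ordinal of each atom
  coords <- cbind(a$x, a$y, a$z)
  n <- nrow(a)
  ## clash pairs: sequence separation >= 2 residues (or different chains)
  ii <- rep(seq_len(n), times = n - seq_len(n))
  jj <- sequence(n - seq_len(n), from = seq_len(n) + 1L)
  sep_ok <- a$chain[ii] != a$chain[jj] | abs(ord[ii] - ord[jj]) >= 2L
  ii <- ii[sep_ok]; jj <- jj[sep_ok]
  ## side-chain reference atom per residue: CB, falling back to CA (Gly)
  cb_idx <- integer(nrow(rt))
  for (r in seq_len(nrow(rt))) {
    at <- which(ord == r)
    hit <- at[a$atom[at] == "CB"]
    if (!length(hit)) hit <- at[a$atom[at] == "CA"]
    cb_idx[r] <- hit[1]
  }
  ca_idx <- vapply(seq_len(nrow(rt)), function(r) {
    at <- which(ord == r); at[a$atom[at] == "CA"][1]
  }, integer(1))
  nr <- nrow(rt)
  ci <- rep(seq_len(nr), times = nr - seq_len(nr))
  cj <- sequence(nr - seq_len(nr), from = seq_len(nr) + 1L)
  csep <- rt$chain[ci] != rt$chain[cj] | abs(ci - cj) >= 2L
  ci <- ci[csep]; cj <- cj[csep]
  kd <- KYTE_DOOLITTLE[rt$aa]
  tvol <- spec$params$template_volumes
  vol_ref <- if (is.null(tvol)) unname(RESIDUE_VOLUME[rt$aa]) else {
    key <- paste0(rt$chain, ":", rt$resno)
    ifelse(key %in% names(tvol), unname(tvol[key]),
           unname(RESIDUE_VOLUME[rt$aa]))
  }
  chain_runs <- split(seq_len(nr), factor(rt$chain, levels = unique(rt$chain)))
  list(coords = coords, ii = ii, jj = jj,
       cb_idx = cb_idx, ca_idx = ca_idx, ci = ci, cj = cj,
       aa = rt$aa, kd = unname(kd),
       expected_exposure = unname((4.5 - kd) / 9),
       vol = unname(RESIDUE_VOLUME[rt$aa]), vol_ref = vol_ref,
       chain_runs = chain_runs, params = spec$params)
}

#' Score a coordinate matrix against a prebuilt context
#' @noRd
score_coords <- function(coords, ctx) {
  p <- ctx$params
  ## clash
  d2 <- (coords[ctx$ii, 1] - coords[ctx$jj, 1])^2 +
    (coords[ctx$ii, 2] - coords[ctx$jj, 2])^2 +
    (coords[ctx$ii, 3] - coords[ctx$jj, 3])^2
  close <- d2 < p$r_clash^2
  clash <- if (any(close))
    p$k_clash * sum((p$r_clash - sqrt(d2[close]))^2) else 0
  ## Cbeta contact counts -> exposure
  cb <- coords[ctx$cb_idx, , drop = FALSE]
  cd2 <- (cb[ctx$ci, 1] - cb[ctx$cj, 1])^2 +
    (cb[ctx$ci, 2] - cb[ctx$cj, 2])^2 +
    (cb[ctx$ci, 3] - cb[ctx$cj, 3])^2
  touch <- cd2 < p$contact_cutoff^2
  contacts <- tabulate(c(ctx$ci[touch], ctx$cj[touch]), nbins = length(ctx$aa))
  exposure <- pmax(0, 1 - contacts / p$c_sat)
  burial <- sum(ctx$kd * (exposure - ctx$expected_exposure))
  ## backbone strain over consecutive Calpha virtual bonds and angles
  strain <- 0
  for (run in ctx$chain_runs) {
    if (length(run) < 2) next
    ca <- coords[ctx$ca_idx[run], , drop = FALSE]
    dv <- diff(ca)
    dl <- sqrt(rowSums(dv^2))
    strain <- strain + p$k_len * sum((dl - p$ideal_ca_dist)^2)
    if (length(run) >= 3) {
      m <- nrow(dv)
      cosang <- -rowSums(dv[-m, , drop = FALSE] * dv[-1, , drop = FALSE]) /
        (dl[-m] * dl[-1])
      ang <- acos(pmin(1, pmax(-1, cosang)))
      strain <- strain + p$k_ang * sum((ang - p$ideal_ca_angle)^2)
    }
  }
  ## volume mismatch at buried sites
  buried <- exposure < p$burial_exposure_max
  volmis <- if (any(buried))
    p$k_vol * sum((ctx$vol[buried] - ctx$vol_ref[buried])^2) else 0
  terms <- c(clash = p$w_clash * clash,
             burial_mismatch = p$w_burial * burial,
             backbone_strain = p$w_strain * strain,
             volume_mismatch = p$w_volume * volmis)
  c(total = sum(terms), terms)
}

#' Score a structure
#'
#' Deterministic given `(s, spec)`. The built-in breakdown satisfies
#' `total == clash + burial_mismatch + backbone_strain + volume_mismatch`.
#' Scores are in internal units (lower is more favourable) and are only
#' meaningful as differences; see the vignette.
#'
#' @param s a validated `ddg_structure` with all residues resolved.
#' @param spec a `ddg_scorer_spec` (builtin backend).
#' @return an object of class `ddg_score`: named list with `total`,
#'   `clash`, `burial_mismatch`, `backbone_strain`, `volume_mismatch`.
#' @export
#' @examples
#' s <- make_ideal_helix(12, strrep("A", 12))
#' score_structure(s, scorer_spec())
score_structure <- function(s, spec = scorer_spec()) {
  stopifnot(inherits(spec, "ddg_scorer_spec"))
  if (spec$backend != "builtin")
    stop("score_structure() computes the built-in potential; use ",
         "external_adapter() for the external backend")
  ctx <- build_score_ctx(s, spec)
  v <- score_coords(ctx$coords, ctx)
  structure(as.list(v), class = "ddg_score")
}

#' @export
print.ddg_score <- function(x, ...) {
  cat(sprintf(
    "<ddg_score> total %.4f (clash %.4f, burial %.4f, strain %.4f, volume %.4f)\n",
    x$total, x$clash, x$burial_mismatch, x$backbone_strain,
    x$volume_mismatch))
  invisible(x)
}

#' Relax a structure by seeded perturbation plus greedy descent
#'
#' One relax trajectory: Gaussian jitter (sd `jitter_sigma`) on the mobile
#' atoms, then up to `max_steps` single-atom proposals accepted only when
#' the total score decreases, stopping early once the relative improvement
#' falls below `tol`. The same seed always yields the same trajectory, and
#' the returned score never exceeds the input structure's score (if the
#' perturbed trajectory fails to descend below the input, the input is
#' returned unchanged).
#'
#' @param s a validated `ddg_structure`.
#' @param spec builtin `ddg_scorer_spec`; `params$mobile_atoms` (integer
#'   atom indices) restricts the move set, default all atoms.
#' @param seed integer trajectory seed.
#' @return list with `structure` (relaxed), `score` (a `ddg_score`) and
#'   `initial` (the input structure's `ddg_score`).
#' @export
relax_structure <- function(s, spec = scorer_spec(), seed = 1L) {
  stopifnot(inherits(spec, "ddg_scorer_spec"))
  if (spec$backend == "stub") {
    tot <- spec$params$fn(s, seed)
    sc <- structure(list(total = tot, clash = 0, burial_mismatch = tot,
                         backbone_strain = 0, volume_mismatch = 0),
                    class = "ddg_score")
    return(list(structure = s, score = sc, initial = sc))
  }
  if (spec$backend != "builtin")
    stop("relax_structure() supports the builtin (or stub) backend only")
  ctx <- build_score_ctx(s, spec)
  p <- ctx$params
  mobile <- p$mobile_atoms %||% seq_len(nrow(ctx$coords))
  v0 <- score_coords(ctx$coords, ctx)
  coords <- ctx$coords
  with_seed(seed, {
    coords[mobile, ] <- coords[mobile, ] +
      matrix(stats::rnorm(length(mobile) * 3, sd = p$jitter_sigma),
             ncol = 3)
    cur <- score_coords(coords, ctx)
    check_at <- 20L
    last_check <- cur[["total"]]
    for (step in seq_len(p$max_steps)) {
      i <- mobile[sample.int(length(mobile), 1L)]
      prop <- coords
      prop[i, ] <- prop[i, ] + stats::rnorm(3, sd = p$step_sigma)
      cand <- score_coords(prop, ctx)
      if (!is.finite(cand[["total"]]))
        stop("non-finite score during relax descent")
      if (cand[["total"]] < cur[["total"]]) {
        coords <- prop
        cur <- cand
      }
      if (step %% check_at == 0L) {
        rel <- (last_check - cur[["total"]]) /
          max(1, abs(last_check))
        if (rel < p$tol) break
        last_check <- cur[["total"]]
      }
    }
  })
  if (cur[["total"]] > v0[["total"]]) {
    ## perturbation failed to find anything at least as good: fixed point
    return(list(structure = s,
                score = structure(as.list(v0), class = "ddg_score"),
                initial = structure(as.list(v0), class = "ddg_score")))
  }
  out <- s
  out$atoms$x <- coords[, 1]; out$atoms$y <- coords[, 2]
  out$atoms$z <- coords[, 3]
  list(structure = out,
       score = structure(as.list(cur), class = "ddg_score"),
       initial = structure(as.list(v0), class = "ddg_score"))
}

## ---- external backend ----------------------------------------------------

#' Parse a whitespace-delimited score table from an external tool
#'
#' Understands the common `SCORE:` line format: a header line containing
#' `total_score` followed by one line per output model.
#'
#' @param text score-file content (string or lines).
#' @return numeric vector of totals, named by the description column when
#'   present.
#' @export
parse_score_table <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  sc <- grep("^SCORE:", lines, value = TRUE)
  if (!length(sc)) sc <- lines[nzchar(trimws(lines))]
  toks <- lapply(sc, function(l) strsplit(trimws(sub("^SCORE:", "", l)),
                                          "[[:space:]]+")[[1]])
  hdr_i <- which(vapply(toks, function(t) "total_score" %in% t, logical(1)))
  if (!length(hdr_i))
    stop("unparsable score table: no 'total_score' header found")
  hdr <- toks[[hdr_i[1]]]
  col <- match("total_score", hdr)
  desc_col <- match("description", hdr)
  rows <- toks[-seq_len(hdr_i[1])]
  rows <- rows[vapply(rows, length, integer(1)) >= col]
  vals <- vapply(rows, function(t) suppressWarnings(as.numeric(t[col])),
                 numeric(1))
  if (anyNA(vals)) stop("unparsable score table: non-numeric total_score")
  if (!is.na(desc_col))
    names(vals) <- vapply(rows, function(t) t[min(desc_col, length(t))],
                          character(1))
  vals
}

#' Invoke an external all-atom relax/score tool
#'
#' Adapter contract around the published protocol's command line. The
#' command template in `spec$params$command` is filled with the written PDB
#' path (`{input}`), the requested number of output structures
#' (`{nstruct}`) and a score-file path (`{scorefile}`), run, and its score
#' table parsed into totals. There is never a silent fallback to the
#' built-in scorer: an unconfigured or missing binary is an error.
#'
#' @param s a `ddg_structure` written as the tool input.
#' @param spec `ddg_scorer_spec` with backend `"external"`.
#' @param mode `"relax"` (ensemble relax, `nstruct` outputs) or
#'   `"mutate_score"` (site-saturation protocol of the external tool).
#' @param workdir scratch directory for tool input/output.
#' @return list of `ddg_score` objects with only `total` populated.
#' @export
external_adapter <- function(s, spec, mode = c("relax", "mutate_score"),
                             workdir = tempfile("ddgscan-ext-")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "ddg_scorer_spec"))
  if (spec$backend != "external")
    stop("external_adapter() requires an external-backend scorer spec")
  cmd_template <- spec$params$command
  if (is.null(cmd_template) || !nzchar(cmd_template))
    stop("external scorer unavailable: no command configured ",
         "(set params$command in the scorer spec)")
  exe <- strsplit(trimws(cmd_template), "[[:space:]]+")[[1]][1]
  if (!nzchar(Sys.which(exe)) && !file.exists(exe))
    stop("external scorer unavailable: binary '", exe, "' not found")
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  input <- file.path(workdir, "input.pdb")
  scorefile <- file.path(workdir, "score.sc")
  write_pdb(s, input)
  nstruct <- spec$params$nstruct %||% 2L
  fills <- c(input = input, nstruct = as.character(nstruct),
             scorefile = scorefile, mode = mode)
  cmd <- cmd_template
  for (k in names(fills))
    cmd <- gsub(paste0("{", k, "}"), fills[[k]], cmd, fixed = TRUE)
  out <- suppressWarnings(system(paste(cmd, "2>&1"), intern = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L)
    stop("external scorer failed (exit ", status, "): ",
         paste(utils::tail(out, 5), collapse = " | "))
  table_text <- if (file.exists(scorefile))
    readLines(scorefile, warn = FALSE) else out
  totals <- parse_score_table(table_text)
  lapply(unname(totals), function(t)
    structure(list(total = t, clash = NA_real_,
                   burial_mismatch = NA_real_, backbone_strain = NA_real_,
                   volume_mismatch = NA_real_), class = "ddg_score"))
}
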