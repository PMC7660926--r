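## deletion_modeling: ensembles of gap-closed backbone models for
## single-residue deletions.
##
## Deleting residue i leaves a backbone gap between i-1 and i+1. The gap is
## closed by shifted-sequence threading: residues within a window of w on
## each side are translated toward the vacated template slot with a taper
## (full shift fraction at the gap, 1/w of it at the window edge), the
## shift fraction chosen adaptively so the new junction Calpha-Calpha
## distance lands near the ideal 3.8 A whatever the local geometry (helix
## gaps are ~5.5 A, extended gaps ~7.6 A). Each ensemble member then gets
## an independent seeded Gaussian jitter on the window atoms, giving the
## median aggregation downstream something to aggregate over. Author
## numbering is preserved with the deleted position vacated.

#' Substitute a residue identity in place (Cbeta-stub side chain)
#'
#' Builds the missense-variant structure for the built-in scoring path:
#' the residue's identity changes, side-chain atoms beyond Cbeta are
#' dropped, and a Cbeta stub is added or removed as needed (glycine has
#' none).
#'
#' @param s a `ddg_structure`.
#' @param v a missense `ddg_variant` whose `wt` matches the structure.
#' @return the mutated `ddg_structure`; the input is never modified.
#' @export
mutate_structure <- function(s, v) {
  stopifnot(inherits(v, "ddg_variant"))
  if (v$kind != "missense") stop("mutate_structure() takes missense variants")
  check_variant_against(v, s)
  a <- s$atoms
  sel <- a$resno == v$position
  keep_atoms <- c("N", "CA", "C", "O", if (v$alt != "G") "CB")
  drop <- sel & !(a$atom %in% keep_atoms)
  a <- a[!drop, , drop = FALSE]
  sel <- a$resno == v$position
  a$aa[sel] <- v$alt
  if (v$alt != "G" && !any(a$atom[sel] == "CB")) {
    get <- function(nm) as.numeric(a[sel & a$atom == nm, c("x", "y", "z")])
    cb <- place_atom(get("C"), get("N"), get("CA"), BB$cb, BB$ang_n_ca_cb,
                     BB$tor_c_n_ca_cb)
    row <- a[sel & a$atom == "CA", , drop = FALSE]
    row$atom <- "CB"; row$element <- "C"
    row$x <- cb[1]; row$y <- cb[2]; row$z <- cb[3]
    a <- rbind(a, row)
    ## keep residue atoms contiguous and in file order
    a <- a[order(match(paste(a$chain, a$resno, a$icode),
                       unique(paste(a$chain, a$resno, a$icode)))), ,
           drop = FALSE]
  }
  out <- new_structure(a, source_id = paste0(s$source_id, "+",
                                             format_variant(v, "ascii")),
                       flagged = s$flagged,
                       missing_positions = s$missing_positions)
  validate_structure(out)
}

#' Build an ensemble of single-residue-deletion models
#'
#' @param s template `ddg_structure` (never modified).
#' @param v a deletion `ddg_variant`; its position must be resolved in `s`.
#' @param n_models ensemble size (protocol default 25).
#' @param seed master seed; per-model seeds are derived stably from
#'   `(seed, variant label, model index)`.
#' @param window closure half-width w in residues (default 3).
#' @param jitter_sigma per-model Gaussian jitter on window atoms, Angstrom
#'   (default 0.3).
#' @param max_retries re-jitter attempts per model when closure geometry
#'   validation fails.
#' @return an object of class `ddg_model_ensemble`: list with `variant`,
#'   `models` (each `n_residues(s) - 1` residues), `template_id`, `seed`,
#'   `terminal` (logical), `retries` (total re-jitter count).
#' @export
#' @examples
#' helix <- make_ideal_helix(21, strrep("A", 21))
#' ens <- build_deletion_models(helix, parse_variant("delA11"), n_models = 3)
#' length(ens$models)
build_deletion_models <- function(s, v, n_models = 25L, seed = 1L,
                                  window = 3L, jitter_sigma = 0.3,
                                  max_retries = 8L) {
  stopifnot(inherits(v, "ddg_variant"))
  if (v$kind != "deletion")
    stop("build_deletion_models() takes deletion variants")
  check_variant_against(v, s)
  rt <- residue_table(s)
  ord <- which(rt$resno == v$position)[1]
  chain <- rt$chain[ord]
  in_chain <- which(rt$chain == chain)
  terminal <- ord == min(in_chain) || ord == max(in_chain)
  label <- format_variant(v, "ascii")
  akey <- paste(s$atoms$chain, s$atoms$resno, s$atoms$icode, sep = "\r")
  rkey <- paste(rt$chain, rt$resno, rt$icode, sep = "\r")
  atom_ord <- match(akey, rkey)
  base <- s$atoms[atom_ord != ord, , drop = FALSE]
  base_ord <- atom_ord[atom_ord != ord]
  ca_of <- function(o) {
    at <- s$atoms[atom_ord == o & s$atoms$atom == "CA", c("x", "y", "z")]
    as.numeric(at[1, ])
  }
  w <- as.integer(window)
  window_ords <- integer()
  base_ca <- NULL
  if (!terminal) {
    window_ords <- intersect(c(ord - seq_len(w), ord + seq_len(w)), in_chain)
    gap <- vnorm(ca_of(ord + 1L) - ca_of(ord - 1L))
    a_base <- min(0.8, max(0.05, 1 - 3.8 / gap))
    ## chain-ordered Calphas over the closure region, anchors first/last
    region <- sort(intersect(seq.int(ord - w - 1L, ord + w + 1L), in_chain))
    region <- setdiff(region, ord)
    anchors <- setdiff(region, window_ords)
    ca0 <- t(vapply(region, ca_of, numeric(3)))
    ## taper shift toward the vacated slot: full fraction at the gap,
    ## 1/w of it at the window edge
    for (r in seq_along(region)) {
      o <- region[r]
      if (!(o %in% window_ords)) next
      k <- abs(o - ord)
      a_k <- a_base * (w + 1L - k) / w
      toward <- if (o < ord) ca_of(o + 1L) - ca_of(o) else
        ca_of(o - 1L) - ca_of(o)
      ca0[r, ] <- ca0[r, ] + a_k * toward
    }
    movable <- region %in% window_ords
    ## iterative bond projection: pull consecutive Calpha virtual bonds
    ## into [3.3, 4.15] A, anchors fixed
    project_bonds <- function(ca, iters = 40L, lo = 3.3, hi = 4.15) {
      for (it in seq_len(iters)) {
        ok <- TRUE
        for (b in seq_len(nrow(ca) - 1L)) {
          dvec <- ca[b + 1L, ] - ca[b, ]
          d <- vnorm(dvec)
          tgt <- if (d > hi) hi else if (d < lo) lo else next
          ok <- FALSE
          corr <- dvec / d * (d - tgt)
          if (movable[b] && movable[b + 1L]) {
            ca[b, ] <- ca[b, ] + corr / 2
            ca[b + 1L, ] <- ca[b + 1L, ] - corr / 2
          } else if (movable[b]) {
            ca[b, ] <- ca[b, ] + corr
          } else if (movable[b + 1L]) {
            ca[b + 1L, ] <- ca[b + 1L, ] - corr
          }
        }
        if (ok) break
      }
      ca
    }
    base_ca <- project_bonds(ca0)
    rownames(base_ca) <- as.character(region)
  }
  closure_ords <- sort(unique(c(window_ords,
                                intersect(c(ord - w - 1L, ord + w + 1L),
                                          in_chain))))
  validate_closure <- function(atoms, ords) {
    keep <- closure_ords
    ca <- do.call(rbind, lapply(keep, function(o) {
      at <- atoms[ords == o & atoms$atom == "CA", c("x", "y", "z")]
      as.numeric(at[1, ])
    }))
    if (is.null(ca) || nrow(ca) < 2) return(TRUE)
    d <- sqrt(rowSums((ca[-1, , drop = FALSE] -
                         ca[-nrow(ca), , drop = FALSE])^2))
    all(d >= 2.8 & d <= 4.3)
  }
  make_model <- function(m) {
    atoms <- base
    if (!terminal) {
      ## side chains in the window reduce to Cbeta stubs
      in_win <- base_ord %in% window_ords
      drop <- in_win & !(atoms$atom %in% c("N", "CA", "C", "O", "CB"))
      atoms <- atoms[!drop, , drop = FALSE]
      kept_ord <- base_ord[!drop]
      retries_here <- 0L
      repeat {
        ## rigid per-residue jitter on the window Calphas, re-projected so
        ## the virtual bonds stay in band, plus light per-atom jitter
        jittered <- atoms
        with_seed(derive_seed(seed, label, m, "build", retries_here), {
          ca_j <- base_ca
          for (r in seq_along(region)) {
            if (movable[r])
              ca_j[r, ] <- ca_j[r, ] + stats::rnorm(3, sd = jitter_sigma)
          }
          ca_j <- project_bonds(ca_j)
          for (o in window_ords) {
            delta <- ca_j[as.character(o), ] - ca_of(o)
            rows <- kept_ord == o
            jittered$x[rows] <- atoms$x[rows] + delta[1]
            jittered$y[rows] <- atoms$y[rows] + delta[2]
            jittered$z[rows] <- atoms$z[rows] + delta[3]
          }
          win_rows <- which(kept_ord %in% window_ords)
          atom_jit <- matrix(stats::rnorm(length(win_rows) * 3,
                                          sd = jitter_sigma / 3), ncol = 3)
          jittered$x[win_rows] <- jittered$x[win_rows] + atom_jit[, 1]
          jittered$y[win_rows] <- jittered$y[win_rows] + atom_jit[, 2]
          jittered$z[win_rows] <- jittered$z[win_rows] + atom_jit[, 3]
        })
        if (validate_closure(jittered, kept_ord)) {
          attr(jittered, "retries") <- retries_here
          return(jittered)
        }
        retries_here <- retries_here + 1L
        if (retries_here > max_retries)
          stop("closure failed geometry validation at position ",
               v$position, " after ", max_retries, " retries")
      }
    }
    attr(atoms, "retries") <- 0L
    atoms
  }
  models <- vector("list", n_models)
  retries <- 0L
  for (m in seq_len(n_models)) {
    atoms <- make_model(m)
    retries <- retries + attr(atoms, "retries")
    attr(atoms, "retries") <- NULL
    st <- validate_structure(new_structure(
      atoms, source_id = sprintf("%s-%s-m%02d", s$source_id, label, m)))
    models[[m]] <- st
  }
  structure(list(variant = v, models = models, template_id = s$source_id,
                 seed = as.integer(seed), terminal = terminal,
                 retries = retries, window = w,
                 window_positions = rt$resno[window_ords]),
            class = "ddg_model_ensemble")
}

#' @export
print.ddg_model_ensemble <- function(x, ...) {
  cat(sprintf("<ddg_model_ensemble> %s: %d models from template '%s'%s\n",
              format_variant(x$variant), length(x$models), x$template_id,
              if (x$terminal) " (terminal; trimmed, no closure)" else ""))
  invisible(x)
}

#' Relax every ensemble member in independent trajectories
#'
#' Runs [relax_structure()] `n_traj` times per model with distinct seeds
#' derived from `(seed, variant label, model index, trajectory index)` and
#' returns all `n_models x n_traj` totals in (model, trajectory) order.
#'
#' @param e a `ddg_model_ensemble`.
#' @param spec a `ddg_scorer_spec`.
#' @param n_traj trajectories per model (protocol default 2).
#' @param seed master seed for trajectory-seed derivation.
#' @return numeric vector of length `length(e$models) * n_traj`.
#' @export
relax_ensemble <- function(e, spec = scorer_spec(), n_traj = 2L, seed = 1L) {
  stopifnot(inherits(e, "ddg_model_ensemble"))
  if (n_traj < 1L) stop("n_traj must be >= 1")
  label <- format_variant(e$variant, "ascii")
  out <- numeric(0)
  for (m in seq_along(e$models)) {
    for (t in seq_len(n_traj)) {
      r <- relax_structure(e$models[[m]], spec,
                           seed = derive_seed(seed, label, m, t))
      out <- c(out, r$score$total)
    }
  }
  out
}

#' Export an ensemble as PDB files plus a manifest TSV
#'
#' @param e a `ddg_model_ensemble`.
#' @param dir output directory (created if needed).
#' @return invisibly the manifest data.frame (variant, model, seed, file,
#'   status).
#' @export
export_ensemble <- function(e, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  label <- format_variant(e$variant, "ascii")
  rows <- lapply(seq_along(e$models), function(m) {
    f <- file.path(dir, sprintf("%s_model%02d.pdb", label, m))
    write_pdb(e$models[[m]], f)
    data.frame(variant = label, model = m,
               seed = derive_seed(e$seed, label, m, "build", 0L),
               file = basename(f),
               status = if (e$terminal) "terminal-trimmed" else "closed",
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
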