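## synthetic_data: desk-scale stand-ins with known ground truth.
##
## Structures are built from ideal internal coordinates (NeRF chain
## extension), so every geometric property is known by construction:
## alpha-helical segments have Calpha-Calpha ~3.8 A and ~1.5 A rise, and
## burial labels on the two-helix bundle are geometric (which way the
## Cbeta points), independent of any scorer.

deg <- function(x) x * pi / 180

vcross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

vnorm <- function(a) sqrt(sum(a^2))

#' Natural-extension-reference-frame atom placement
#' @noRd
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- c - b; bc <- bc / vnorm(bc)
  n <- vcross(b - a, bc); n <- n / vnorm(n)
  m <- cbind(bc, vcross(n, bc), n)
  d <- c(-bond * cos(angle), bond * sin(angle) * cos(torsion),
         bond * sin(angle) * sin(torsion))
  as.vector(c + m %*% d)
}

## canonical backbone internal coordinates (A / degrees)
BB <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
           cb = 1.521,
           ang_n_ca_c = deg(111.2), ang_ca_c_n = deg(116.2),
           ang_c_n_ca = deg(121.7), ang_ca_c_o = deg(120.5),
           ang_n_ca_cb = deg(110.4), tor_c_n_ca_cb = deg(-122.6))

#' Build a peptide backbone from phi/psi angles
#'
#' @param phi,psi numeric vectors (radians), one per residue; `phi[1]` and
#'   `psi[n]` are used only to place the terminal O/CB frames.
#' @return list of per-residue named coordinate lists (N, CA, C, O, CB).
#' @noRd
build_backbone <- function(phi, psi) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2)
  res <- vector("list", n)
  N <- c(0, 0, 0)
  CA <- c(BB$n_ca, 0, 0)
  C <- place_atom(c(0, 1, 0), N, CA, BB$ca_c, BB$ang_n_ca_c, phi[1])
  res[[1]] <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n - 1)) {
    Nn <- place_atom(res[[i]]$N, res[[i]]$CA, res[[i]]$C,
                     BB$c_n, BB$ang_ca_c_n, psi[i])
    CAn <- place_atom(res[[i]]$CA, res[[i]]$C, Nn,
                      BB$n_ca, BB$ang_c_n_ca, pi) # omega = 180
    Cn <- place_atom(res[[i]]$C, Nn, CAn,
                     BB$ca_c, BB$ang_n_ca_c, phi[i + 1])
    res[[i + 1]] <- list(N = Nn, CA = CAn, C = Cn)
  }
  for (i in seq_len(n)) {
    r <- res[[i]]
    res[[i]]$O <- place_atom(r$N, r$CA, r$C, BB$c_o, BB$ang_ca_c_o,
                             psi[i] + pi)
    res[[i]]$CB <- place_atom(r$C, r$N, r$CA, BB$cb, BB$ang_n_ca_cb,
                              BB$tor_c_n_ca_cb)
  }
  res
}

residues_to_structure <- function(res_list, sequence, chain = "A",
                                  start_resno = 1L, source_id) {
  rows <- list()
  for (i in seq_along(res_list)) {
    aa <- substr(sequence, i, i)
    atoms <- res_list[[i]]
    if (aa == "G") atoms$CB <- NULL
    for (nm in names(atoms)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resno = start_resno + i - 1L, icode = "",
        aa = aa, atom = nm, element = substr(nm, 1, 1),
        x = atoms[[nm]][1], y = atoms[[nm]][2], z = atoms[[nm]][3],
        occ = 1, altloc = "", stringsAsFactors = FALSE)
    }
  }
  validate_structure(new_structure(do.call(rbind, rows),
                                   source_id = source_id))
}

#' Build an ideal alpha-helix
#'
#' Backbone from ideal helical dihedrals (phi = -57, psi = -47 degrees) and
#' standard bond geometry; Cbeta stubs are placed on every non-glycine
#' residue. Consecutive Calpha atoms sit ~3.8 A apart with a helical rise
#' of ~1.5 A per residue. Deterministic: no randomness is involved.
#'
#' @param n number of residues (>= 4).
#' @param sequence one-letter sequence of length `n` (default poly-alanine).
#' @param chain chain identifier.
#' @param start_resno author number of the first residue.
#' @param source_id provenance label.
#' @return a `ddg_structure`.
#' @export
#' @examples
#' h <- make_ideal_helix(20, strrep("A", 20))
#' n_residues(h)
make_ideal_helix <- function(n, sequence = strrep("A", n), chain = "A",
                             start_resno = 1L,
                             source_id = "synthetic-helix") {
  if (n < 4) stop("a helix needs at least 4 residues")
  if (nchar(sequence) != n)
    stop("sequence length (", nchar(sequence), ") != n (", n, ")")
  bad <- setdiff(strsplit(sequence, "")[[1]], AA1)
  if (length(bad)) stop("unknown residue letter(s): ",
                        paste(unique(bad), collapse = ", "))
  res <- build_backbone(rep(deg(-57), n), rep(deg(-47), n))
  residues_to_structure(res, sequence, chain, start_resno, source_id)
}

#' Rigid transform helpers
#' @noRd
transform_structure <- function(s, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- cbind(s$atoms$x, s$atoms$y, s$atoms$z) %*% t(rot)
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}

#' Rotation taking unit vector `from` to unit vector `to`
#' @noRd
rotation_between <- function(from, to) {
  from <- from / vnorm(from); to <- to / vnorm(to)
  v <- vcross(from, to); s <- vnorm(v); cth <- sum(from * to)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    ## pick any perpendicular axis for a 180-degree flip
    ax <- if (abs(from[1]) < 0.9) vcross(from, c(1, 0, 0)) else
      vcross(from, c(0, 1, 0))
    ax <- ax / vnorm(ax)
    return(2 * outer(ax, ax) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

#' Align a helix so its axis runs along +z through the origin
#' @noRd
align_helix_z <- function(s) {
  ca <- s$atoms[s$atoms$atom == "CA", c("x", "y", "z")]
  axis <- colMeans(utils::tail(ca, -1) - utils::head(ca, -1))
  s <- transform_structure(s, rotation_between(as.numeric(axis), c(0, 0, 1)))
  ca <- s$atoms[s$atoms$atom == "CA", c("x", "y", "z")]
  transform_structure(s, shift = c(-mean(ca$x), -mean(ca$y), -ca$z[1]))
}

#' Specification for a synthetic structure
#'
#' @param topology `"single_helix"`, `"helix_linker_helix"` or
#'   `"two_helix_bundle"` (the last two share the same geometry: two
#'   antiparallel helices joined by a linker arc; the bundle emphasises a
#'   packed hydrophobic interface via the auto sequence).
#' @param length_per_segment integer vector: helix length for
#'   `single_helix`; `c(helix1, linker, helix2)` otherwise.
#' @param sequence full one-letter sequence or `"auto"` (hydrophobic at
#'   interface-facing positions, polar elsewhere, G/S in the linker).
#' @param inter_axis_distance distance between the two helix axes in
#'   Angstrom (default 9, a packed coiled-coil-like interface).
#' @param seed reserved for future stochastic decoration; the generator is
#'   deterministic.
#' @return list of class `ddg_synth_spec`.
#' @export
synth_structure_spec <- function(topology = c("two_helix_bundle",
                                              "helix_linker_helix",
                                              "single_helix"),
                                 length_per_segment = NULL,
                                 sequence = "auto",
                                 inter_axis_distance = 9,
                                 seed = 1L) {
  topology <- match.arg(topology)
  if (is.null(length_per_segment))
    length_per_segment <- if (topology == "single_helix") 16L else
      c(12L, 4L, 12L)
  if (topology == "single_helix" && length(length_per_segment) != 1L)
    stop("single_helix takes one segment length")
  if (topology != "single_helix" && length(length_per_segment) != 3L)
    stop(topology, " takes c(helix1, linker, helix2) lengths")
  structure(list(topology = topology,
                 length_per_segment = as.integer(length_per_segment),
                 sequence = sequence,
                 inter_axis_distance = inter_axis_distance,
                 seed = as.integer(seed)),
            class = "ddg_synth_spec")
}

#' Cbeta contact counts per residue
#'
#' Number of side-chain neighbours within `cutoff` Angstrom of each
#' residue's Cbeta (Calpha for glycine), ignoring sequence neighbours
#' closer than `min_sep` positions. This is the burial proxy used both by
#' the built-in scorer's exposure term and by the synthetic ground truth.
#'
#' @param s a `ddg_structure`.
#' @param cutoff contact radius in Angstrom.
#' @param min_sep minimum residue separation counted.
#' @return integer vector, one count per residue in structure order.
#' @export
cb_contact_counts <- function(s, cutoff = 7, min_sep = 2L) {
  ctx <- build_score_ctx(s, scorer_spec())
  cbm <- ctx$coords[ctx$cb_idx, , drop = FALSE]
  nrs <- nrow(cbm)
  dm <- as.matrix(stats::dist(cbm))
  diag(dm) <- Inf
  vapply(seq_len(nrs), function(i)
    sum(dm[i, ] < cutoff & abs(seq_len(nrs) - i) >= min_sep), integer(1))
}

#' Check consecutive Calpha geometry
#'
#' @param s a `ddg_structure`.
#' @param lo,hi allowed Calpha-Calpha distance range in Angstrom.
#' @return logical; attribute `"distances"` carries the vector.
#' @export
check_geometry <- function(s, lo = 2.8, hi = 4.3) {
  a <- s$atoms[s$atoms$atom == "CA", , drop = FALSE]
  ok <- TRUE; dists <- numeric()
  for (ch in unique(a$chain)) {
    ca <- a[a$chain == ch, c("x", "y", "z"), drop = FALSE]
    if (nrow(ca) < 2) next
    d <- sqrt(rowSums((utils::tail(ca, -1) - utils::head(ca, -1))^2))
    dists <- c(dists, d)
    ok <- ok && all(d >= lo & d <= hi)
  }
  structure(ok, distances = dists)
}

#' Build a synthetic two-helix structure with geometric ground truth
#'
#' Two ideal antiparallel helices at a configurable inter-axis distance,
#' joined N-to-C by a linker whose Calpha atoms follow an arc sampled at
#' ~3.6 A spacing. Ground-truth position classes are geometric: a helix
#' position is `buried` when its Cbeta points toward the partner helix,
#' `exposed` otherwise; linker residues are `linker`. With
#' `sequence = "auto"`, buried positions cycle through L/I/V/F, exposed
#' through E/K/Q/S and the linker through G/S.
#'
#' @param spec a `ddg_synth_spec` (see [synth_structure_spec()]).
#' @return list with `structure` (a `ddg_structure`) and `classes`
#'   (data.frame: `resno`, `class`, `segment`).
#' @export
#' @examples
#' b <- make_two_helix_bundle(synth_structure_spec())
#' table(b$classes$class)
make_two_helix_bundle <- function(spec = synth_structure_spec()) {
  stopifnot(inherits(spec, "ddg_synth_spec"))
  if (spec$topology == "single_helix") {
    n <- spec$length_per_segment[1]
    seqn <- if (identical(spec$sequence, "auto")) strrep("A", n) else
      spec$sequence
    s <- make_ideal_helix(n, seqn, source_id = "synthetic-single-helix")
    return(list(structure = s,
                classes = data.frame(resno = seq_len(n), class = "exposed",
                                     segment = "helix1")))
  }
  n1 <- spec$length_per_segment[1]
  nl <- spec$length_per_segment[2]
  n2 <- spec$length_per_segment[3]
  d <- spec$inter_axis_distance
  ## provisional poly-A helices to fix geometry (sequence applied later)
  hA <- align_helix_z(make_ideal_helix(n1, strrep("A", n1)))
  hB <- align_helix_z(make_ideal_helix(n2, strrep("A", n2)))
  ## antiparallel: flip B about the x axis, then set its axis at x = d and
  ## its N-terminus near A's C-terminus so the linker connects the tops
  flip_x <- diag(c(1, -1, -1))
  hB <- transform_structure(hB, flip_x)
  caA <- hA$atoms[hA$atoms$atom == "CA", c("x", "y", "z")]
  caB0 <- hB$atoms[hB$atoms$atom == "CA", c("x", "y", "z")]
  z_top <- max(caA$z)
  hB <- transform_structure(hB, shift = c(d, 0, z_top - max(caB0$z)))
  caB <- hB$atoms[hB$atoms$atom == "CA", c("x", "y", "z")]
  p_start <- as.numeric(caA[nrow(caA), ]) # A C-terminal CA
  p_end <- as.numeric(caB[1, ])           # B N-terminal CA
  ## linker CA path: quadratic Bezier bulging upward, arc length tuned so
  ## consecutive CAs sit ~3.6 A apart
  target_len <- 3.8 * (nl + 1)
  chord <- vnorm(p_end - p_start)
  if (target_len < chord * 1.02)
    stop("linker too short to bridge ", round(chord, 1), " A: increase the ",
         "linker segment or reduce inter_axis_distance")
  mid <- (p_start + p_end) / 2
  bez_len <- function(h) {
    ctrl <- mid + c(0, 0, h)
    t <- seq(0, 1, length.out = 201)
    pts <- outer((1 - t)^2, p_start) + outer(2 * t * (1 - t), ctrl) +
      outer(t^2, p_end)
    sum(sqrt(rowSums(diff(pts)^2)))
  }
  h_bulge <- stats::uniroot(function(h) bez_len(h) - target_len,
                            c(0, 6 * target_len))$root
  ctrl <- mid + c(0, 0, h_bulge)
  t_fine <- seq(0, 1, length.out = 400)
  pts <- outer((1 - t_fine)^2, p_start) + outer(2 * t_fine * (1 - t_fine),
                                                ctrl) +
    outer(t_fine^2, p_end)
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  want <- seq(0, arc[length(arc)], length.out = nl + 2)[2:(nl + 1)]
  link_ca <- t(vapply(want, function(w) {
    i <- which.min(abs(arc - w)); pts[i, ]
  }, numeric(3)))
  ## derive linker backbone atoms from the local path tangent
  path <- rbind(p_start, link_ca, p_end)
  link_rows <- list()
  for (k in seq_len(nl)) {
    ca <- path[k + 1, ]
    tang <- path[k + 2, ] - path[k, ]; tang <- tang / vnorm(tang)
    ref <- if (abs(tang[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    nrm <- vcross(tang, ref); nrm <- nrm / vnorm(nrm)
    bin <- vcross(tang, nrm)
    link_rows[[k]] <- list(N = ca - 1.05 * tang + 0.35 * nrm,
                           CA = ca,
                           C = ca + 1.05 * tang + 0.35 * nrm,
                           O = ca + 1.05 * tang + 0.35 * nrm + 1.23 * nrm,
                           CB = ca + 1.52 * bin)
  }
  ## ground truth is geometric burial by Cbeta contact count: helix
  ## positions with >= 5 contacts (7 A cutoff, sequence separation >= 2,
  ## counted on the Cbeta-complete backbone) are "buried"; in this packed
  ## antiparallel geometry those are exactly the interface-facing sites.
  seg <- c(rep("helix1", n1), rep("linker", nl), rep("helix2", n2))
  cb_all <- rbind(
    as.matrix(hA$atoms[hA$atoms$atom == "CB", c("x", "y", "z")]),
    do.call(rbind, lapply(link_rows, function(r) r$CB)),
    as.matrix(hB$atoms[hB$atoms$atom == "CB", c("x", "y", "z")]))
  classify_counts <- function(cbm) {
    nrs <- nrow(cbm)
    dm <- as.matrix(stats::dist(cbm))
    diag(dm) <- Inf
    counts <- vapply(seq_len(nrs), function(i)
      sum(dm[i, ] < 7 & abs(seq_len(nrs) - i) >= 2L), integer(1))
    ifelse(seg == "linker", "linker",
           ifelse(counts >= 5L, "buried", "exposed"))
  }
  classes <- data.frame(
    resno = seq_len(n1 + nl + n2),
    class = classify_counts(cb_all),
    segment = seg,
    stringsAsFactors = FALSE)
  ## sequence
  seq_chr <- if (identical(spec$sequence, "auto")) {
    pick <- function(cls) {
      pools <- list(buried = c("L", "I", "V", "F"),
                    exposed = c("E", "K", "Q", "S"),
                    linker = c("G", "S"))
      counters <- c(buried = 0L, exposed = 0L, linker = 0L)
      vapply(cls, function(cl) {
        counters[cl] <<- counters[cl] + 1L
        pool <- pools[[cl]]
        pool[(counters[cl] - 1L) %% length(pool) + 1L]
      }, character(1))
    }
    pick(classes$class)
  } else {
    if (nchar(spec$sequence) != n1 + nl + n2)
      stop("sequence length must equal total residue count")
    strsplit(spec$sequence, "")[[1]]
  }
  ## assemble one chain with continuous author numbering
  collect <- function(s, offset, letters_chr) {
    a <- s$atoms
    a$resno <- a$resno + offset
    a$aa <- letters_chr[a$resno - min(a$resno) + 1L]
    drop <- a$aa == "G" & a$atom == "CB"
    a[!drop, , drop = FALSE]
  }
  aA <- collect(hA, 0L, seq_chr[seq_len(n1)])
  aL <- do.call(rbind, lapply(seq_len(nl), function(k) {
    aa <- seq_chr[n1 + k]
    atoms <- link_rows[[k]]
    if (aa == "G") atoms$CB <- NULL
    do.call(rbind, lapply(names(atoms), function(nm) data.frame(
      chain = "A", resno = n1 + k, icode = "", aa = aa, atom = nm,
      element = substr(nm, 1, 1), x = atoms[[nm]][1], y = atoms[[nm]][2],
      z = atoms[[nm]][3], occ = 1, altloc = "", stringsAsFactors = FALSE)))
  }))
  aB <- collect(hB, n1 + nl, seq_chr[n1 + nl + seq_len(n2)])
  s <- validate_structure(new_structure(
    rbind(aA, aL, aB),
    source_id = paste0("synthetic-", spec$topology)))
  ## reject specs that pack the helices into steric clashes
  ctx_spec <- scorer_spec()
  ctx <- build_score_ctx(s, ctx_spec)
  dmin2 <- min((ctx$coords[ctx$ii, 1] - ctx$coords[ctx$jj, 1])^2 +
                 (ctx$coords[ctx$ii, 2] - ctx$coords[ctx$jj, 2])^2 +
                 (ctx$coords[ctx$ii, 3] - ctx$coords[ctx$jj, 3])^2)
  if (sqrt(dmin2) < ctx_spec$params$r_clash)
    stop("inter_axis_distance ", d, " A packs the helices below the clash ",
         "radius (min non-bonded distance ", round(sqrt(dmin2), 2), " A)")
  list(structure = s, classes = classes)
}

#' Specification for synthetic variant annotation tables
#'
#' Defaults state the emulated world: common variants are near-neutral
#' (ddG ~ N(0, 0.5) kcal/mol) and frequent (allele frequency 1e-3..1e-1,
#' benign labels); rare pathogenic variants are destabilised (ddG ~
#' N(4, 1)) and rare (1e-6..1e-4).
#'
#' @param n_common,n_rare_pathogenic stratum sizes.
#' @param common_ddg_mean,common_ddg_sd,pathogenic_ddg_mean,pathogenic_ddg_sd
#'   normal-draw parameters per stratum (kcal/mol).
#' @param common_freq_range,rare_freq_range allele-frequency ranges
#'   (log-uniform draws).
#' @param domain_start,domain_end author-numbering range variants are drawn
#'   over.
#' @param seed integer seed; identical seeds give byte-identical tables.
#' @return list of class `ddg_annotation_spec`.
#' @export
annotation_spec <- function(n_common = 50L, n_rare_pathogenic = 20L,
                            common_ddg_mean = 0, common_ddg_sd = 0.5,
                            pathogenic_ddg_mean = 4, pathogenic_ddg_sd = 1,
                            common_freq_range = c(1e-3, 1e-1),
                            rare_freq_range = c(1e-6, 1e-4),
                            domain_start = 341L, domain_end = 566L,
                            seed = 1L) {
  n_pos <- domain_end - domain_start + 1L
  if (n_common + n_rare_pathogenic > n_pos)
    stop("more variants requested than positions available")
  structure(list(n_common = as.integer(n_common),
                 n_rare_pathogenic = as.integer(n_rare_pathogenic),
                 common_ddg_mean = common_ddg_mean,
                 common_ddg_sd = common_ddg_sd,
                 pathogenic_ddg_mean = pathogenic_ddg_mean,
                 pathogenic_ddg_sd = pathogenic_ddg_sd,
                 common_freq_range = common_freq_range,
                 rare_freq_range = rare_freq_range,
                 domain_start = as.integer(domain_start),
                 domain_end = as.integer(domain_end),
                 seed = as.integer(seed)),
            class = "ddg_annotation_spec")
}

#' Generate synthetic allele-frequency and clinical-label tables
#'
#' Emulates the statistical structure of a population-frequency /
#' clinical-label join: a common near-neutral stratum and a rare
#' destabilised pathogenic stratum (about 30% of which are single-residue
#' deletions). Allele counts are drawn against a fixed allele number of
#' 2,000,000 and the reported frequency is exactly count/number.
#'
#' @param spec a `ddg_annotation_spec`.
#' @param dir directory the two TSV files are written into (created if
#'   needed); default a fresh temporary directory.
#' @return list with `frequency_tsv`, `label_tsv` (paths), `frequency`,
#'   `labels` (data.frames as written) and `truth` (variant, stratum,
#'   ddg_kcal, frequency, category).
#' @export
#' @examples
#' tabs <- make_annotation_tables(annotation_spec(n_common = 10,
#'                                                n_rare_pathogenic = 5))
#' head(tabs$truth)
make_annotation_tables <- function(spec = annotation_spec(),
                                   dir = tempfile("ddgscan-synth-")) {
  stopifnot(inherits(spec, "ddg_annotation_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  an <- 2000000L
  out <- with_seed(spec$seed, {
    n_tot <- spec$n_common + spec$n_rare_pathogenic
    positions <- sample(seq.int(spec$domain_start, spec$domain_end), n_tot)
    stratum <- c(rep("common", spec$n_common),
                 rep("rare_pathogenic", spec$n_rare_pathogenic))
    wt <- sample(AA1, n_tot, replace = TRUE)
    is_del <- stratum == "rare_pathogenic" &
      stats::runif(n_tot) < 0.3
    alt <- vapply(seq_len(n_tot), function(i) {
      if (is_del[i]) return(NA_character_)
      sample(setdiff(AA1, wt[i]), 1)
    }, character(1))
    label <- ifelse(is_del, paste0("Δ", wt, positions),
                    paste0(wt, positions, alt))
    ddg <- ifelse(stratum == "common",
                  stats::rnorm(n_tot, spec$common_ddg_mean,
                               spec$common_ddg_sd),
                  stats::rnorm(n_tot, spec$pathogenic_ddg_mean,
                               spec$pathogenic_ddg_sd))
    lo <- ifelse(stratum == "common", spec$common_freq_range[1],
                 spec$rare_freq_range[1])
    hi <- ifelse(stratum == "common", spec$common_freq_range[2],
                 spec$rare_freq_range[2])
    f_draw <- 10^stats::runif(n_tot, log10(lo), log10(hi))
    ac <- pmax(1L, as.integer(round(f_draw * an)))
    freq <- ac / an
    category <- ifelse(stratum == "common",
                       sample(c("benign", "likely_benign"), n_tot,
                              replace = TRUE),
                       sample(c("pathogenic", "likely_pathogenic"), n_tot,
                              replace = TRUE))
    list(label = label, stratum = stratum, ddg = ddg, ac = ac,
         freq = freq, category = category)
  })
  frequency <- data.frame(variant = out$label, allele_count = out$ac,
                          allele_number = an, frequency = out$freq,
                          stringsAsFactors = FALSE)
  labels <- data.frame(variant = out$label, category = out$category,
                       stringsAsFactors = FALSE)
  truth <- data.frame(variant = out$label, stratum = out$stratum,
                      ddg_kcal = out$ddg, frequency = out$freq,
                      category = out$category, stringsAsFactors = FALSE)
  freq_path <- file.path(dir, "frequency.tsv")
  label_path <- file.path(dir, "labels.tsv")
  write_tsv_det(frequency, freq_path)
  write_tsv_det(labels, label_path)
  list(frequency_tsv = freq_path, label_tsv = label_path,
       frequency = frequency, labels = labels, truth = truth)
}
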