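## structure_io: read, validate, slice and write protein structures in
## fixed-column PDB format. Structures are the substrate of every modelling
## stage; all residue addressing uses author (deposited) numbering, 1-based,
## so variant positions match the literature (e.g. K508).

BACKBONE_ATOMS <- c("N", "CA", "C")

#' Construct a structure object from an atom table
#'
#' Low-level constructor; most users will call [read_pdb()] or the
#' synthetic-structure generators instead.
#'
#' @param atoms data.frame with columns `chain`, `resno` (integer, author
#'   numbering), `icode` (insertion code, `""` if none), `aa` (one-letter
#'   residue code), `atom` (PDB atom name), `element`, `x`, `y`, `z`
#'   (coordinates in Angstrom), `occ` (occupancy), `altloc`.
#' @param source_id free-text label for provenance (e.g. `"3V42"` or
#'   `"synthetic-helix"`).
#' @param flagged data.frame of residues that failed backbone validation
#'   (columns `chain`, `resno`, `icode`, `reason`); these residues are kept
#'   in the coordinate table but excluded from scans.
#' @param missing_positions integer vector of author positions known to be
#'   absent (set by [slice_domain()]).
#' @return an object of class `ddg_structure`.
#' @export
new_structure <- function(atoms, source_id = "unknown",
                          flagged = NULL, missing_positions = integer()) {
  needed <- c("chain", "resno", "icode", "aa", "atom", "element",
              "x", "y", "z", "occ", "altloc")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(atoms$occ < 0 | atoms$occ > 1))
    stop("occupancy outside [0, 1]")
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  if (is.null(flagged))
    flagged <- data.frame(chain = character(), resno = integer(),
                          icode = character(), reason = character())
  structure(list(atoms = atoms, source_id = source_id, flagged = flagged,
                 missing_positions = as.integer(missing_positions)),
            class = "ddg_structure")
}

#' Residue-level view of a structure
#'
#' @param s a `ddg_structure`.
#' @return data.frame with one row per residue in file order: `chain`,
#'   `resno`, `icode`, `aa`, `n_atoms`, `resolved` (has N, CA and C and is
#'   not flagged).
#' @export
residue_table <- function(s) {
  stopifnot(inherits(s, "ddg_structure"))
  a <- s$atoms
  key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  idx <- !duplicated(key)
  res <- data.frame(chain = a$chain[idx], resno = a$resno[idx],
                    icode = a$icode[idx], aa = a$aa[idx],
                    stringsAsFactors = FALSE)
  ukey <- key[idx]
  res$n_atoms <- as.integer(table(factor(key, levels = ukey)))
  has_bb <- vapply(ukey, function(k) {
    all(BACKBONE_ATOMS %in% a$atom[key == k])
  }, logical(1))
  fkey <- paste(s$flagged$chain, s$flagged$resno, s$flagged$icode, sep = "\r")
  res$resolved <- has_bb & !(ukey %in% fkey)
  rownames(res) <- NULL
  res
}

#' @export
print.ddg_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<ddg_structure '%s'>: %d residues (%d resolved), %d atoms\n",
              x$source_id, nrow(rt), sum(rt$resolved), nrow(x$atoms)))
  if (length(x$missing_positions))
    cat("  missing positions:",
        paste(x$missing_positions, collapse = ", "), "\n")
  invisible(x)
}

#' Number of residues in a structure
#' @param s a `ddg_structure`.
#' @export
n_residues <- function(s) nrow(residue_table(s))

#' Validate a structure for modelling
#'
#' Checks finite coordinates and that every residue retains the N, CA and C
#' backbone atoms; residues failing the backbone check are moved to the
#' `flagged` table rather than dropped.
#'
#' @param s a `ddg_structure`.
#' @return the structure with `flagged` updated.
#' @export
validate_structure <- function(s) {
  rt <- residue_table(s)
  bad <- rt[!rt$resolved, , drop = FALSE]
  if (nrow(bad)) {
    add <- data.frame(chain = bad$chain, resno = bad$resno,
                      icode = bad$icode, reason = "missing backbone atoms")
    s$flagged <- unique(rbind(s$flagged, add))
  }
  s
}

parse_pdb_num <- function(txt, lineno, what) {
  v <- suppressWarnings(as.numeric(txt))
  if (anyNA(v))
    stop(sprintf("PDB parse error at line %d: bad %s field '%s'",
                 lineno[is.na(v)][1], what, trimws(txt[is.na(v)][1])))
  v
}

#' Read a structure from PDB-format text
#'
#' Parses fixed-column (v3.3) ATOM records. HETATM records, waters and
#' non-standard residues are dropped with a warning; alternate locations are
#' resolved per atom according to `altloc_policy`. Residues missing any of
#' the N/CA/C backbone atoms are flagged (see [validate_structure()]), not
#' silently removed.
#'
#' @param text PDB file content as a single string or character vector of
#'   lines. A path to an existing file is also accepted.
#' @param altloc_policy `"highest_occupancy"` (default; ties broken by
#'   altloc character order) or `"first"` (first occurrence in the file).
#' @param source_id provenance label stored on the result.
#' @return a validated `ddg_structure`.
#' @export
#' @examples
#' helix <- make_ideal_helix(10, strrep("A", 10))
#' s <- read_pdb(write_pdb(helix))
#' n_residues(s)
read_pdb <- function(text, altloc_policy = c("highest_occupancy", "first"),
                     source_id = "pdb") {
  altloc_policy <- match.arg(altloc_policy)
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    source_id <- if (identical(source_id, "pdb"))
      tools::file_path_sans_ext(basename(text)) else source_id
    text <- readLines(text, warn = FALSE)
  }
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  if (!length(lines) || all(!nzchar(trimws(lines))))
    stop("PDB parse error: empty input")
  rec <- substr(lines, 1, 6)
  is_atom <- trimws(rec) == "ATOM"
  n_het <- sum(trimws(rec) == "HETATM")
  if (n_het)
    warning(sprintf("dropping %d HETATM record(s) (waters/ligands)", n_het))
  if (!any(is_atom))
    stop("PDB parse error: no ATOM records found")
  ln <- which(is_atom)
  al <- lines[is_atom]
  if (any(nchar(al) < 54))
    stop(sprintf("PDB parse error at line %d: ATOM line shorter than 54 columns",
                 ln[nchar(al) < 54][1]))
  resname <- trimws(substr(al, 18, 20))
  aa <- aa3_to_aa1(resname)
  nonstd <- is.na(aa)
  if (any(nonstd)) {
    warning(sprintf("dropping %d atom(s) in non-standard residue(s): %s",
                    sum(nonstd),
                    paste(unique(resname[nonstd]), collapse = ", ")))
    al <- al[!nonstd]; ln <- ln[!nonstd]; aa <- aa[!nonstd]
    if (!length(al)) stop("PDB parse error: no standard amino-acid residues")
  }
  occ_txt <- trimws(substr(al, 55, 60))
  occ <- ifelse(nzchar(occ_txt),
                parse_pdb_num(ifelse(nzchar(occ_txt), occ_txt, "1"), ln,
                              "occupancy"), 1)
  atoms <- data.frame(
    chain = substr(al, 22, 22),
    resno = as.integer(parse_pdb_num(substr(al, 23, 26), ln, "residue number")),
    icode = trimws(substr(al, 27, 27)),
    aa = aa,
    atom = trimws(substr(al, 13, 16)),
    element = trimws(substr(al, 77, 78)),
    x = parse_pdb_num(substr(al, 31, 38), ln, "x coordinate"),
    y = parse_pdb_num(substr(al, 39, 46), ln, "y coordinate"),
    z = parse_pdb_num(substr(al, 47, 54), ln, "z coordinate"),
    occ = pmin(occ, 1),
    altloc = trimws(substr(al, 17, 17)),
    stringsAsFactors = FALSE)
  guess <- !nzchar(atoms$element)
  atoms$element[guess] <- substr(gsub("[0-9]", "", atoms$atom[guess]), 1, 1)
  ## resolve altlocs per (residue, atom name)
  akey <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$atom, sep = "\r")
  if (anyDuplicated(akey)) {
    keep <- logical(nrow(atoms))
    for (grp in split(seq_len(nrow(atoms)), factor(akey, levels = unique(akey)))) {
      if (length(grp) == 1L) { keep[grp] <- TRUE; next }
      if (altloc_policy == "first") {
        keep[grp[1]] <- TRUE
      } else {
        ord <- order(-atoms$occ[grp], atoms$altloc[grp])
        keep[grp[ord[1]]] <- TRUE
      }
    }
    atoms <- atoms[keep, , drop = FALSE]
  }
  validate_structure(new_structure(atoms, source_id = source_id))
}

#' Write a structure as PDB-format text
#'
#' Inverse of [read_pdb()]: output re-parses to an equivalent structure with
#' coordinates preserved to 1e-3 Angstrom (the PDB fixed-column precision).
#'
#' @param s a `ddg_structure`.
#' @param path optional file path; when given the text is also written there.
#' @return PDB text as a single string (invisibly when `path` is given).
#' @export
write_pdb <- function(s, path = NULL) {
  stopifnot(inherits(s, "ddg_structure"))
  a <- s$atoms
  if (!nrow(a)) stop("cannot write an empty structure")
  name4 <- ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom)
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)) %% 100000, name4, substr(paste0(a$altloc, " "), 1, 1),
    aa1_to_aa3(a$aa), a$chain, a$resno,
    substr(paste0(a$icode, " "), 1, 1), a$x, a$y, a$z, a$occ, 0, a$element)
  txt <- paste(c(sprintf("REMARK   1 SOURCE %s", s$source_id), lines, "END"),
               collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Extract a residue range from one chain
#'
#' Returns the residues with `start <= resno <= end` on the given chain in
#' their original order. Author positions absent from the range (chain
#' breaks, unresolved density) are recorded in the result's
#' `missing_positions` field rather than silently skipped.
#'
#' @param s a `ddg_structure`.
#' @param chain chain identifier.
#' @param start,end inclusive author-numbering bounds, `start <= end`.
#' @return a `ddg_structure` restricted to the range.
#' @export
slice_domain <- function(s, chain, start, end) {
  stopifnot(inherits(s, "ddg_structure"))
  if (start > end) stop("start must be <= end")
  if (!chain %in% unique(s$atoms$chain))
    stop("chain '", chain, "' not present in structure")
  sel <- s$atoms$chain == chain & s$atoms$resno >= start & s$atoms$resno <= end
  if (!any(sel)) stop(sprintf("empty slice: no residues in %d-%d on chain %s",
                              start, end, chain))
  atoms <- s$atoms[sel, , drop = FALSE]
  present <- unique(atoms$resno)
  missing <- setdiff(seq.int(start, end), present)
  fl <- s$flagged[s$flagged$chain == chain &
                    s$flagged$resno >= start & s$flagged$resno <= end, ,
                  drop = FALSE]
  new_structure(atoms, source_id = sprintf("%s[%s:%d-%d]", s$source_id,
                                           chain, start, end),
                flagged = fl, missing_positions = missing)
}

#' One-letter sequence of a structure
#' @param s a `ddg_structure`.
#' @return named character vector of one-letter codes, names are author
#'   residue numbers.
#' @export
structure_sequence <- function(s) {
  rt <- residue_table(s)
  stats::setNames(rt$aa, rt$resno)
}
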