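## variants: parse, format and enumerate missense and single-residue
## deletion variants in the short notation used in the clinical literature
## ("R362C", "ΔK508"/"delK508"/"K508del").

#' Create a variant object
#'
#' @param kind `"missense"` or `"deletion"`.
#' @param position author-numbering residue position (integer > 0).
#' @param wt one-letter wild-type residue.
#' @param alt one-letter substituted residue (missense only; must be absent
#'   for deletions).
#' @return an object of class `ddg_variant`.
#' @export
new_variant <- function(kind = c("missense", "deletion"), position, wt,
                        alt = NULL) {
  kind <- match.arg(kind)
  position <- as.integer(position)
  if (is.na(position) || position <= 0) stop("variant position must be > 0")
  if (!is_aa1(wt)) stop("unknown amino-acid letter: ", wt)
  if (kind == "missense") {
    if (is.null(alt)) stop("missense variant requires an alt residue")
    if (!is_aa1(alt)) stop("unknown amino-acid letter: ", alt)
  } else if (!is.null(alt)) {
    stop("deletion variant must not carry an alt residue")
  }
  structure(list(kind = kind, position = position, wt = wt, alt = alt),
            class = "ddg_variant")
}

#' @export
print.ddg_variant <- function(x, ...) {
  cat("<ddg_variant>", format_variant(x), "\n")
  invisible(x)
}

#' Parse a variant label
#'
#' Accepts missense labels like `"R362C"` and single-residue deletions
#' written `"ΔK508"`, `"delK508"` or `"K508del"` (the `del` spelling is
#' case-insensitive). `"K508K"` parses as an identity missense variant (the
#' wild-type reference).
#'
#' @param label non-empty variant label.
#' @return a `ddg_variant`.
#' @export
#' @examples
#' parse_variant("R362C")
#' parse_variant("delK508")
parse_variant <- function(label) {
  if (!is.character(label) || length(label) != 1L || !nzchar(trimws(label)))
    stop("variant label must be a non-empty string")
  lab <- trimws(label)
  m <- regmatches(lab, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", lab))[[1]]
  if (length(m)) {
    pos <- suppressWarnings(as.integer(m[3]))
    if (is.na(pos) || pos <= 0)
      stop("invalid variant position in label: ", label)
    return(new_variant("missense", pos, toupper(m[2]), toupper(m[4])))
  }
  del <- regmatches(
    lab, regexec("^(?:Δ|[Dd][Ee][Ll])([A-Za-z])([0-9]+)$", lab))[[1]]
  if (!length(del))
    del <- regmatches(
      lab, regexec("^([A-Za-z])([0-9]+)[Dd][Ee][Ll]$", lab))[[1]]
  if (length(del)) {
    pos <- suppressWarnings(as.integer(del[3]))
    if (is.na(pos) || pos <= 0)
      stop("invalid variant position in label: ", label)
    return(new_variant("deletion", pos, toupper(del[2])))
  }
  stop("cannot parse variant label: ", label)
}

#' Format a variant as a label
#'
#' Round-trips with [parse_variant()]. Deletions render as `"ΔK508"` by
#' default; `style = "ascii"` gives `"delK508"`.
#'
#' @param v a `ddg_variant`.
#' @param style `"unicode"` (default) or `"ascii"`.
#' @return character label.
#' @export
format_variant <- function(v, style = c("unicode", "ascii")) {
  style <- match.arg(style)
  stopifnot(inherits(v, "ddg_variant"))
  if (v$kind == "missense")
    return(paste0(v$wt, v$position, v$alt))
  prefix <- if (style == "unicode") "Δ" else "del"
  paste0(prefix, v$wt, v$position)
}

#' Check a variant's wild-type residue against a structure
#' @param v a `ddg_variant`; `s` a `ddg_structure`.
#' @return invisibly `TRUE`; errors if the position is absent/unresolved or
#'   the structure's residue differs from `v$wt`.
#' @noRd
check_variant_against <- function(v, s) {
  rt <- residue_table(s)
  row <- rt[rt$resno == v$position, , drop = FALSE]
  if (!nrow(row))
    stop("position ", v$position, " not present in structure")
  if (!row$resolved[1])
    stop("position ", v$position, " is unresolved (missing backbone atoms)")
  if (row$aa[1] != v$wt)
    stop(sprintf("wild-type mismatch at %d: variant says %s, structure has %s",
                 v$position, v$wt, row$aa[1]))
  invisible(TRUE)
}

#' Enumerate the full saturation variant set of a structure
#'
#' For every resolved position: the 20 amino-acid identities (19 proper
#' substitutions plus the wild-type reference, flagged in `is_reference`)
#' and one single-residue deletion, in deterministic order (position, then
#' alt residue alphabetically, deletion last). Unresolved positions are
#' skipped and listed in the `skipped_positions` attribute.
#'
#' @param s a `ddg_structure` with at least one resolved residue.
#' @return a data.frame of class `ddg_variant_set` with columns `kind`,
#'   `position`, `wt`, `alt` (`NA` for deletions), `is_reference`, `label`;
#'   attributes `domain_start`, `domain_end`, `skipped_positions`.
#' @export
enumerate_saturation <- function(s) {
  rt <- residue_table(s)
  if (!nrow(rt)) stop("empty structure")
  res <- rt[rt$resolved, , drop = FALSE]
  if (!nrow(res)) stop("no resolved residues to enumerate")
  per_pos <- function(i) {
    pos <- res$resno[i]; wt <- res$aa[i]
    data.frame(
      kind = c(rep("missense", 20L), "deletion"),
      position = pos,
      wt = wt,
      alt = c(AA1, NA_character_),
      is_reference = c(AA1 == wt, FALSE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(res)), per_pos))
  out$label <- ifelse(out$kind == "deletion",
                      paste0("Δ", out$wt, out$position),
                      paste0(out$wt, out$position, out$alt))
  if (anyDuplicated(out$label)) stop("internal error: duplicate variants")
  rownames(out) <- NULL
  attr(out, "domain_start") <- min(res$resno)
  attr(out, "domain_end") <- max(res$resno)
  attr(out, "skipped_positions") <- rt$resno[!rt$resolved]
  class(out) <- c("ddg_variant_set", class(out))
  out
}

#' Convert one row of a variant set to a `ddg_variant`
#' @noRd
variant_from_row <- function(row) {
  if (row$kind == "deletion")
    new_variant("deletion", row$position, row$wt)
  else new_variant("missense", row$position, row$wt, row$alt)
}
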