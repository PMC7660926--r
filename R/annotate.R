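## annotate: join ddG records with population allele frequencies and
## clinical labels, classify stability, and derive fishtail tables,
## per-segment heatmap matrices and consensus-motif scans.

CLINICAL_CATEGORIES <- c("benign", "likely_benign", "VUS", "conflicting",
                         "pathogenic", "likely_pathogenic")

normalize_category <- function(x) {
  key <- gsub("[ .]", "_", tolower(trimws(x)))
  map <- c(benign = "benign", likely_benign = "likely_benign",
           like__benign = "likely_benign", vus = "VUS",
           conflicting = "conflicting", pathogenic = "pathogenic",
           likely_pathogenic = "likely_pathogenic")
  out <- unname(map[key])
  if (anyNA(out))
    stop("unknown clinical category: ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' Load a gnomAD-style allele-frequency table
#'
#' Expects a TSV with a header naming at least `variant`, `allele_count`,
#' `allele_number` and `frequency`. Rows whose variant label does not parse
#' or whose frequency disagrees with `allele_count / allele_number` by more
#' than 1e-9 are collected into a rejects report, never silently dropped.
#'
#' @param tsv path to a TSV file, or its content as a string.
#' @return data.frame with columns `variant` (canonical label), `position`,
#'   `allele_count`, `allele_number`, `frequency`; attribute `"rejects"`
#'   holds a data.frame of rejected rows with reasons.
#' @export
load_frequency_table <- function(tsv) {
  df <- read_tsv_arg(tsv)
  needed <- c("variant", "allele_count", "allele_number", "frequency")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("frequency table lacks column(s): ", paste(missing, collapse = ", "))
  keep <- logical(nrow(df)); rejects <- list()
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    v <- tryCatch(parse_variant(df$variant[i]), error = function(e) e)
    if (inherits(v, "error")) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(row = i, variant = df$variant[i],
                   reason = conditionMessage(v))
      next
    }
    ac <- as.numeric(df$allele_count[i]); an <- as.numeric(df$allele_number[i])
    f <- as.numeric(df$frequency[i])
    if (is.finite(ac) && is.finite(an) && an > 0 &&
        abs(f - ac / an) > 1e-9) {
      rejects[[length(rejects) + 1L]] <-
        data.frame(row = i, variant = df$variant[i],
                   reason = sprintf("frequency %g inconsistent with %g/%g",
                                    f, ac, an))
      next
    }
    keep[i] <- TRUE
    out[[i]] <- data.frame(variant = format_variant(v),
                           position = v$position,
                           allele_count = as.integer(ac),
                           allele_number = as.integer(an),
                           frequency = f, stringsAsFactors = FALSE)
  }
  res <- if (any(keep)) do.call(rbind, out[keep]) else
    data.frame(variant = character(), position = integer(),
               allele_count = integer(), allele_number = integer(),
               frequency = numeric())
  rownames(res) <- NULL
  attr(res, "rejects") <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(row = integer(), variant = character(), reason = character())
  res
}

#' Load a ClinVar-style clinical-label table
#'
#' Expects columns `variant` and `category`; categories are normalised to
#' the closed set benign / likely_benign / VUS / conflicting / pathogenic /
#' likely_pathogenic, and anything else is an error at load.
#'
#' @param tsv path to a TSV file, or its content as a string.
#' @return data.frame with `variant` (canonical label), `position`,
#'   `category`.
#' @export
load_label_table <- function(tsv) {
  df <- read_tsv_arg(tsv)
  missing <- setdiff(c("variant", "category"), names(df))
  if (length(missing))
    stop("label table lacks column(s): ", paste(missing, collapse = ", "))
  vars <- lapply(df$variant, parse_variant)
  data.frame(variant = vapply(vars, format_variant, character(1)),
             position = vapply(vars, `[[`, integer(1), "position"),
             category = normalize_category(df$category),
             stringsAsFactors = FALSE)
}

read_tsv_arg <- function(tsv) {
  if (length(tsv) == 1L && !grepl("\n", tsv) && file.exists(tsv))
    return(utils::read.delim(tsv, stringsAsFactors = FALSE,
                             check.names = TRUE))
  utils::read.delim(text = paste(tsv, collapse = "\n"),
                    stringsAsFactors = FALSE, check.names = TRUE)
}

#' Classify a ddG value into a stability class
#'
#' `ddg < neutral_max` is `neutral`; `ddg >= destabilized_min` is
#' `destabilized` (the boundary is inclusive on the destabilised side);
#' anything between is `intermediate`. The 3 kcal/mol default anchor is the
#' destabilisation magnitude at which cellular quality control reliably
#' engages.
#'
#' @param ddg_kcal numeric vector of ddG values (kcal/mol).
#' @param neutral_max upper bound of the neutral class (default 1.0).
#' @param destabilized_min lower bound of the destabilised class
#'   (default 3.0); must be `>= neutral_max`.
#' @return character vector in {"neutral", "intermediate", "destabilized"}.
#' @export
#' @examples
#' classify_stability(c(0.02, 2, 5))
classify_stability <- function(ddg_kcal, neutral_max = 1.0,
                               destabilized_min = 3.0) {
  if (neutral_max > destabilized_min)
    stop("neutral_max must be <= destabilized_min")
  ifelse(ddg_kcal >= destabilized_min, "destabilized",
         ifelse(ddg_kcal < neutral_max, "neutral", "intermediate"))
}

record_label <- function(rec) format_variant(rec$variant)

#' Build a fishtail table from ddG records and annotation tables
#'
#' Outer join on the ddG side: one row per record, with allele frequency
#' and clinical category attached by exact variant-label match where
#' available. A variant absent from the frequency table gets `NA` frequency
#' (population absence is censoring, not frequency zero). Unmatched
#' annotation rows are reported via the `"unmatched"` attribute; a
#' duplicated annotation for one variant is an error.
#'
#' @param ddg list of `ddg_record` objects (e.g. `records` from
#'   [saturation_scan()]).
#' @param freq frequency table from [load_frequency_table()] (or `NULL`).
#' @param labels label table from [load_label_table()] (or `NULL`).
#' @param neutral_max,destabilized_min thresholds for
#'   [classify_stability()].
#' @return data.frame sorted by position then label: `variant`, `position`,
#'   `kind`, `ddg_kcal`, `frequency`, `category`, `stability_class`.
#' @export
build_fishtail <- function(ddg, freq = NULL, labels = NULL,
                           neutral_max = 1.0, destabilized_min = 3.0) {
  if (inherits(ddg, "ddg_record")) ddg <- list(ddg)
  stopifnot(all(vapply(ddg, inherits, logical(1), "ddg_record")))
  check_dup <- function(tab, what) {
    if (!is.null(tab) && anyDuplicated(tab$variant))
      stop("duplicate ", what, " annotation for variant(s): ",
           paste(unique(tab$variant[duplicated(tab$variant)]),
                 collapse = ", "))
  }
  check_dup(freq, "frequency"); check_dup(labels, "clinical")
  rows <- lapply(ddg, function(rec) {
    lab <- record_label(rec)
    data.frame(variant = lab, position = rec$variant$position,
               kind = rec$variant$kind, ddg_kcal = rec$ddg_kcal,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$frequency <- if (is.null(freq)) NA_real_ else
    freq$frequency[match(out$variant, freq$variant)]
  out$category <- if (is.null(labels)) NA_character_ else
    labels$category[match(out$variant, labels$variant)]
  out$stability_class <- classify_stability(out$ddg_kcal, neutral_max,
                                            destabilized_min)
  out <- out[order(out$position, out$variant), , drop = FALSE]
  rownames(out) <- NULL
  unmatched <- c(
    if (!is.null(freq)) setdiff(freq$variant, out$variant),
    if (!is.null(labels)) setdiff(labels$variant, out$variant))
  attr(out, "unmatched") <- unique(unmatched)
  out
}

#' Per-segment heatmap matrix of ddG values
#'
#' 21 rows ("del" first, then the 20 amino acids alphabetically) by one
#' column per position in `[start, end]`. Cells without a record are `NA`;
#' wild-type identity cells are exactly 0.
#'
#' @param ddg list of `ddg_record` objects.
#' @param start,end inclusive author-numbering range.
#' @return an object of class `ddg_heatmap`: list with `matrix` (21 x
#'   n-positions), `positions`, `wt` (named wild-type letters where known).
#' @export
heatmap_matrix <- function(ddg, start, end) {
  if (start > end) stop("start must be <= end")
  if (inherits(ddg, "ddg_record")) ddg <- list(ddg)
  positions <- seq.int(start, end)
  keep <- Filter(function(r) r$variant$position >= start &&
                   r$variant$position <= end, ddg)
  if (!length(keep)) stop("no ddG records in range ", start, "-", end)
  rows <- c("del", AA1)
  m <- matrix(NA_real_, nrow = length(rows), ncol = length(positions),
              dimnames = list(rows, positions))
  wt <- stats::setNames(rep(NA_character_, length(positions)),
                        positions)
  for (r in keep) {
    col <- as.character(r$variant$position)
    row <- if (r$variant$kind == "deletion") "del" else r$variant$alt
    m[row, col] <- r$ddg_kcal
    wt[col] <- r$variant$wt
  }
  structure(list(matrix = m, positions = positions, wt = wt),
            class = "ddg_heatmap")
}

#' @export
print.ddg_heatmap <- function(x, ...) {
  cat(sprintf("<ddg_heatmap> 21 x %d (positions %d-%d), %d cells filled\n",
              ncol(x$matrix), min(x$positions), max(x$positions),
              sum(!is.na(x$matrix))))
  invisible(x)
}

#' Write a heatmap matrix as TSV (and optionally render it)
#'
#' @param hm a `ddg_heatmap`.
#' @param path TSV output path.
#' @param image optional PNG path; rendered with pheatmap when available,
#'   skipped with a message otherwise.
#' @return invisibly `path`.
#' @export
write_heatmap <- function(hm, path, image = NULL) {
  stopifnot(inherits(hm, "ddg_heatmap"))
  df <- data.frame(variant = rownames(hm$matrix), hm$matrix,
                   check.names = FALSE)
  write_tsv_det(df, path)
  if (!is.null(image)) {
    ok <- requireNamespace("pheatmap", quietly = TRUE)
    if (ok) {
      m <- hm$matrix
      m[is.na(m)] <- 0
      tryCatch({
        grDevices::png(image, width = 120 + 24 * ncol(m), height = 560)
        pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE)
        grDevices::dev.off()
      }, error = function(e) message("heatmap image skipped: ",
                                     conditionMessage(e)))
    } else message("heatmap image skipped: pheatmap not installed")
  }
  invisible(path)
}

## ---- consensus-motif scanning -------------------------------------------

#' Default deubiquitinase-recognition consensus patterns
#'
#' `TRAF`: `[PA]xxS` (the P/A-x-x-S recognition motif of the TRAF-domain
#' binding pocket). `UBL12`: `KxKxxxK` (lysine-spaced pattern consistent
#' with the known UBL1/2-domain binding sites). `x` matches any residue;
#' both are configuration, not biology baked into the code.
#'
#' @return named character vector of patterns.
#' @export
default_usp7_patterns <- function() {
  c(TRAF = "[PA]xxS", UBL12 = "KxKxxxK")
}

parse_motif_pattern <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  sets <- list(); i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L; cls <- character()
      while (j <= length(chars) && chars[j] != "]") {
        cls <- c(cls, chars[j]); j <- j + 1L
      }
      if (j > length(chars)) stop("invalid pattern syntax: unclosed '[' in ",
                                  pattern)
      if (!length(cls) || !all(cls %in% AA1))
        stop("invalid pattern syntax: bad residue class in ", pattern)
      sets[[length(sets) + 1L]] <- cls
      i <- j + 1L
    } else if (ch == "x" || ch == "X") {
      sets[[length(sets) + 1L]] <- AA1
      i <- i + 1L
    } else if (toupper(ch) %in% AA1) {
      sets[[length(sets) + 1L]] <- toupper(ch)
      i <- i + 1L
    } else stop("invalid pattern syntax: character '", ch, "' in ", pattern)
  }
  if (!length(sets)) stop("invalid pattern syntax: empty pattern")
  sets
}

#' Scan a sequence for position-wise consensus motifs
#'
#' Patterns are position-wise residue-class strings: a literal one-letter
#' residue, `x` for any residue, or a bracketed class like `[PA]`. All
#' (possibly overlapping) matches are returned with 1-based start
#' positions.
#'
#' @param sequence one-letter amino-acid string.
#' @param patterns named character vector of patterns (default
#'   [default_usp7_patterns()]).
#' @param offset value added to reported positions (use the author number
#'   of the first sequence residue minus one).
#' @return data.frame: `motif`, `start`, `match`.
#' @export
#' @examples
#' scan_usp7_motifs("AAKVKVLFKSAARSA")
scan_usp7_motifs <- function(sequence, patterns = default_usp7_patterns(),
                             offset = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.null(names(patterns)) || any(!nzchar(names(patterns))))
    stop("patterns must be named")
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  hits <- list()
  for (nm in names(patterns)) {
    sets <- parse_motif_pattern(patterns[[nm]])
    k <- length(sets)
    if (length(seq_chars) >= k) {
      for (start in seq_len(length(seq_chars) - k + 1L)) {
        ok <- TRUE
        for (j in seq_len(k)) {
          if (!(seq_chars[start + j - 1L] %in% sets[[j]])) { ok <- FALSE; break }
        }
        if (ok)
          hits[[length(hits) + 1L]] <- data.frame(
            motif = nm, start = start + as.integer(offset),
            match = paste(seq_chars[start:(start + k - 1L)], collapse = ""),
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(motif = character(), start = integer(),
                      match = character()))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}
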