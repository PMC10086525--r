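#' Read and validate a counts matrix with its sample metadata
#'
#' Counts are a TSV with a `feature` header column and one column per
#' sample; metadata is a TSV with columns sample_id, strain, tissue,
#' age_months, sex. Malformed records (duplicate ids, negative or
#' non-integer counts, metadata/sample mismatches) are rejected with an
#' error naming the offending record rather than silently coerced.
#'
#' @param counts_path Path to the counts TSV.
#' @param samples_path Path to the sample metadata TSV.
#' @return List with `counts` (wide tibble) and `samples` (tibble).
#' @export
read_counts <- function(counts_path, samples_path) {
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE,
                            progress = FALSE)
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE,
                             progress = FALSE)
  validate_counts(counts, samples)
  counts <- mutate(counts, across(-"feature", as.integer))
  list(counts = counts, samples = as_tibble(samples))
}

#' Write a counts matrix and sample metadata to TSV
#'
#' @param counts Wide counts tibble (`feature` + one column per sample).
#' @param samples Sample metadata tibble.
#' @param counts_path,samples_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_counts <- function(counts, samples, counts_path, samples_path) {
  validate_counts(counts, samples)
  readr::write_tsv(counts, counts_path, progress = FALSE)
  readr::write_tsv(samples, samples_path, progress = FALSE)
  invisible(c(counts_path, samples_path))
}

#' Read a GMT gene-set collection
#'
#' Standard GMT semantics: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`. Member order is
#' preserved for reporting; duplicate members within a line are stored
#' once. An empty file yields an empty collection.
#'
#' @param path Path to a GMT file.
#' @return Tibble with columns set, description, and a list-column
#'   `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(set = character(), description = character(),
                  members = list()))
  }
  parsed <- purrr::imap(lines, function(ln, i) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields, found %d.",
                    i, length(parts)))
    }
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      abort(sprintf("GMT parse error at line %d: set '%s' has no members.",
                    i, parts[1]))
    }
    tibble(set = parts[1], description = parts[2],
           members = list(unique(members)))
  })
  out <- bind_rows(parsed)
  if (anyDuplicated(out$set)) {
    abort(sprintf("Duplicate gene-set names in %s.", path))
  }
  out
}

#' Write a gene-set collection to GMT
#'
#' @param collection Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(collection, function(set, description, members) {
    paste(c(set, description, members), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read genomic intervals from BED
#'
#' Peaks are BED3+ (chrom, start, end, optional name); footprints are
#' BED6 where the name field carries the TF and the score field the
#' purity scaled to \[0, 1000\] (purity = score / 1000). All intervals
#' are 0-based half-open; records with `end <= start` or an unknown
#' strand are rejected.
#'
#' @param path Path to a BED file.
#' @param kind `"peaks"` or `"footprints"`.
#' @return Tibble of intervals; footprints carry `tf`, `purity`,
#'   `strand`.
#' @export
read_bed <- function(path, kind = c("peaks", "footprints")) {
  kind <- match.arg(kind)
  min_cols <- if (kind == "peaks") 3L else 6L
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    if (kind == "peaks") {
      return(tibble(chrom = character(), start = integer(),
                    end = integer(), name = character()))
    }
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  tf = character(), purity = double(),
                  strand = character()))
  }
  rows <- purrr::imap(lines, function(ln, i) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < min_cols) {
      abort(sprintf("BED parse error at line %d: expected >= %d fields.",
                    i, min_cols))
    }
    start <- suppressWarnings(as.integer(parts[2]))
    end <- suppressWarnings(as.integer(parts[3]))
    if (is.na(start) || is.na(end) || start < 0 || end <= start) {
      abort(sprintf("BED validation error at line %d: need 0 <= start < end (got %s, %s).",
                    i, parts[2], parts[3]))
    }
    if (kind == "peaks") {
      tibble(chrom = parts[1], start = start, end = end,
             name = if (length(parts) >= 4) parts[4] else NA_character_)
    } else {
      score <- suppressWarnings(as.numeric(parts[5]))
      if (is.na(score) || score < 0 || score > 1000) {
        abort(sprintf("BED validation error at line %d: footprint score must be in [0, 1000].", i))
      }
      strand <- parts[6]
      if (!strand %in% c("+", "-", ".")) {
        abort(sprintf("BED validation error at line %d: unknown strand '%s'.",
                      i, strand))
      }
      tibble(chrom = parts[1], start = start, end = end,
             tf = parts[4], purity = score / 1000, strand = strand)
    }
  })
  bind_rows(rows)
}

#' Write intervals to BED
#'
#' Footprint purity is written as the BED score, rounded to an integer
#' in \[0, 1000\] (score = purity x 1000).
#'
#' @param intervals Tibble of peaks (chrom/start/end\[/name\]) or
#'   footprints (chrom/start/end/tf/purity\[/strand\]).
#' @param path Output path.
#' @param kind `"peaks"` or `"footprints"`.
#' @export
write_bed <- function(intervals, path, kind = c("peaks", "footprints")) {
  kind <- match.arg(kind)
  if (kind == "peaks") {
    nm <- if ("name" %in% names(intervals)) intervals$name
          else if ("peak_id" %in% names(intervals)) intervals$peak_id
          else sprintf("peak_%d", seq_len(nrow(intervals)))
    lines <- sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                     as.integer(intervals$start),
                     as.integer(intervals$end), nm)
  } else {
    strand <- if ("strand" %in% names(intervals)) intervals$strand else "."
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", intervals$chrom,
                     as.integer(intervals$start),
                     as.integer(intervals$end), intervals$tf,
                     as.integer(round(intervals$purity * 1000)), strand)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSS table
#'
#' TSV with columns gene, chrom, pos (single 0-based coordinate),
#' strand (+ or -); one entry per gene.
#'
#' @param path Path to the TSS TSV.
#' @return Tibble gene/chrom/pos/strand.
#' @export
read_tss <- function(path) {
  tss <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("gene", "chrom", "pos", "strand")
  if (!all(req %in% names(tss))) {
    abort(sprintf("TSS table must have columns %s.",
                  paste(req, collapse = ", ")))
  }
  if (anyDuplicated(tss$gene)) abort("TSS table has duplicate gene ids.")
  if (any(tss$pos < 0)) abort("TSS positions must be >= 0.")
  if (!all(tss$strand %in% c("+", "-"))) {
    abort("TSS strand must be '+' or '-'.")
  }
  as_tibble(tss)
}

#' Write a TSS table
#' @param tss Tibble gene/chrom/pos/strand.
#' @param path Output path.
#' @export
write_tss <- function(tss, path) {
  readr::write_tsv(tss[, c("gene", "chrom", "pos", "strand")], path,
                   progress = FALSE)
  invisible(path)
}
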