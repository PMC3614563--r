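#' Construct and validate an exon model
#'
#' An exon model is the ordered set of capture-target intervals over which
#' read depth is counted. Intervals use BED conventions: 0-based starts,
#' exclusive ends. The tibble is sorted by `(chrom, start)` with chromosome
#' order taken from `genome_order` (first-appearance order by default).
#'
#' @param x A data frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive) and optionally `exon_id`.
#' @param genome_order Character vector giving chromosome sort order. Defaults
#'   to order of first appearance in `x`.
#'
#' @return A tibble of class `exon_model` with columns `chrom`, `start`,
#'   `end`, `exon_id`, sorted by genome position. The chromosome order is
#'   kept in attribute `genome_order`.
#' @export
#' @examples
#' exon_model(data.frame(chrom = "chr1", start = 0, end = 100))
exon_model <- function(x, genome_order = NULL) {
  x <- as_tibble(x)
  need <- c("chrom", "start", "end")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("exon model is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"exon_id" %in% names(x) || all(is.na(x$exon_id))) {
    x$exon_id <- sprintf("exon_%06d", seq_len(nrow(x)))
  }
  x$chrom <- as.character(x$chrom)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x$exon_id <- as.character(x$exon_id)
  bad <- which(x$start >= x$end)
  if (length(bad) > 0) {
    abort(sprintf("exon model has start >= end at row %d (%s:%d-%d)",
                  bad[1], x$chrom[bad[1]], x$start[bad[1]], x$end[bad[1]]))
  }
  if (anyDuplicated(x$exon_id)) {
    abort("exon model has duplicate exon_id values")
  }
  genome_order <- genome_order %||% unique(x$chrom)
  x <- x[order(match(x$chrom, genome_order), x$start, x$end), , drop = FALSE]
  x <- x[, c("chrom", "start", "end", "exon_id")]
  structure(x, genome_order = genome_order,
            class = c("exon_model", class(tibble())))
}

#' Read an exon model from a BED file
#'
#' Parses a 3+ column BED file (tab-separated, 0-based half-open intervals).
#' Column 4, when present, supplies exon identifiers; otherwise stable ids
#' are generated. Lines starting with `track`, `browser` or `#` are skipped.
#'
#' @param path Path to a BED file.
#' @return An [exon_model] tibble, sorted by genome position.
#' @export
read_exon_model <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) abort(paste0("no intervals in BED file: ", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    i <- which(nf < 3)[1]
    abort(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                  line_no[i], path))
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    i <- which(is.na(start) | is.na(end))[1]
    abort(sprintf("malformed BED line %d in %s: non-integer coordinates",
                  line_no[i], path))
  }
  ids <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], ""), NA)
  bad <- which(start >= end)
  if (length(bad) > 0) {
    abort(sprintf("invalid interval on BED line %d in %s: start %d >= end %d",
                  line_no[bad[1]], path, start[bad[1]], end[bad[1]]))
  }
  exon_model(tibble(chrom = chrom, start = start, end = end, exon_id = ids))
}

#' Write an exon model to a BED file
#'
#' @param model An [exon_model].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exon_model <- function(model, path) {
  model <- exon_model(model, attr(model, "genome_order"))
  readr::write_tsv(as_tibble(model)[, c("chrom", "start", "end", "exon_id")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Locate 1-based variant positions in an exon model
#'
#' A variant at 1-based position `p` lies inside the 0-based half-open exon
#' `[s, e)` iff `s < p <= e`. This is the single point where the two
#' coordinate conventions meet.
#'
#' @param model An [exon_model].
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @return Integer vector of row indices into `model` (NA when the position
#'   falls in no exon; the first containing exon when several overlap).
#' @export
locate_in_exon <- function(model, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  purrr::map2_int(chrom, pos, function(ch, p) {
    hit <- which(model$chrom == ch & model$start < p & p <= model$end)
    if (length(hit) == 0) NA_integer_ else hit[1]
  })
}
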