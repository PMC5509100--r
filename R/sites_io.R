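#' Read candidate motif sites from a BED file
#'
#' Parses a 3- to 6-column BED file of candidate binding sites. Coordinates
#' are kept in BED convention: 0-based, half-open `[start, end)`. A stable
#' `site_id` of the form `"chrom:start-end:strand"` is attached; it is the
#' canonical join key between score tables, statistics tables and truth
#' labels throughout the package.
#'
#' @param path Path to a BED file (no header). Columns beyond the sixth are
#'   ignored. When a name column is present it is kept as `name`; the score
#'   column, when numeric, is kept as `motif_score`.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`
#'   (`"+"`, `"-"` or `"."` when absent), `site_id`, and `motif_score`
#'   (`NA` when the BED file has no score column).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t119\t.\t0\t+", bed)
#' read_sites_bed(bed)
#' @export
read_sites_bed <- function(path) {
  # read.table(fill = TRUE) tolerates mixed BED3/BED6 records
  raw <- utils::read.table(path,
    sep = "\t", quote = "", comment.char = "#",
    colClasses = "character", fill = TRUE
  )
  if (ncol(raw) < 3L) {
    stop("BED file must have at least 3 columns, got ", ncol(raw), call. = FALSE)
  }
  sites <- tibble::tibble(
    chrom = raw[[1L]],
    start = as.integer(raw[[2L]]),
    end = as.integer(raw[[3L]]),
    name = if (ncol(raw) >= 4L) dplyr::na_if(raw[[4L]], "") else NA_character_,
    motif_score = if (ncol(raw) >= 5L) suppressWarnings(as.numeric(raw[[5L]])) else NA_real_,
    strand = if (ncol(raw) >= 6L) raw[[6L]] else "."
  )
  sites$strand[is.na(sites$strand) | sites$strand == ""] <- "."
  bad <- which(!(sites$start < sites$end) | sites$start < 0L)
  if (length(bad) > 0L) {
    stop("invalid interval (start >= end or start < 0) at line ", bad[1L],
      " of ", path,
      call. = FALSE
    )
  }
  bad_strand <- which(!sites$strand %in% c("+", "-", "."))
  if (length(bad_strand) > 0L) {
    stop("invalid strand '", sites$strand[bad_strand[1L]], "' at line ",
      bad_strand[1L],
      call. = FALSE
    )
  }
  sites$site_id <- make_site_id(sites$chrom, sites$start, sites$end, sites$strand)
  dplyr::select(
    sites, "chrom", "start", "end", "strand", "site_id",
    "name", "motif_score"
  )
}

#' Write candidate sites back to BED
#'
#' Inverse of [read_sites_bed()]: emits BED6 (`chrom start end name score
#' strand`) with `.`/`0` placeholders for missing name/score, so that
#' `write_sites_bed(read_sites_bed(f))` round-trips canonical input
#' byte-identically.
#'
#' @param sites A tibble as returned by [read_sites_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  out <- data.frame(
    chrom = sites$chrom,
    start = format(sites$start, scientific = FALSE, trim = TRUE),
    end = format(sites$end, scientific = FALSE, trim = TRUE),
    name = ifelse(is.na(sites$name), ".", sites$name),
    score = ifelse(is.na(sites$motif_score), "0",
      format(sites$motif_score, scientific = FALSE, trim = TRUE)
    ),
    strand = sites$strand
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

make_site_id <- function(chrom, start, end, strand) {
  paste0(chrom, ":", start, "-", end, ":", strand)
}

#' Read a per-site score table
#'
#' Reads a TSV (with header) of per-site raw binding scores, one row per
#' candidate motif site. Site coordinates are taken from `chrom`, `start`,
#' `end` and (optionally) `strand` columns; score columns are named
#' explicitly per condition. The bound condition must have exactly two
#' replicate columns; the unbound condition one or two — the reproducibility
#' model needs a replicate pair on the bound side, while the unbound side
#' only contributes a mean rank.
#'
#' Rows with a missing value in any score column are excluded from model
#' fitting downstream but are retained here, flagged in the `complete`
#' column; a message reports how many were flagged.
#'
#' @param path TSV file with a header row.
#' @param bound Character vector of the two bound-condition replicate score
#'   columns (e.g. `c("K_rep1", "K_rep2")`).
#' @param unbound Character vector of one or two unbound-condition replicate
#'   score columns.
#' @return A tibble with site columns (`chrom`, `start`, `end`, `strand`,
#'   `site_id`), the score columns, and a logical `complete` column. The
#'   score-column mapping is stored in the `"score_cols"` attribute
#'   (`list(bound = ..., unbound = ...)`) so downstream verbs need no
#'   re-specification.
#' @export
read_score_table <- function(path, bound = c("K_rep1", "K_rep2"),
                             unbound = c("G_rep1", "G_rep2")) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  new_score_table(tab, bound = bound, unbound = unbound)
}

#' Construct a score table from an in-memory data frame
#'
#' Validates and annotates a data frame of per-site scores the same way
#' [read_score_table()] does for a TSV on disk.
#'
#' @param data Data frame with `chrom`, `start`, `end` (and optionally
#'   `strand`) plus the score columns.
#' @inheritParams read_score_table
#' @return See [read_score_table()].
#' @export
new_score_table <- function(data, bound = c("K_rep1", "K_rep2"),
                            unbound = c("G_rep1", "G_rep2")) {
  tab <- tibble::as_tibble(data)
  if (length(bound) != 2L) {
    stop("the bound condition requires exactly 2 replicate score columns; got ",
      length(bound),
      call. = FALSE
    )
  }
  if (!length(unbound) %in% c(1L, 2L)) {
    stop("the unbound condition requires 1 or 2 replicate score columns; got ",
      length(unbound),
      call. = FALSE
    )
  }
  needed <- c("chrom", "start", "end", bound, unbound)
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"strand" %in% names(tab)) tab$strand <- "."
  if (!"site_id" %in% names(tab)) {
    tab$site_id <- make_site_id(tab$chrom, tab$start, tab$end, tab$strand)
  }
  dup <- tab$site_id[duplicated(tab$site_id)]
  if (length(dup) > 0L) {
    stop("duplicate site_id: ", dup[1L], call. = FALSE)
  }
  score_mat <- as.matrix(tab[, c(bound, unbound)])
  if (!is.numeric(score_mat)) {
    stop("score columns must be numeric", call. = FALSE)
  }
  tab$complete <- rowSums(!is.finite(score_mat)) == 0L
  n_bad <- sum(!tab$complete)
  if (n_bad > 0L) {
    message(n_bad, " site(s) with missing scores flagged; they are excluded ",
            "from model fitting and reported with NA probabilities")
  }
  tab <- dplyr::relocate(
    tab, "chrom", "start", "end", "strand", "site_id",
    dplyr::all_of(c(bound, unbound))
  )
  attr(tab, "score_cols") <- list(bound = bound, unbound = unbound)
  tab
}

#' Write a score table to TSV
#'
#' @param scores Tibble from [read_score_table()] / [new_score_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  cols <- score_cols(scores)
  out <- scores[, c("chrom", "start", "end", "strand", cols$bound, cols$unbound)]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

score_cols <- function(scores) {
  cols <- attr(scores, "score_cols", exact = TRUE)
  if (is.null(cols)) {
    stop("not a score table: missing the \"score_cols\" attribute; ",
      "use read_score_table() or new_score_table()",
      call. = FALSE
    )
  }
  cols
}
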