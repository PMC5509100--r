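#' Agreement stopping rule over a ranked differential list
#'
#' Walks down the multi-condition peak caller's ordered differential list
#' and, at each rank, computes the proportion of sites in a trailing window
#' that are also called differential by the independent count test. The
#' walk stops the first time this local agreement drops below
#' (max proportion seen so far) / 1.6; sites from that rank on are excluded.
#' If agreement never drops below the threshold the whole list is kept
#' (including the degenerate no-agreement case, where the threshold is 0).
#'
#' @param in_edger_set Logical vector in `gem_rank` order (position 1 = most
#'   differential by the multi-condition caller): whether each site is also
#'   in the count-test differential set.
#' @param local_window Trailing window length for the local proportion
#'   (default 200 sites).
#' @return The cutoff rank: sites with rank `<= cutoff` are retained. The
#'   trailing proportions are attached as attribute `"proportions"`.
#' @examples
#' agreement_cutoff(c(TRUE, TRUE, TRUE, FALSE, FALSE), local_window = 2)
#' @export
agreement_cutoff <- function(in_edger_set, local_window = 200L) {
  m <- length(in_edger_set)
  local_window <- as.integer(local_window)
  if (m < local_window) {
    stop("need at least local_window (", local_window, ") sites; got ", m,
      call. = FALSE
    )
  }
  x <- as.numeric(in_edger_set)
  cs <- cumsum(x)
  idx <- seq_len(m)
  lo <- pmax(idx - local_window, 0L)
  prop <- (cs - c(0, cs)[lo + 1L]) / pmin(idx, local_window)
  running_max <- cummax(prop)
  drop_at <- which(prop < running_max / 1.6)
  cutoff <- if (length(drop_at) == 0L) {
    message("agreement proportion never dropped below max/1.6; keeping all ",
            m, " sites")
    m
  } else {
    drop_at[1L] - 1L
  }
  structure(cutoff, proportions = prop)
}

#' Threshold filter for high-confidence differential events
#'
#' Given per-site statistics from the two upstream tools — the
#' multi-condition peak caller's per-condition q-values (carried as
#' `-log10 Q`) and the count test's p-value — keeps exactly the sites that
#' are differential by the count test and show the asymmetric peak-caller
#' signal expected of a site bound in the bound condition only. All four
#' inequalities are strict:
#'
#' * `p_edger < 0.05` — count-test differential;
#' * `q1 < 2.5` — insignificant in the unbound condition (`q1 = -log10 Q1`);
#' * `q2 > 2.5` — significant in the bound condition (`q2 = -log10 Q2`);
#' * `q2 - q1 > 0.5` — a reasonably large significance difference.
#'
#' @param stats Tibble with columns `site_id`, `q1`, `q2`, `p_edger`
#'   (extra columns pass through).
#' @return The surviving rows, with logical trace columns `pass_p`,
#'   `pass_q1`, `pass_q2`, `pass_qdiff` retained on the full input attached
#'   as attribute `"trace"`.
#' @export
threshold_filter <- function(stats) {
  needed <- c("site_id", "q1", "q2", "p_edger")
  missing_cols <- setdiff(needed, names(stats))
  if (length(missing_cols) > 0L) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  trace <- dplyr::mutate(
    tibble::as_tibble(stats),
    pass_p = .data$p_edger < 0.05,
    pass_q1 = .data$q1 < 2.5,
    pass_q2 = .data$q2 > 2.5,
    pass_qdiff = (.data$q2 - .data$q1) > 0.5
  )
  out <- dplyr::filter(
    trace,
    .data$pass_p & .data$pass_q1 & .data$pass_q2 & .data$pass_qdiff
  )
  attr(out, "trace") <- trace
  out
}

#' Match differential events to candidate motif sites
#'
#' The final ground-truth step: a differential event (e.g. a ChIP-seq peak)
#' is kept only if its center lies within `max_dist` bp of the center of a
#' candidate motif site, and the truth label is attached to that motif
#' site's `site_id`. The nearest motif wins; an exact distance tie is broken
#' deterministically by motif `site_id` with a warning.
#'
#' @param events Tibble of events with `chrom`, `start`, `end` (BED
#'   half-open coordinates).
#' @param motifs Tibble of candidate sites as from [read_sites_bed()]
#'   (`chrom`, `start`, `end`, `site_id`).
#' @param max_dist Maximum center-to-center distance in bp (default 20).
#' @return A tibble of truth labels over *all* motif sites: `site_id`,
#'   `label` (`"differential"` for matched motifs, `"non_differential"`
#'   otherwise), and for matched motifs the matched event's center and the
#'   distance.
#' @export
match_to_motifs <- function(events, motifs, max_dist = 20) {
  e_center <- (events$start + events$end) / 2
  m_center <- (motifs$start + motifs$end) / 2

  matched <- rep(NA_character_, nrow(events))
  match_dist <- rep(NA_real_, nrow(events))
  tie_seen <- FALSE
  for (ch in unique(events$chrom)) {
    ei <- which(events$chrom == ch)
    mi <- which(motifs$chrom == ch)
    if (length(mi) == 0L) next
    mc <- m_center[mi]
    ord <- order(mc, motifs$site_id[mi])
    mc <- mc[ord]
    ids <- motifs$site_id[mi][ord]
    pos <- findInterval(e_center[ei], mc)
    for (k in seq_along(ei)) {
      cand <- unique(pmin(pmax(c(pos[k], pos[k] + 1L), 1L), length(mc)))
      dist <- abs(mc[cand] - e_center[ei[k]])
      best <- which(dist == min(dist))
      if (length(best) > 1L) {
        tie_seen <- TRUE
        best <- best[order(ids[cand][best])][1L]
      }
      if (dist[best] <= max_dist) {
        matched[ei[k]] <- ids[cand][best]
        match_dist[ei[k]] <- dist[best]
      }
    }
  }
  if (tie_seen) {
    warning("equal-distance motif matches resolved by site_id order",
      call. = FALSE
    )
  }
  hits <- tibble::tibble(
    site_id = matched,
    event_center = e_center,
    match_dist = match_dist
  )
  hits <- dplyr::slice_min(
    dplyr::group_by(dplyr::filter(hits, !is.na(.data$site_id)), .data$site_id),
    .data$match_dist,
    n = 1, with_ties = FALSE
  )
  out <- dplyr::left_join(
    tibble::tibble(site_id = motifs$site_id),
    dplyr::ungroup(hits),
    by = "site_id"
  )
  out$label <- ifelse(is.na(out$event_center), "non_differential", "differential")
  out <- dplyr::relocate(out, "site_id", "label")
  attr(out, "event_matched") <- !is.na(matched)
  out
}

#' Build the ground-truth differential set from statistics tables
#'
#' Composes the three algorithmic ground-truth stages in their fixed order —
#' agreement stopping rule, threshold filter, motif-proximity matching —
#' each stage only removing sites. The input is the per-site statistics
#' table produced upstream (peak-caller q-values per condition, count-test
#' p-values, the caller's differential ordering) plus event coordinates;
#' the upstream tools themselves are not run here.
#'
#' @param stats Tibble with `site_id`, `gem_rank` (1 = most differential),
#'   `q1`, `q2`, `p_edger`, and event coordinates `chrom`, `start`, `end`.
#' @param motifs Candidate motif sites (as from [read_sites_bed()]), or
#'   `NULL` to skip the proximity stage.
#' @param local_window Trailing window for [agreement_cutoff()].
#' @param max_dist Center-to-center matching distance for
#'   [match_to_motifs()].
#' @return A list with `labels` (tibble `site_id`, `label` over the motif
#'   sites when `motifs` is given, else over the surviving events), `trace`
#'   (per input site: which stages it passed) and `cutoff_rank`.
#' @export
build_truth_set <- function(stats, motifs = NULL, local_window = 200L,
                            max_dist = 20) {
  stats <- dplyr::arrange(tibble::as_tibble(stats), .data$gem_rank)
  stats$in_edger_set <- stats$p_edger < 0.05

  cutoff <- agreement_cutoff(stats$in_edger_set, local_window = local_window)
  stage1 <- dplyr::filter(stats, .data$gem_rank <= as.integer(cutoff))
  stage2 <- threshold_filter(stage1)

  trace <- dplyr::mutate(
    stats,
    pass_agreement = .data$gem_rank <= as.integer(cutoff),
    pass_thresholds = .data$site_id %in% stage2$site_id
  )

  if (!is.null(motifs)) {
    labels <- match_to_motifs(stage2, motifs, max_dist = max_dist)
    trace$matched_motif <- FALSE
    trace$matched_motif[match(stage2$site_id, trace$site_id)] <-
      attr(labels, "event_matched")
  } else {
    labels <- tibble::tibble(
      site_id = stage2$site_id,
      label = "differential"
    )
  }
  list(labels = labels, trace = trace, cutoff_rank = as.integer(cutoff))
}
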