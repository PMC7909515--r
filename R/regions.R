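# Contig-level summaries: rolling-average score tracks, NCLDV calls at a
# score cutoff, marker-gene reports, and endogenous viral-region calling.

#' Region-calling parameters
#'
#' @param window rolling-window size in ORFs (default 15). Even values are
#'   incremented to the next odd number so the window can be centered.
#' @param cutoff score cutoff discriminating NCLDV from non-NCLDV (default
#'   0); calls and region membership use a strict `>`.
#' @param min_region_orfs minimum ORFs for a reported region (default 4),
#'   suppressing one-ORF noise regions.
#' @param require_gvog_hit drop regions containing no ORF with a GVOG best
#'   hit (default `TRUE`).
#' @return List of class `"region_params"`.
#' @export
region_params <- function(window = 15L, cutoff = 0, min_region_orfs = 4L,
                          require_gvog_hit = TRUE) {
  if (!is.numeric(window) || window < 1) stop("window must be >= 1")
  window <- as.integer(window)
  if (window %% 2L == 0L) {
    message("rolling window ", window, " is even; using ", window + 1L)
    window <- window + 1L
  }
  if (!is.numeric(min_region_orfs) || min_region_orfs < 1) {
    stop("min_region_orfs must be >= 1")
  }
  structure(list(window = window, cutoff = cutoff,
                 min_region_orfs = as.integer(min_region_orfs),
                 require_gvog_hit = isTRUE(require_gvog_hit)),
            class = "region_params")
}

#' Centered rolling average of per-ORF scores
#'
#' Mean over a centered window of half-width `floor(window / 2)`, truncated
#' at the contig edges (the mean is taken over the neighbors that exist), so
#' the output has the same length as the input.
#'
#' @param scores numeric vector of per-ORF final scores, in ordinal order.
#' @param window window size in ORFs; even values are incremented to the
#'   next odd number.
#' @return Numeric vector of windowed scores, same length as `scores`.
#' @export
rolling_average <- function(scores, window = 15L) {
  if (!is.numeric(window) || window < 1) stop("window must be >= 1")
  n <- length(scores)
  if (n == 0L) return(numeric(0))
  window <- as.integer(window)
  if (window %% 2L == 0L) {
    message("rolling window ", window, " is even; using ", window + 1L)
    window <- window + 1L
  }
  half <- window %/% 2L
  cs <- c(0, cumsum(scores))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Classify a contig by its mean score
#'
#' `"NCLDV"` iff the mean score strictly exceeds the cutoff; a mean exactly
#' at the cutoff is `"NON_NCLDV"`.
#'
#' @param mean_score contig mean of raw per-ORF final scores.
#' @param cutoff score cutoff (default 0).
#' @return Character vector, `"NCLDV"` or `"NON_NCLDV"`.
#' @export
classify_contig <- function(mean_score, cutoff = 0) {
  ifelse(mean_score > cutoff, "NCLDV", "NON_NCLDV")
}

marker_of_profile <- function(profile_ids, db) {
  gmeta <- db[db$database == "GVOG", ]
  gmeta$marker_name[match(profile_ids, gmeta$profile_id)]
}

format_markers <- function(counts) {
  nz <- counts[counts > 0]
  if (length(nz) == 0L) return(".")
  paste(sprintf("%s:%d", names(nz), nz), collapse = ",")
}

#' Call endogenous viral regions from the rolling score track
#'
#' A region is a maximal run of consecutive ORFs whose rolling-average score
#' strictly exceeds the cutoff. Runs shorter than `min_region_orfs` are
#' dropped, as are (optionally) runs containing no GVOG best hit. Nucleotide
#' coordinates span the start of the first ORF to the end of the last
#' (1-based inclusive); the region mean is over raw (unsmoothed) scores.
#'
#' @param scores per-ORF score table from [score_all_orfs()]; may contain
#'   several contigs.
#' @param params a [region_params()] object.
#' @param db optional profile metadata for marker reporting.
#' @return `data.frame` with one row per region: `contig_id`,
#'   `first_ordinal`, `last_ordinal`, `start`, `end`, `length_bp`, `n_orfs`,
#'   `mean_score`, `markers`.
#' @export
call_viral_regions <- function(scores, params = region_params(), db = NULL) {
  empty <- data.frame(
    contig_id = character(), first_ordinal = integer(),
    last_ordinal = integer(), start = integer(), end = integer(),
    length_bp = integer(), n_orfs = integer(), mean_score = numeric(),
    markers = character(), stringsAsFactors = FALSE)
  if (nrow(scores) == 0L) return(empty)
  out <- list()
  for (ctg in unique(scores$contig_id)) {
    sc <- scores[scores$contig_id == ctg, , drop = FALSE]
    sc <- sc[order(sc$ordinal), , drop = FALSE]
    if (!identical(sc$ordinal, seq_len(nrow(sc)))) {
      stop("score table for contig '", ctg,
           "' is not a complete ordinal sequence")
    }
    roll <- rolling_average(sc$s_final, params$window)
    pos <- roll > params$cutoff
    if (!any(pos)) next
    r <- rle(pos)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i1 <- starts[k]; i2 <- ends[k]
      if (i2 - i1 + 1L < params$min_region_orfs) next
      run <- sc[i1:i2, , drop = FALSE]
      has_gvog <- !is.na(run$gvog_profile)
      if (params$require_gvog_hit && !any(has_gvog)) next
      if (!is.null(db)) {
        mk <- marker_of_profile(run$gvog_profile[has_gvog], db)
        counts <- table(factor(mk[!is.na(mk)], levels = GV_MARKERS))
        markers <- format_markers(as.integer(counts) |>
                                    stats::setNames(GV_MARKERS))
      } else {
        markers <- "."
      }
      out[[length(out) + 1L]] <- data.frame(
        contig_id = ctg,
        first_ordinal = run$ordinal[1L],
        last_ordinal = run$ordinal[nrow(run)],
        start = run$start[1L],
        end = run$end[nrow(run)],
        length_bp = run$end[nrow(run)] - run$start[1L] + 1L,
        n_orfs = nrow(run),
        mean_score = mean(run$s_final),
        markers = markers,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Marker-gene hit counts per contig
#'
#' Counts, for each contig, the ORFs whose best GVOG hit is one of the ten
#' NCLDV marker families. Best-hit identity avoids double counting: an ORF
#' contributes to a marker only if the marker profile is its best GVOG hit.
#'
#' @param scores per-ORF score table from [score_all_orfs()].
#' @param db profile metadata with marker flags.
#' @return `data.frame` with `contig_id` and one integer column per marker
#'   in [GV_MARKERS]; absent markers are 0.
#' @export
report_markers <- function(scores, db) {
  contigs <- unique(scores$contig_id)
  mk <- marker_of_profile(scores$gvog_profile, db)
  tab <- table(factor(scores$contig_id, levels = contigs),
               factor(mk, levels = GV_MARKERS))
  out <- data.frame(contig_id = contigs, stringsAsFactors = FALSE)
  for (m in GV_MARKERS) out[[m]] <- as.integer(tab[, m])
  out
}

#' Per-contig summary with NCLDV call
#'
#' The contig mean is the mean of the raw per-ORF final scores (not of the
#' rolling track, which differs at the edges).
#'
#' @param scores per-ORF score table from [score_all_orfs()].
#' @param db profile metadata (for marker counts).
#' @param params a [region_params()] object.
#' @param contig_lengths optional named vector of contig lengths in bp; when
#'   absent, the end of the last ORF is used.
#' @param with_regions also count regions per contig (default `TRUE`).
#' @return `data.frame` with `contig_id`, `length_bp`, `n_orfs`,
#'   `mean_score`, `call`, `n_regions`, `markers`.
#' @export
contig_summary <- function(scores, db, params = region_params(),
                           contig_lengths = NULL, with_regions = TRUE) {
  contigs <- unique(scores$contig_id)
  regions <- if (with_regions) call_viral_regions(scores, params, db) else NULL
  marks <- report_markers(scores, db)
  rows <- lapply(contigs, function(ctg) {
    sc <- scores[scores$contig_id == ctg, , drop = FALSE]
    len <- if (!is.null(contig_lengths) && ctg %in% names(contig_lengths)) {
      as.integer(contig_lengths[[ctg]])
    } else {
      max(sc$end)
    }
    mrow <- marks[marks$contig_id == ctg, GV_MARKERS, drop = FALSE]
    counts <- stats::setNames(as.integer(mrow[1L, ]), GV_MARKERS)
    data.frame(
      contig_id = ctg,
      length_bp = len,
      n_orfs = nrow(sc),
      mean_score = mean(sc$s_final),
      call = classify_contig(mean(sc$s_final), params$cutoff),
      n_regions = if (is.null(regions)) NA_integer_ else
        sum(regions$contig_id == ctg),
      markers = format_markers(counts),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Export regions as BED
#'
#' Converts the 1-based inclusive region coordinates to BED's 0-based
#' half-open convention; the score column carries the region mean.
#'
#' @param regions table from [call_viral_regions()].
#' @param path output BED file.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$contig_id,
                    chromStart = regions$start - 1L,
                    chromEnd = regions$end,
                    name = sprintf("%s:%d-%d", regions$contig_id,
                                   regions$first_ordinal,
                                   regions$last_ordinal),
                    score = round(regions$mean_score, 3),
                    strand = ".")
  write_tsv_atomic(bed, path, col.names = FALSE)
}

#' Plot the rolling score track of one contig
#'
#' Raw per-ORF scores as points, the rolling average as a line, and the
#' cutoff as a horizontal reference.
#'
#' @param scores per-ORF score table.
#' @param contig_id contig to plot.
#' @param params a [region_params()] object.
#' @param file optional PNG path; when `NULL`, plots to the active device.
#' @export
plot_score_track <- function(scores, contig_id, params = region_params(),
                             file = NULL) {
  sc <- scores[scores$contig_id == contig_id, , drop = FALSE]
  if (nrow(sc) == 0L) stop("no ORFs for contig '", contig_id, "'")
  sc <- sc[order(sc$ordinal), ]
  roll <- rolling_average(sc$s_final, params$window)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 300)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(sc$ordinal, sc$s_final, pch = 16, cex = 0.5,
                 col = "grey60", xlab = "ORF ordinal",
                 ylab = "score", main = contig_id)
  graphics::lines(sc$ordinal, roll, col = "firebrick", lwd = 2)
  graphics::abline(h = params$cutoff, lty = 2)
  invisible(roll)
}
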