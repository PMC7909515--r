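# End-to-end drivers: score a genome's ORFs from its search tables and
# write the standard outputs, or run the synthetic benchmark.

#' Run the detection pipeline on one genome
#'
#' Reads gene-caller proteins (for ORF coordinates) and the GVOG/Pfam
#' search tables, selects best hits at the e-value cutoff, scores every
#' ORF, and writes the per-ORF score table, contig summary, viral regions
#' (TSV and BED), marker report and a run log to `output_dir`. Outputs are
#' written atomically, so a rerun with the same inputs is byte-identical.
#'
#' @param proteins_faa protein FASTA with gene-caller coordinate headers.
#' @param gvog_table,pfam_table per-domain search tables against the GVOG
#'   and Pfam databases.
#' @param db profile metadata: a [profile_db()] table or a path readable by
#'   [read_profile_db()].
#' @param output_dir directory for outputs (created if needed).
#' @param window rolling-window size in ORFs (default 15).
#' @param evalue_max hit e-value cutoff (default `1e-5`).
#' @param cutoff classification score cutoff (default 0).
#' @param contig_level suppress the rolling track and region calling,
#'   reporting contig means only (default `FALSE`).
#' @param min_region_orfs,require_gvog_hit region filters, see
#'   [region_params()].
#' @param eq1_variant GVOG-reward variant, see [score_params()].
#' @param contig_lengths optional named vector of true contig lengths.
#' @param plots write a PNG score track per contig (default `FALSE`).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `scores`, `summary`, `regions`,
#'   `markers` and the output paths.
#' @export
run_detect <- function(proteins_faa, gvog_table, pfam_table, db, output_dir,
                       window = 15L, evalue_max = 1e-5, cutoff = 0,
                       contig_level = FALSE, min_region_orfs = 4L,
                       require_gvog_hit = TRUE,
                       eq1_variant = c("ratio", "literal"),
                       contig_lengths = NULL, plots = FALSE, quiet = FALSE) {
  eq1_variant <- match.arg(eq1_variant)
  if (is.character(db)) db <- read_profile_db(db)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- score_params(evalue_max = evalue_max, eq1_variant = eq1_variant)
  rp <- suppressMessages(
    region_params(window = window, cutoff = cutoff,
                  min_region_orfs = min_region_orfs,
                  require_gvog_hit = require_gvog_hit))

  orfs <- parse_orf_headers(proteins_faa)
  hits <- rbind(parse_search_table(gvog_table, "GVOG"),
                parse_search_table(pfam_table, "PFAM"))
  best <- best_hit_per_orf(hits, evalue_max)
  scores <- score_all_orfs(orfs, best, db, sp)

  regions <- if (contig_level) NULL else call_viral_regions(scores, rp, db)
  summary <- contig_summary(scores, db, rp, contig_lengths,
                            with_regions = !contig_level)
  markers <- report_markers(scores, db)

  paths <- list(scores = file.path(output_dir, "orf_scores.tsv"),
                summary = file.path(output_dir, "contig_summary.tsv"),
                markers = file.path(output_dir, "markers.tsv"),
                log = file.path(output_dir, "run.log"))
  write_score_table(scores, paths$scores)
  write_tsv_atomic(summary, paths$summary)
  write_tsv_atomic(markers, paths$markers)
  if (!is.null(regions)) {
    paths$regions <- file.path(output_dir, "regions.tsv")
    paths$bed <- file.path(output_dir, "regions.bed")
    write_tsv_atomic(regions, paths$regions)
    write_regions_bed(regions, paths$bed)
  }
  if (plots && !contig_level) {
    for (ctg in unique(scores$contig_id)) {
      plot_score_track(scores, ctg, rp,
                       file = file.path(output_dir,
                                        paste0("track_", ctg, ".png")))
    }
  }
  log_lines <- c(
    paste0("gvscan ", as.character(utils::packageVersion("gvscan"))),
    paste0("proteins: ", proteins_faa),
    paste0("gvog_table: ", gvog_table),
    paste0("pfam_table: ", pfam_table),
    sprintf("params: window=%d evalue_max=%g cutoff=%g contig_level=%s eq1_variant=%s min_region_orfs=%d require_gvog_hit=%s",
            rp$window, evalue_max, cutoff, contig_level, eq1_variant,
            rp$min_region_orfs, rp$require_gvog_hit),
    sprintf("counts: %d contigs, %d ORFs, %d hits (%d best), %d regions",
            length(unique(orfs$contig_id)), nrow(orfs), nrow(hits),
            nrow(best), if (is.null(regions)) 0L else nrow(regions)))
  writeLines(log_lines, paths$log)
  if (!quiet) message(paste(log_lines, collapse = "\n"))
  invisible(list(scores = scores, summary = summary, regions = regions,
                 markers = markers, paths = paths))
}

#' Synthetic benchmark: specificity and sensitivity at the cutoff
#'
#' Builds a synthetic profile database plus labelled genomes (NCLDV
#' positives, phage and cellular negatives), shreds the negatives into
#' pseudocontigs, classifies every item by its mean score at the cutoff,
#' and reports confusion counts with specificity and sensitivity.
#' Deterministic given `seed`.
#'
#' @param seed master integer seed.
#' @param n_per_class genomes per class (default 2).
#' @param n_orfs ORFs per genome (default 150).
#' @param frag_min,frag_max pseudocontig length bounds in bp.
#' @param cutoff classification cutoff (default 0).
#' @param spec optional [fixture_spec()] (its seed is replaced by `seed`).
#' @param output_dir optional directory for a metrics TSV and per-item
#'   table.
#' @return List with `counts` (confusion counts), `specificity`,
#'   `sensitivity`, `items` (per-item table: id, truth, n_orfs,
#'   mean_score, call) and `class_means` (mean item score per truth class).
#' @export
run_benchmark <- function(seed = 1L, n_per_class = 2L, n_orfs = 150L,
                          frag_min = 5000L, frag_max = 25000L, cutoff = 0,
                          spec = NULL, output_dir = NULL) {
  if (is.null(spec)) spec <- fixture_spec(seed = seed)
  else spec$seed <- as.integer(seed)
  made <- make_profile_db(spec)
  db <- made$db
  sp <- score_params()

  items <- list()
  add_item <- function(id, truth, scores) {
    items[[length(items) + 1L]] <<- data.frame(
      id = id, truth = truth, n_orfs = nrow(scores),
      mean_score = mean(scores$s_final),
      call = classify_contig(mean(scores$s_final), cutoff),
      stringsAsFactors = FALSE)
  }

  classes <- c(rep("NCLDV", n_per_class), rep("PHAGE", n_per_class),
               rep("CELLULAR", n_per_class))
  for (g in seq_along(classes)) {
    cls <- classes[g]
    gen <- make_genome(cls, n_orfs, spec, db,
                       contig_id = sprintf("%s_g%02d", tolower(cls), g),
                       seed = derive_seed(seed, 10L + g))
    best <- best_hit_per_orf(gen$hits, sp$evalue_max)
    if (cls == "NCLDV") {
      scores <- score_all_orfs(gen$orfs, best, db, sp)
      add_item(gen$contig_id, "NCLDV", scores)
    } else {
      frags <- shred(gen$contig_id, gen$contig_length, frag_min, frag_max,
                     seed = derive_seed(seed, 100L + g))
      forfs <- assign_orfs_to_fragments(frags, gen$orfs)
      if (nrow(forfs) == 0L) next
      fbest <- best
      fbest <- fbest[fbest$orf_id %in% forfs$source_orf_id, , drop = FALSE]
      fbest$orf_id <- forfs$orf_id[match(fbest$orf_id, forfs$source_orf_id)]
      fscores <- score_all_orfs(forfs[, names(forfs) != "source_orf_id"],
                                fbest, db, sp)
      for (fid in unique(fscores$contig_id)) {
        add_item(fid, cls, fscores[fscores$contig_id == fid, , drop = FALSE])
      }
    }
  }
  items <- do.call(rbind, items)
  rownames(items) <- NULL

  truth_binary <- ifelse(items$truth == "NCLDV", "NCLDV", "OTHER")
  counts <- confusion_counts(truth_binary, items$call)
  spec_pct <- if (counts$n_negatives > 0)
    specificity(counts$n_negatives, counts$n_false_pos) else NA_real_
  sens_pct <- if (counts$n_positives > 0)
    sensitivity(counts$n_positives, counts$n_false_neg) else NA_real_
  class_means <- tapply(items$mean_score, items$truth, mean)

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_atomic(items, file.path(output_dir, "benchmark_items.tsv"))
    metrics <- data.frame(
      n_negatives = counts$n_negatives, n_false_pos = counts$n_false_pos,
      n_positives = counts$n_positives, n_false_neg = counts$n_false_neg,
      specificity = spec_pct, sensitivity = sens_pct)
    write_tsv_atomic(metrics, file.path(output_dir, "benchmark_metrics.tsv"))
  }
  list(counts = counts, specificity = spec_pct, sensitivity = sens_pct,
       items = items, class_means = class_means)
}
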