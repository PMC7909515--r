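# Synthetic-fixture generator. Fabricates profile metadata, occurrence
# surveys, genomes, ORF layouts and profile-search tables with planted class
# structure so the whole pipeline can be exercised with no external binaries
# or reference databases. Fixtures plant search RESULTS (bit scores), not
# sequences that genuinely match profiles.
#
# The planted bit-score and occurrence bands are chosen so the sign of each
# scored ORF is certain, not merely likely:
#   * NCLDV ORFs hit NCLDV-specific GVOGs (p_caudo = 0) at B in [80, 200];
#     any accompanying Pfam hit is NCLDV-common (p_ncldv >= 0.5,
#     p_caudo <= 0.1) at B in [20, 60], so reward - penalty >= sqrt(80) -
#     sqrt(30.2) > 3 on every hit ORF.
#   * Phage ORFs with a shared-GVOG hit (p_ncldv <= p_caudo, ratio <= 1/2,
#     B <= 150) always also carry a phage-common Pfam hit (p_caudo >= 0.5,
#     B >= 60, penalty >= 60 + 0.5/0.01 = 110), so every hit ORF is
#     negative: sqrt(75) - sqrt(110) < 0.
#   * Cellular ORFs only hit normalization-ineligible Pfams, so their
#     penalty is the raw bit score.
# ORFs without hits score exactly 0 and contigs are called NCLDV only on a
# strictly positive mean, so class separation survives shredding.

#' Fixture-generation settings
#'
#' @param seed master integer seed; every random draw in the generator flows
#'   from it through one stream per product.
#' @param n_gvogs number of GVOG profiles (>= 20; the first ten are the
#'   marker families).
#' @param n_pfams number of Pfam profiles (>= 10).
#' @param n_survey_ncldv,n_survey_caudo genomes per class in the synthetic
#'   occurrence survey; occurrence proportions are exact multiples of the
#'   class size so metadata and survey agree exactly.
#' @param orf_length_bp mean gene length in bp.
#' @param intergenic_bp mean spacer between genes in bp.
#' @return List of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, n_gvogs = 60L, n_pfams = 40L,
                         n_survey_ncldv = 20L, n_survey_caudo = 20L,
                         orf_length_bp = 900L, intergenic_bp = 120L) {
  if (n_gvogs < 20L) stop("n_gvogs must be >= 20")
  if (n_pfams < 10L) stop("n_pfams must be >= 10")
  structure(list(seed = as.integer(seed), n_gvogs = as.integer(n_gvogs),
                 n_pfams = as.integer(n_pfams),
                 n_survey_ncldv = as.integer(n_survey_ncldv),
                 n_survey_caudo = as.integer(n_survey_caudo),
                 orf_length_bp = as.integer(orf_length_bp),
                 intergenic_bp = as.integer(intergenic_bp)),
            class = "fixture_spec")
}

# Draw occurrence proportions as k/n so they are exactly representable in a
# presence matrix over n genomes.
grid_prop <- function(rng, n, k_lo, k_hi, size = 1L) {
  k <- rng$sample(seq.int(k_lo, k_hi), size, replace = TRUE)
  k / n
}

#' Fabricate a profile database with a matching occurrence survey
#'
#' Emits three GVOG strata (NCLDV-specific, shared with Caudovirales, rare)
#' and three Pfam strata (NCLDV-common, phage-common, cellular-only), with
#' the first ten GVOGs flagged as the marker families. The returned
#' presence matrix reproduces the metadata proportions exactly.
#'
#' @param spec a [fixture_spec()].
#' @return List with `db` (a [profile_db()] table carrying an extra
#'   `stratum` column) and `occurrence` (an [occurrence_matrix()]).
#' @export
make_profile_db <- function(spec) {
  rng <- local_rng(derive_seed(spec$seed, 1L))
  nn <- spec$n_survey_ncldv
  nc <- spec$n_survey_caudo

  n_marker <- 10L
  n_rest <- spec$n_gvogs - n_marker
  n_specific <- max(1L, round(0.5 * n_rest))
  n_shared <- max(1L, round(0.3 * n_rest))
  n_rare <- n_rest - n_specific - n_shared

  gvog_ids <- sprintf("GVOG%04d", seq_len(spec$n_gvogs))
  g_stratum <- c(rep("marker", n_marker), rep("specific", n_specific),
                 rep("shared", n_shared), rep("rare", n_rare))
  g_pn <- numeric(spec$n_gvogs)
  g_pc <- numeric(spec$n_gvogs)
  g_pn[g_stratum == "marker"] <-
    grid_prop(rng, nn, ceiling(0.7 * nn), nn - 1L, n_marker)
  g_pn[g_stratum == "specific"] <-
    grid_prop(rng, nn, ceiling(0.5 * nn), nn - 1L, n_specific)
  # shared families: at least as common in Caudovirales as in NCLDV, so the
  # ratio normalization halves (or worse) their reward
  kc <- rng$sample(seq.int(ceiling(0.4 * nc), ceiling(0.6 * nc)),
                   n_shared, replace = TRUE)
  kn <- vapply(kc, function(k)
    rng$sample(seq.int(ceiling(0.2 * nn), k), 1L), integer(1L))
  g_pc[g_stratum == "shared"] <- kc / nc
  g_pn[g_stratum == "shared"] <- kn / nn
  if (n_rare > 0L) {
    g_pn[g_stratum == "rare"] <- grid_prop(rng, nn, 1L, max(1L, nn %/% 10L),
                                           n_rare)
  }

  n_pf_ncldv <- max(1L, round(0.3 * spec$n_pfams))
  n_pf_phage <- max(1L, round(0.3 * spec$n_pfams))
  n_pf_cell <- spec$n_pfams - n_pf_ncldv - n_pf_phage
  pfam_ids <- sprintf("PF%05d", seq_len(spec$n_pfams))
  p_stratum <- c(rep("ncldv_common", n_pf_ncldv),
                 rep("phage_common", n_pf_phage),
                 rep("cellular", n_pf_cell))
  p_pn <- numeric(spec$n_pfams)
  p_pc <- numeric(spec$n_pfams)
  p_pn[p_stratum == "ncldv_common"] <-
    grid_prop(rng, nn, ceiling(0.5 * nn), nn, n_pf_ncldv)
  p_pc[p_stratum == "ncldv_common"] <-
    grid_prop(rng, nc, 0L, max(0L, nc %/% 10L), n_pf_ncldv)
  p_pc[p_stratum == "phage_common"] <-
    grid_prop(rng, nc, ceiling(0.5 * nc), nc, n_pf_phage)

  annotations <- c("DNA polymerase", "helicase", "capsid protein",
                   "transcription factor", "kinase", "membrane protein",
                   NA_character_)
  db <- profile_db(
    profile_id = c(gvog_ids, pfam_ids),
    database = c(rep("GVOG", spec$n_gvogs), rep("PFAM", spec$n_pfams)),
    p_ncldv = c(g_pn, p_pn),
    p_caudo = c(g_pc, p_pc),
    annotation = annotations[rng$sample(length(annotations),
                                        spec$n_gvogs + spec$n_pfams,
                                        replace = TRUE)],
    marker_name = c(GV_MARKERS, rep(NA_character_,
                                    spec$n_gvogs - n_marker + spec$n_pfams))
  )
  db$stratum <- c(g_stratum, p_stratum)

  genome_ids <- c(sprintf("ncldv_g%03d", seq_len(nn)),
                  sprintf("caudo_g%03d", seq_len(nc)))
  genome_class <- c(rep("NCLDV", nn), rep("CAUDOVIRALES", nc))
  presence <- matrix(FALSE, nrow = nn + nc, ncol = nrow(db),
                     dimnames = list(genome_ids, db$profile_id))
  for (j in seq_len(nrow(db))) {
    k_n <- round(db$p_ncldv[j] * nn)
    k_c <- round(db$p_caudo[j] * nc)
    if (k_n > 0L) presence[rng$sample(nn, k_n), j] <- TRUE
    if (k_c > 0L) presence[nn + rng$sample(nc, k_c), j] <- TRUE
  }
  list(db = db, occurrence = occurrence_matrix(presence, genome_class))
}

random_dna <- function(rng, n) {
  paste(rng$sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(rng, n) {
  paste(rng$sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n,
                   replace = TRUE), collapse = "")
}

# Lay out n non-overlapping, strand-alternating ORFs along a contig.
layout_orfs <- function(rng, contig_id, n_orfs, spec) {
  lens <- 3L * pmax(100L, as.integer(round(
    rng$rnorm(n_orfs, spec$orf_length_bp / 3, 40))))
  gaps <- rng$rpois(n_orfs, spec$intergenic_bp)
  starts <- integer(n_orfs)
  ends <- integer(n_orfs)
  pos <- 0L
  for (i in seq_len(n_orfs)) {
    starts[i] <- pos + gaps[i] + 1L
    ends[i] <- starts[i] + lens[i] - 1L
    pos <- ends[i]
  }
  data.frame(orf_id = sprintf("%s_%d", contig_id, seq_len(n_orfs)),
             contig_id = contig_id, ordinal = seq_len(n_orfs),
             start = starts, end = ends,
             strand = rep_len(c("+", "-"), n_orfs),
             stringsAsFactors = FALSE)
}

hit_row <- function(orf_id, profile_id, database, bitscore,
                    evalue = 10^-(bitscore / 5)) {
  data.frame(orf_id = orf_id, profile_id = profile_id, database = database,
             bitscore = round(bitscore, 1), evalue = evalue,
             stringsAsFactors = FALSE)
}

rbind_hits <- function(rows) {
  if (length(rows) == 0L) {
    return(data.frame(orf_id = character(), profile_id = character(),
                      database = character(), bitscore = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pool <- function(db, database, strata) {
  db$profile_id[db$database == database & db$stratum %in% strata]
}

#' Fabricate one genome of a given class, with its search results
#'
#' Produces a nucleotide contig, gene-caller-style proteins with coordinate
#' headers, and GVOG/Pfam search tables whose planted bit scores give the
#' class its expected score sign: NCLDV contigs end positive, phage and
#' cellular contigs non-positive (phage above cellular).
#'
#' @param class `"NCLDV"`, `"PHAGE"` or `"CELLULAR"`.
#' @param n_orfs number of ORFs (>= 1).
#' @param spec a [fixture_spec()].
#' @param db profile metadata from [make_profile_db()] (built from `spec`
#'   when omitted).
#' @param contig_id contig name.
#' @param seed seed for this genome (defaults to one derived from
#'   `spec$seed`).
#' @param dir when given, write `<contig>.fna`, `<contig>.faa`,
#'   `<contig>_gvog.tbl` and `<contig>_pfam.tbl` there.
#' @return List with `class`, `contig_id`, `contig_length`, `orfs`, `hits`,
#'   `proteins`, `nucleotide`, and (when `dir` is given) `paths`.
#' @export
make_genome <- function(class = c("NCLDV", "PHAGE", "CELLULAR"), n_orfs,
                        spec = fixture_spec(), db = NULL,
                        contig_id = paste0(tolower(class), "_ctg1"),
                        seed = derive_seed(spec$seed, 2L), dir = NULL) {
  class <- match.arg(class)
  if (n_orfs < 1L) stop("n_orfs must be >= 1")
  if (is.null(db)) db <- make_profile_db(spec)$db
  rng <- local_rng(seed)
  orfs <- layout_orfs(rng, contig_id, n_orfs, spec)

  marker_pool <- pool(db, "GVOG", "marker")
  specific_pool <- pool(db, "GVOG", c("marker", "specific"))
  shared_pool <- pool(db, "GVOG", "shared")
  pf_ncldv <- pool(db, "PFAM", "ncldv_common")
  pf_phage <- pool(db, "PFAM", "phage_common")
  pf_cell <- pool(db, "PFAM", "cellular")

  rows <- list()
  if (class == "NCLDV") {
    has_gvog <- rng$runif(n_orfs) < 0.75
    has_gvog[1L] <- TRUE  # guarantee at least one NCLDV signature
    for (i in which(has_gvog)) {
      prof <- if (i == 1L) rng$sample(marker_pool, 1L)
              else rng$sample(specific_pool, 1L)
      rows[[length(rows) + 1L]] <-
        hit_row(orfs$orf_id[i], prof, "GVOG", rng$runif(1L, 80, 200))
      if (rng$runif(1L) < 0.2) {
        rows[[length(rows) + 1L]] <-
          hit_row(orfs$orf_id[i], rng$sample(pf_ncldv, 1L), "PFAM",
                  rng$runif(1L, 20, 60))
      }
    }
  } else if (class == "PHAGE") {
    has_pfam <- rng$runif(n_orfs) < 0.6
    has_pfam[1L] <- TRUE
    for (i in which(has_pfam)) {
      rows[[length(rows) + 1L]] <-
        hit_row(orfs$orf_id[i], rng$sample(pf_phage, 1L), "PFAM",
                rng$runif(1L, 60, 150))
      if (rng$runif(1L) < 0.5) {
        rows[[length(rows) + 1L]] <-
          hit_row(orfs$orf_id[i], rng$sample(shared_pool, 1L), "GVOG",
                  rng$runif(1L, 60, 150))
      }
    }
  } else {
    has_pfam <- rng$runif(n_orfs) < 0.8
    has_pfam[1L] <- TRUE
    for (i in which(has_pfam)) {
      rows[[length(rows) + 1L]] <-
        hit_row(orfs$orf_id[i], rng$sample(pf_cell, 1L), "PFAM",
                rng$runif(1L, 60, 150))
    }
  }
  # sub-threshold decoys that the e-value filter must remove
  for (k in 1:2) {
    i <- rng$sample(n_orfs, 1L)
    dbn <- if (k == 1L) "GVOG" else "PFAM"
    prof <- rng$sample(db$profile_id[db$database == dbn], 1L)
    rows[[length(rows) + 1L]] <-
      hit_row(orfs$orf_id[i], prof, dbn, rng$runif(1L, 10, 25),
              evalue = 1e-3)
  }
  hits <- rbind_hits(rows)

  contig_length <- max(orfs$end) + rng$rpois(1L, spec$intergenic_bp)
  nucleotide <- random_dna(rng, contig_length)
  prot_len <- pmax(1L, (orfs$end - orfs$start + 1L) %/% 3L - 1L)
  proteins <- data.frame(
    id = sprintf("%s # %d # %d # %d # ID=%d", orfs$orf_id, orfs$start,
                 orfs$end, ifelse(orfs$strand == "+", 1L, -1L),
                 orfs$ordinal),
    sequence = vapply(prot_len, function(n) random_protein(rng, n),
                      character(1L)),
    stringsAsFactors = FALSE)

  out <- list(class = class, contig_id = contig_id,
              contig_length = contig_length, orfs = orfs, hits = hits,
              proteins = proteins, nucleotide = nucleotide)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fna = file.path(dir, paste0(contig_id, ".fna")),
      faa = file.path(dir, paste0(contig_id, ".faa")),
      gvog = file.path(dir, paste0(contig_id, "_gvog.tbl")),
      pfam = file.path(dir, paste0(contig_id, "_pfam.tbl")))
    write_fasta(data.frame(id = contig_id, sequence = nucleotide),
                paths$fna)
    write_fasta(proteins, paths$faa)
    write_search_table(hits[hits$database == "GVOG", ], paths$gvog)
    write_search_table(hits[hits$database == "PFAM", ], paths$pfam)
    out$paths <- paths
  }
  out
}

#' Fabricate a host genome carrying an endogenous viral region
#'
#' Host ORFs all hit cellular Pfam domains (negative scores); the ORFs of
#' `insert_span` instead hit NCLDV-specific GVOGs, the first of them a
#' marker family. The returned truth record carries the exact planted
#' bounds, against which region-caller recovery can be measured.
#'
#' @param host_n_orfs total ORFs on the host contig.
#' @param insert_span integer pair `c(first, last)` of planted ordinals, or
#'   `NULL` for an insert-free control.
#' @param spec a [fixture_spec()].
#' @param db profile metadata from [make_profile_db()].
#' @param contig_id contig name.
#' @param seed seed for this genome.
#' @param dir optional output directory, as in [make_genome()].
#' @return As [make_genome()], plus `truth`: `NULL` for controls, else a
#'   list with `first_ordinal`, `last_ordinal`, `start`, `end`.
#' @export
make_endogenized_genome <- function(host_n_orfs, insert_span,
                                    spec = fixture_spec(), db = NULL,
                                    contig_id = "host_ctg1",
                                    seed = derive_seed(spec$seed, 3L),
                                    dir = NULL) {
  if (!is.null(insert_span)) {
    if (length(insert_span) != 2L || insert_span[1L] > insert_span[2L] ||
        insert_span[1L] < 1L || insert_span[2L] > host_n_orfs) {
      stop("insert_span must be an ordered ordinal pair inside the host")
    }
  }
  if (is.null(db)) db <- make_profile_db(spec)$db
  rng <- local_rng(seed)
  orfs <- layout_orfs(rng, contig_id, host_n_orfs, spec)

  marker_pool <- pool(db, "GVOG", "marker")
  specific_pool <- pool(db, "GVOG", c("marker", "specific"))
  pf_cell <- pool(db, "PFAM", "cellular")

  inserted <- if (is.null(insert_span)) integer(0) else
    seq.int(insert_span[1L], insert_span[2L])
  rows <- list()
  for (i in seq_len(host_n_orfs)) {
    if (i %in% inserted) {
      prof <- if (i == inserted[1L]) rng$sample(marker_pool, 1L)
              else rng$sample(specific_pool, 1L)
      rows[[length(rows) + 1L]] <-
        hit_row(orfs$orf_id[i], prof, "GVOG", rng$runif(1L, 100, 200))
    } else {
      rows[[length(rows) + 1L]] <-
        hit_row(orfs$orf_id[i], rng$sample(pf_cell, 1L), "PFAM",
                rng$runif(1L, 60, 150))
    }
  }
  hits <- rbind_hits(rows)

  contig_length <- max(orfs$end) + rng$rpois(1L, spec$intergenic_bp)
  nucleotide <- random_dna(rng, contig_length)
  prot_len <- pmax(1L, (orfs$end - orfs$start + 1L) %/% 3L - 1L)
  proteins <- data.frame(
    id = sprintf("%s # %d # %d # %d # ID=%d", orfs$orf_id, orfs$start,
                 orfs$end, ifelse(orfs$strand == "+", 1L, -1L),
                 orfs$ordinal),
    sequence = vapply(prot_len, function(n) random_protein(rng, n),
                      character(1L)),
    stringsAsFactors = FALSE)

  truth <- if (is.null(insert_span)) NULL else
    list(first_ordinal = insert_span[1L], last_ordinal = insert_span[2L],
         start = orfs$start[insert_span[1L]], end = orfs$end[insert_span[2L]])

  out <- list(class = "HOST", contig_id = contig_id,
              contig_length = contig_length, orfs = orfs, hits = hits,
              proteins = proteins, nucleotide = nucleotide, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fna = file.path(dir, paste0(contig_id, ".fna")),
      faa = file.path(dir, paste0(contig_id, ".faa")),
      gvog = file.path(dir, paste0(contig_id, "_gvog.tbl")),
      pfam = file.path(dir, paste0(contig_id, "_pfam.tbl")))
    write_fasta(data.frame(id = contig_id, sequence = nucleotide),
                paths$fna)
    write_fasta(proteins, paths$faa)
    write_search_table(hits[hits$database == "GVOG", ], paths$gvog)
    write_search_table(hits[hits$database == "PFAM", ], paths$pfam)
    out$paths <- paths
  }
  out
}
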