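# Profile-family metadata: occurrence proportions in NCLDV vs Caudovirales
# genomes, functional annotations, and marker-gene membership.

#' The ten NCLDV marker gene families
#'
#' Conserved protein families used to corroborate NCLDV provenance: the five
#' markers commonly used in phylogenetic reconstruction (PolB, A32, VLTF3,
#' SFII, MCP) plus five families present in most NCLDV genomes (the two RNA
#' polymerase subunits, the mRNA capping enzyme, ribonucleotide reductase and
#' the D5 primase/helicase).
#'
#' @format Character vector of length 10.
#' @export
GV_MARKERS <- c("PolB", "A32", "VLTF3", "SFII", "MCP",
                "RNAPL", "RNAPS", "mRNAc", "RNR", "D5")

#' Construct a profile-metadata table
#'
#' One row per profile family. `p_ncldv` and `p_caudo` are the fractions of
#' surveyed NCLDV and Caudovirales genomes, respectively, that carry at least
#' one hit to the profile; they drive the score normalization.
#'
#' @param profile_id character vector of profile names, unique per database.
#' @param database `"GVOG"` or `"PFAM"`, recycled.
#' @param p_ncldv,p_caudo numeric fractions in `[0, 1]`.
#' @param annotation optional functional annotation (`NA` for none).
#' @param marker_name optional marker gene name from [GV_MARKERS] (`NA` for
#'   non-marker profiles); only GVOG profiles may carry one.
#' @return A `data.frame` with class `"profile_db"` and columns
#'   `profile_id`, `database`, `p_ncldv`, `p_caudo`, `annotation`,
#'   `marker_name`, `is_marker`.
#' @export
profile_db <- function(profile_id, database, p_ncldv, p_caudo,
                       annotation = NA_character_,
                       marker_name = NA_character_) {
  db <- data.frame(
    profile_id = as.character(profile_id),
    database = as.character(database),
    p_ncldv = as.numeric(p_ncldv),
    p_caudo = as.numeric(p_caudo),
    annotation = as.character(annotation),
    marker_name = as.character(marker_name),
    stringsAsFactors = FALSE
  )
  db$is_marker <- !is.na(db$marker_name)
  validate_profile_db(db)
  class(db) <- c("profile_db", "data.frame")
  db
}

validate_profile_db <- function(db) {
  stopifnot(is.data.frame(db))
  if (!all(db$database %in% c("GVOG", "PFAM"))) {
    stop("database must be 'GVOG' or 'PFAM'")
  }
  bad <- !is.finite(db$p_ncldv) | db$p_ncldv < 0 | db$p_ncldv > 1 |
    !is.finite(db$p_caudo) | db$p_caudo < 0 | db$p_caudo > 1
  if (any(bad)) {
    stop("occurrence proportions must lie in [0, 1]: ",
         paste(db$profile_id[bad], collapse = ", "))
  }
  if (anyDuplicated(paste(db$database, db$profile_id))) {
    stop("profile_id must be unique within a database")
  }
  mk <- !is.na(db$marker_name)
  if (any(mk & db$database != "GVOG")) {
    stop("marker profiles must belong to the GVOG database")
  }
  if (!all(db$marker_name[mk] %in% GV_MARKERS)) {
    stop("unknown marker_name: ",
         paste(setdiff(db$marker_name[mk], GV_MARKERS), collapse = ", "))
  }
  invisible(db)
}

#' Construct a genome-by-profile occurrence matrix
#'
#' Records, for a survey of genomes, whether each genome has at least one
#' profile hit (presence, not hit counts). Used to derive the occurrence
#' proportions stored in the profile metadata.
#'
#' @param presence logical matrix, genomes in rows, profiles in columns;
#'   dimnames give genome and profile ids.
#' @param genome_class character vector, `"NCLDV"` or `"CAUDOVIRALES"` per
#'   genome (row).
#' @return An object of class `"occurrence_matrix"`.
#' @export
occurrence_matrix <- function(presence, genome_class) {
  if (!is.matrix(presence) || !is.logical(presence)) {
    stop("presence must be a logical matrix")
  }
  if (is.null(rownames(presence)) || is.null(colnames(presence))) {
    stop("presence must have genome (row) and profile (column) names")
  }
  if (length(genome_class) != nrow(presence)) {
    stop("genome_class must have one entry per genome")
  }
  if (!all(genome_class %in% c("NCLDV", "CAUDOVIRALES"))) {
    stop("genome_class entries must be 'NCLDV' or 'CAUDOVIRALES'")
  }
  structure(
    list(genome_ids = rownames(presence),
         genome_class = as.character(genome_class),
         presence = presence),
    class = "occurrence_matrix"
  )
}

#' Occurrence proportions of each profile in NCLDV and Caudovirales genomes
#'
#' For every profile (column) of the survey, the fraction of NCLDV genomes
#' and the fraction of Caudovirales genomes with at least one hit.
#'
#' @param mat an [occurrence_matrix()].
#' @return `data.frame` with columns `profile_id`, `p_ncldv`, `p_caudo`.
#' @export
compute_occurrence_proportions <- function(mat) {
  stopifnot(inherits(mat, "occurrence_matrix"))
  n_ncldv <- sum(mat$genome_class == "NCLDV")
  n_caudo <- sum(mat$genome_class == "CAUDOVIRALES")
  if (n_ncldv == 0L) stop("occurrence survey has no NCLDV genomes")
  if (n_caudo == 0L) stop("occurrence survey has no CAUDOVIRALES genomes")
  data.frame(
    profile_id = colnames(mat$presence),
    p_ncldv = colSums(mat$presence[mat$genome_class == "NCLDV", , drop = FALSE]) / n_ncldv,
    p_caudo = colSums(mat$presence[mat$genome_class == "CAUDOVIRALES", , drop = FALSE]) / n_caudo,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Is a Pfam domain subject to score normalization?
#'
#' Only Pfam domains present in at least 1% of surveyed NCLDV genomes or at
#' least 1% of surveyed Caudovirales genomes are normalized; all others are
#' penalized at their raw bit score.
#'
#' @param p_ncldv,p_caudo occurrence fractions of the domain.
#' @param database must be `"PFAM"`; passing a GVOG profile is an error.
#' @param threshold eligibility threshold (default 0.01, inclusive).
#' @return logical.
#' @export
pfam_normalization_eligible <- function(p_ncldv, p_caudo,
                                        database = "PFAM",
                                        threshold = 0.01) {
  if (any(database != "PFAM")) {
    stop("normalization eligibility applies only to PFAM profiles")
  }
  p_ncldv >= threshold | p_caudo >= threshold
}

#' Majority-vote annotation of a protein family
#'
#' A family is annotated with a label only if strictly more than half of ALL
#' its member proteins share that best-match label; members without a best
#' match still count in the denominator. Ties at exactly 50% give no
#' annotation.
#'
#' @param member_best_matches character vector of per-member best-match
#'   labels; `NA` for members without a match.
#' @return The majority label, or `NA_character_` if none.
#' @export
majority_annotation <- function(member_best_matches) {
  if (length(member_best_matches) == 0L) {
    stop("majority_annotation: empty member list")
  }
  n <- length(member_best_matches)
  labels <- member_best_matches[!is.na(member_best_matches)]
  if (length(labels) == 0L) return(NA_character_)
  tab <- table(labels)
  top <- which.max(tab)
  if (tab[[top]] * 2L > n) names(tab)[top] else NA_character_
}

#' Write profile metadata to a tab-separated file
#'
#' Columns `profile_id`, `database`, `p_ncldv`, `p_caudo`, `annotation`,
#' `marker_name`; absent annotation/marker written as `"."`.
#'
#' @param db a [profile_db()] table.
#' @param path output file.
#' @export
write_profile_db <- function(db, path) {
  validate_profile_db(db)
  out <- db[, c("profile_id", "database", "p_ncldv", "p_caudo",
                "annotation", "marker_name")]
  out$annotation[is.na(out$annotation)] <- "."
  out$marker_name[is.na(out$marker_name)] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read profile metadata written by [write_profile_db()]
#'
#' @param path tab-separated metadata file.
#' @return A validated [profile_db()] table.
#' @export
read_profile_db <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  need <- c("profile_id", "database", "p_ncldv", "p_caudo",
            "annotation", "marker_name")
  if (!all(need %in% names(raw))) {
    stop("profile metadata file missing columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  }
  raw$annotation[raw$annotation == "."] <- NA_character_
  raw$marker_name[raw$marker_name == "."] <- NA_character_
  profile_db(
    profile_id = raw$profile_id,
    database = raw$database,
    p_ncldv = as.numeric(raw$p_ncldv),
    p_caudo = as.numeric(raw$p_caudo),
    annotation = raw$annotation,
    marker_name = raw$marker_name
  )
}
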