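# Per-ORF scoring: a GVOG reward and a Pfam penalty, each normalized by the
# family's occurrence in NCLDV vs Caudovirales genomes, combined on a
# square-root scale. Positive final scores indicate NCLDV-like content.

#' Scoring parameters
#'
#' @param evalue_max e-value cutoff applied when selecting best hits
#'   (default `1e-5`, the threshold used for the occurrence surveys).
#' @param pncldv_floor lower floor applied to `p_ncldv` wherever it appears
#'   in a denominator (default `0.01`, the Pfam normalization-eligibility
#'   threshold), so phage-only families do not divide by zero.
#' @param eq1_variant algebraic form of the GVOG reward. `"ratio"` (default)
#'   down-weights families shared with Caudovirales:
#'   `B * p_ncldv / (p_ncldv + p_caudo)`. `"literal"` is the alternative
#'   additive form `B * (p_ncldv + p_caudo / p_ncldv)`, retained for
#'   comparison; note it grows with `p_caudo`, so phage-shared families
#'   inflate rather than damp the reward under this variant (see the methods
#'   vignette for why `"ratio"` is the default).
#' @return List of class `"score_params"`.
#' @export
score_params <- function(evalue_max = 1e-5, pncldv_floor = 0.01,
                         eq1_variant = c("ratio", "literal")) {
  eq1_variant <- match.arg(eq1_variant)
  if (!is.numeric(evalue_max) || evalue_max <= 0) {
    stop("evalue_max must be > 0")
  }
  if (!is.numeric(pncldv_floor) || pncldv_floor <= 0 || pncldv_floor > 1) {
    stop("pncldv_floor must be in (0, 1]")
  }
  structure(list(evalue_max = evalue_max, pncldv_floor = pncldv_floor,
                 eq1_variant = eq1_variant),
            class = "score_params")
}

check_proportions <- function(p_ncldv, p_caudo) {
  if (any(!is.finite(p_ncldv)) || any(p_ncldv < 0) || any(p_ncldv > 1) ||
      any(!is.finite(p_caudo)) || any(p_caudo < 0) || any(p_caudo > 1)) {
    stop("occurrence proportions must lie in [0, 1]")
  }
}

#' GVOG reward for one protein-profile match
#'
#' The raw bit score `B` (clamped below at 0) is scaled by how specific the
#' family is to NCLDVs. The default `"ratio"` variant multiplies by
#' `p_ncldv / (p_ncldv + p_caudo)`, so a family as common in Caudovirales as
#' in NCLDVs keeps only half its score and an NCLDV-exclusive family keeps
#' all of it; a family absent from both surveys scores 0. The `"literal"`
#' variant computes `B * (p_ncldv + p_caudo / max(p_ncldv, floor))`.
#'
#' @param bitscore full-sequence bit score `B` of the best GVOG hit.
#' @param p_ncldv,p_caudo occurrence fractions of the profile in NCLDV and
#'   Caudovirales genomes.
#' @param params a [score_params()] object.
#' @return Non-negative score, vectorized over its first three arguments.
#' @export
score_gvog <- function(bitscore, p_ncldv, p_caudo, params = score_params()) {
  check_proportions(p_ncldv, p_caudo)
  b <- pmax(bitscore, 0)
  if (params$eq1_variant == "ratio") {
    denom <- p_ncldv + p_caudo
    s <- ifelse(denom > 0, b * p_ncldv / denom, 0)
  } else {
    s <- b * (p_ncldv + p_caudo / pmax(p_ncldv, params$pncldv_floor))
  }
  pmax(s, 0)
}

#' Pfam penalty for one protein-domain match
#'
#' Domains common in NCLDVs should not drag the score down: for
#' normalization-eligible domains the penalty is
#' `B * (1 - p_ncldv) + p_caudo / max(p_ncldv, floor)`, clamped below at 0,
#' which vanishes for NCLDV-universal domains and grows for phage-typical
#' ones. Ineligible domains (rare in both surveys, i.e. typically cellular)
#' are penalized at the raw bit score.
#'
#' @inheritParams score_gvog
#' @param eligible logical from [pfam_normalization_eligible()].
#' @return Non-negative penalty, vectorized.
#' @export
score_pfam <- function(bitscore, p_ncldv, p_caudo, eligible,
                       params = score_params()) {
  check_proportions(p_ncldv, p_caudo)
  b <- pmax(bitscore, 0)
  s <- ifelse(eligible,
              b * (1 - p_ncldv) + p_caudo / pmax(p_ncldv, params$pncldv_floor),
              b)
  pmax(s, 0)
}

#' Combine GVOG reward and Pfam penalty into the final per-ORF score
#'
#' `s_final = sqrt(s_gvog) - sqrt(s_pfam)`. The square-root scale keeps the
#' domain-level Pfam scores (typically smaller) commensurate with the
#' full-protein GVOG scores and stops single outlier matches from dominating
#' a contig. A missing hit contributes 0 to its component.
#'
#' @param s_gvog,s_pfam non-negative component scores.
#' @return Signed final score.
#' @export
combine_scores <- function(s_gvog, s_pfam) {
  sqrt(pmax(s_gvog, 0)) - sqrt(pmax(s_pfam, 0))
}

#' Score every ORF of one or more contigs
#'
#' Looks up the best GVOG and best Pfam hit of each ORF in the profile
#' metadata, computes the normalized reward and penalty, and returns the
#' per-ORF score table in ordinal order per contig. ORFs without hits appear
#' with all-zero scores; a hit naming an ORF absent from `orfs` is an error.
#'
#' @param orfs ORF table from [parse_orf_headers()].
#' @param best_hits best-hit table from [best_hit_per_orf()].
#' @param db profile metadata ([profile_db()] / [read_profile_db()]).
#' @param params a [score_params()] object.
#' @return `data.frame` with columns `contig_id`, `orf_id`, `ordinal`,
#'   `start`, `end`, `strand`, `gvog_profile`, `s_gvog`, `pfam_profile`,
#'   `s_pfam`, `s_final`.
#' @export
score_all_orfs <- function(orfs, best_hits, db, params = score_params()) {
  validate_orfs(orfs)
  unknown <- setdiff(best_hits$orf_id, orfs$orf_id)
  if (length(unknown) > 0L) {
    stop("hit references unknown ORF: ", unknown[1L])
  }
  unknown_prof <- setdiff(
    paste(best_hits$database, best_hits$profile_id),
    paste(db$database, db$profile_id))
  if (length(unknown_prof) > 0L) {
    stop("hit references profile absent from metadata: ", unknown_prof[1L])
  }

  out <- orfs[order(orfs$contig_id, orfs$ordinal),
              c("contig_id", "orf_id", "ordinal", "start", "end", "strand")]
  rownames(out) <- NULL
  out$gvog_profile <- NA_character_
  out$s_gvog <- 0
  out$pfam_profile <- NA_character_
  out$s_pfam <- 0

  gv <- best_hits[best_hits$database == "GVOG", , drop = FALSE]
  if (nrow(gv) > 0L) {
    i <- match(gv$orf_id, out$orf_id)
    meta <- db[db$database == "GVOG", ]
    j <- match(gv$profile_id, meta$profile_id)
    out$gvog_profile[i] <- gv$profile_id
    out$s_gvog[i] <- score_gvog(gv$bitscore, meta$p_ncldv[j],
                                meta$p_caudo[j], params)
  }
  pf <- best_hits[best_hits$database == "PFAM", , drop = FALSE]
  if (nrow(pf) > 0L) {
    i <- match(pf$orf_id, out$orf_id)
    meta <- db[db$database == "PFAM", ]
    j <- match(pf$profile_id, meta$profile_id)
    eligible <- pfam_normalization_eligible(meta$p_ncldv[j], meta$p_caudo[j])
    out$pfam_profile[i] <- pf$profile_id
    out$s_pfam[i] <- score_pfam(pf$bitscore, meta$p_ncldv[j],
                                meta$p_caudo[j], eligible, params)
  }
  out$s_final <- combine_scores(out$s_gvog, out$s_pfam)
  out
}

#' Write the per-ORF score table as TSV
#'
#' @param scores table from [score_all_orfs()].
#' @param path output file (written atomically).
#' @export
write_score_table <- function(scores, path) {
  write_tsv_atomic(scores, path)
}
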