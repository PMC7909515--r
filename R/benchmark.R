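# Benchmarking and curation utilities: pseudocontig shredding, confusion
# metrics at the score cutoff, N50, single-linkage dereplication and the
# genome quality filter.

#' Shred a sequence into non-overlapping pseudocontigs
#'
#' Cuts sequential fragments from the start of the parent, with lengths
#' drawn i.i.d. uniformly on `[min_len, max_len]`; a terminal remainder
#' shorter than `min_len` is discarded. Mimics assembly fragmentation for
#' false-positive-rate benchmarks. Deterministic given `seed`.
#'
#' @param parent_id id of the parent sequence.
#' @param parent_length parent length in bp.
#' @param min_len,max_len fragment length bounds in bp (defaults 5000 and
#'   100000).
#' @param seed integer seed fixing the fragment-length stream.
#' @return `data.frame` with columns `id` (`<parent>|<offset>|<length>`),
#'   `parent_id`, `offset` (0-based start within the parent), `length`.
#'   Empty (with a message) if the parent is shorter than `min_len`.
#' @export
shred <- function(parent_id, parent_length, min_len = 5000L,
                  max_len = 100000L, seed = 1L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  empty <- data.frame(id = character(), parent_id = character(),
                      offset = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (parent_length < min_len) {
    message("sequence '", parent_id, "' (", parent_length,
            " bp) is shorter than min_len; no pseudocontigs")
    return(empty)
  }
  rng <- local_rng(seed)
  offsets <- integer(0)
  lengths <- integer(0)
  pos <- 0L
  repeat {
    len <- if (min_len == max_len) min_len else
      as.integer(floor(rng$runif(1L, min_len, max_len + 1)))
    if (pos + len > parent_length) {
      # take the remainder if it is still a legal fragment
      len <- as.integer(parent_length - pos)
      if (len >= min_len) {
        offsets <- c(offsets, pos); lengths <- c(lengths, len)
      }
      break
    }
    offsets <- c(offsets, pos); lengths <- c(lengths, len)
    pos <- pos + len
    if (pos >= parent_length) break
  }
  data.frame(id = sprintf("%s|%d|%d", parent_id, offsets, lengths),
             parent_id = parent_id, offset = offsets, length = lengths,
             stringsAsFactors = FALSE)
}

#' Assign ORFs to pseudocontig fragments
#'
#' An ORF belongs to a fragment when it lies wholly inside it; ORFs
#' straddling a cut are dropped, matching what a gene caller would predict
#' on the fragment. Coordinates are re-based to the fragment and ordinals
#' renumbered from 1.
#'
#' @param fragments fragment table from [shred()] (one parent).
#' @param orfs ORF table for the parent sequence.
#' @return ORF table with `contig_id` set to the fragment id; an extra
#'   `source_orf_id` column links back to the parent's ORF ids.
#' @export
assign_orfs_to_fragments <- function(fragments, orfs) {
  rows <- lapply(seq_len(nrow(fragments)), function(i) {
    fr <- fragments[i, ]
    inside <- orfs$contig_id == fr$parent_id &
      orfs$start > fr$offset & orfs$end <= fr$offset + fr$length
    sub <- orfs[inside, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    sub <- sub[order(sub$start), , drop = FALSE]
    data.frame(orf_id = sprintf("%s_%d", fr$id, seq_len(nrow(sub))),
               contig_id = fr$id,
               ordinal = seq_len(nrow(sub)),
               start = sub$start - fr$offset,
               end = sub$end - fr$offset,
               strand = sub$strand,
               source_orf_id = sub$orf_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(orf_id = character(), contig_id = character(),
                      ordinal = integer(), start = integer(),
                      end = integer(), strand = character(),
                      source_orf_id = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Specificity from negative-set counts
#'
#' `100 * (n_negatives - n_false_pos) / n_negatives`, rounded half up to one
#' decimal, as a percentage.
#'
#' @param n_negatives number of true non-NCLDV items tested.
#' @param n_false_pos how many of them were called NCLDV.
#' @export
specificity <- function(n_negatives, n_false_pos) {
  if (n_negatives == 0) stop("specificity undefined: no negatives")
  if (n_false_pos < 0 || n_false_pos > n_negatives) {
    stop("n_false_pos must lie in [0, n_negatives]")
  }
  round_half_up(100 * (n_negatives - n_false_pos) / n_negatives, 1L)
}

#' False-positive rate, the complement of specificity
#'
#' Defined as `100 - specificity(...)` so the two always sum to exactly 100
#' for the same counts.
#'
#' @inheritParams specificity
#' @export
false_positive_rate <- function(n_negatives, n_false_pos) {
  100 - specificity(n_negatives, n_false_pos)
}

#' Sensitivity from positive-set counts
#'
#' `100 * (n_positives - n_false_neg) / n_positives`, rounded half up to one
#' decimal, as a percentage.
#'
#' @param n_positives number of true NCLDV items tested.
#' @param n_false_neg how many of them were called non-NCLDV.
#' @export
sensitivity <- function(n_positives, n_false_neg) {
  if (n_positives == 0) stop("sensitivity undefined: no positives")
  if (n_false_neg < 0 || n_false_neg > n_positives) {
    stop("n_false_neg must lie in [0, n_positives]")
  }
  round_half_up(100 * (n_positives - n_false_neg) / n_positives, 1L)
}

#' N50 of an assembly
#'
#' The largest contig length L such that contigs of length >= L together
#' cover at least half the total assembly length.
#'
#' @param contig_lengths positive contig lengths in bp.
#' @return N50 in bp.
#' @export
compute_n50 <- function(contig_lengths) {
  if (length(contig_lengths) == 0L) stop("compute_n50: empty length list")
  if (any(contig_lengths <= 0)) stop("compute_n50: lengths must be > 0")
  lens <- sort(contig_lengths, decreasing = TRUE)
  half <- sum(lens) / 2
  lens[which(cumsum(lens) >= half)[1L]]
}

#' Single-linkage clustering at a distance threshold
#'
#' Connected components of the graph whose edges are genome pairs with
#' distance strictly below the threshold (the convention used when
#' dereplicating at a k-mer distance of 0.05, i.e. roughly 95% ANI); ids
#' without any qualifying edge are singletons.
#'
#' @param distances `data.frame` with columns `id1`, `id2`, `distance`;
#'   symmetric duplicates are allowed.
#' @param ids all genome ids (isolated genomes included).
#' @param threshold strict upper bound on linking distances (default 0.05).
#' @return `data.frame` with `genome_id` and integer `cluster_id`; clusters
#'   are numbered by their lexicographically smallest member.
#' @export
single_linkage_clusters <- function(distances, ids, threshold = 0.05) {
  if (threshold <= 0) stop("threshold must be > 0")
  extra <- setdiff(unique(c(distances$id1, distances$id2)), ids)
  if (length(extra) > 0L) {
    stop("distance table names unknown genome id: ", extra[1L])
  }
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  link <- distances[distances$distance < threshold, , drop = FALSE]
  for (k in seq_len(nrow(link))) {
    a <- find(match(link$id1[k], ids))
    b <- find(match(link$id2[k], ids))
    if (a != b) parent[[max(a, b)]] <- min(a, b)
  }
  roots <- vapply(seq_along(ids), find, integer(1L))
  # stable numbering: clusters ordered by their smallest member id
  rep_id <- vapply(split(ids, roots), min, character(1L))
  cluster_id <- match(rep_id[as.character(roots)], sort(unique(rep_id)))
  data.frame(genome_id = ids, cluster_id = cluster_id,
             stringsAsFactors = FALSE)
}

#' Pick a cluster representative by N50
#'
#' The member with the highest N50 represents the cluster; ties go to the
#' lexicographically smallest id.
#'
#' @param members genome ids of one cluster.
#' @param n50 named numeric vector of N50 values covering all members.
#' @return The representative's id.
#' @export
select_representative <- function(members, n50) {
  if (length(members) == 0L) stop("select_representative: empty cluster")
  missing <- setdiff(members, names(n50))
  if (length(missing) > 0L) {
    stop("no N50 for member: ", missing[1L])
  }
  v <- n50[members]
  best <- members[v == max(v)]
  sort(best)[1L]
}

#' Dereplicate genomes: cluster, then pick representatives
#'
#' @inheritParams single_linkage_clusters
#' @param n50 named vector of per-genome N50 values.
#' @return `data.frame` with `genome_id`, `cluster_id`, `is_representative`.
#' @export
dereplicate_genomes <- function(distances, ids, n50, threshold = 0.05) {
  cl <- single_linkage_clusters(distances, ids, threshold)
  reps <- vapply(split(cl$genome_id, cl$cluster_id),
                 select_representative, character(1L), n50 = n50)
  cl$is_representative <- cl$genome_id %in% reps
  cl
}

#' Genome quality filter for database construction
#'
#' A genome passes only if (1) each of the four single-copy markers A32,
#' PolB, VLTF3 and SFII is present at least once; (2) no marker is
#' duplicated with copies below 90% amino-acid identity (a signature of two
#' genomes binned together); (3) the assembly has fewer than 30 contigs; and
#' (4) it is not externally flagged low quality.
#'
#' @param contig_lengths contig lengths in bp (non-empty, positive).
#' @param marker_counts named counts for `A32`, `PolB`, `VLTF3`, `SFII`.
#' @param duplicate_marker_min_identity lowest pairwise amino-acid identity
#'   among duplicated marker copies, as a fraction; `NA` when no marker is
#'   duplicated.
#' @param flagged_low_quality external low-quality flag.
#' @return List with `pass` (logical) and `failed` (character vector naming
#'   the violated criteria).
#' @export
quality_filter <- function(contig_lengths, marker_counts,
                           duplicate_marker_min_identity = NA_real_,
                           flagged_low_quality = FALSE) {
  if (length(contig_lengths) == 0L || any(contig_lengths <= 0)) {
    stop("contig_lengths must be non-empty and positive")
  }
  need <- c("A32", "PolB", "VLTF3", "SFII")
  if (!all(need %in% names(marker_counts))) {
    stop("marker_counts must name A32, PolB, VLTF3 and SFII")
  }
  failed <- character(0)
  if (any(marker_counts[need] < 1L)) {
    failed <- c(failed, "missing_single_copy_marker")
  }
  if (!is.na(duplicate_marker_min_identity) &&
      duplicate_marker_min_identity < 0.90) {
    failed <- c(failed, "divergent_duplicate_marker")
  }
  if (length(contig_lengths) >= 30L) {
    failed <- c(failed, "too_many_contigs")
  }
  if (isTRUE(flagged_low_quality)) {
    failed <- c(failed, "flagged_low_quality")
  }
  list(pass = length(failed) == 0L, failed = failed)
}

#' Confusion counts from truth labels and calls
#'
#' @param truth character vector, `"NCLDV"` for true positives and anything
#'   else for negatives.
#' @param call character vector of [classify_contig()] calls.
#' @return List with `n_negatives`, `n_false_pos`, `n_positives`,
#'   `n_false_neg`.
#' @export
confusion_counts <- function(truth, call) {
  if (length(truth) != length(call)) stop("truth and call lengths differ")
  pos <- truth == "NCLDV"
  list(n_negatives = sum(!pos),
       n_false_pos = sum(!pos & call == "NCLDV"),
       n_positives = sum(pos),
       n_false_neg = sum(pos & call != "NCLDV"))
}
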