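# Readers for the standard inputs the scanner consumes: assembly FASTA,
# gene-caller protein FASTA with coordinate headers, and profile-search
# tabular output. All downstream code works from these parsed tables, so the
# external binaries (gene caller, hmmsearch) are never required for tests.

#' Read a FASTA file into a sequence table
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' invariants the pipeline relies on: at least one record, non-empty unique
#' ids, non-empty sequences.
#'
#' @param path FASTA file (nucleotide or amino acid).
#' @return `data.frame` with columns `id`, `sequence`, `length`, in file
#'   order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("FASTA parse error at line 1: empty file: ", path)
  if (!startsWith(first, ">")) {
    stop("FASTA parse error at line 1: expected '>' header in ", path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("FASTA parse error: empty sequence id in ", path)
  if (anyDuplicated(ids)) {
    stop("FASTA parse error: duplicate id '", ids[duplicated(ids)][1L],
         "' in ", path)
  }
  if (any(Biostrings::width(set) == 0L)) {
    stop("FASTA parse error: zero-length sequence '",
         ids[Biostrings::width(set) == 0L][1L], "' in ", path)
  }
  data.frame(id = ids,
             sequence = as.character(set),
             length = Biostrings::width(set),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a sequence table to FASTA
#'
#' @param seqs `data.frame` with `id` and `sequence` columns (as returned by
#'   [read_fasta()]).
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs$sequence)
  names(set) <- seqs$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Parse gene coordinates from gene-caller protein headers
#'
#' The gene caller emits protein headers of the form
#' `<contig>_<n> # <start> # <end> # <strand> # <attributes>` with 1-based
#' inclusive nucleotide coordinates and strand coded 1 / -1. The ordinal `n`
#' numbers ORFs consecutively along each contig.
#'
#' @param path protein FASTA with coordinate headers.
#' @return `data.frame` with columns `orf_id`, `contig_id`, `ordinal`,
#'   `start`, `end`, `strand` ("+"/"-"), ordered as in the file.
#' @export
parse_orf_headers <- function(path) {
  headers <- grep("^>", readLines(path, warn = FALSE), value = TRUE)
  if (length(headers) == 0L) stop("no protein records in ", path)
  parse_one <- function(h) {
    h <- sub("^>", "", h)
    parts <- trimws(strsplit(h, "#", fixed = TRUE)[[1L]])
    if (length(parts) < 4L) {
      stop("ORF header parse error: missing coordinate fields in record '",
           parts[1L], "'")
    }
    orf_id <- sub("\\s.*$", "", parts[1L])
    m <- regmatches(orf_id, regexec("^(.*)_([0-9]+)$", orf_id))[[1L]]
    if (length(m) != 3L) {
      stop("ORF header parse error: id '", orf_id,
           "' does not end in _<ordinal>")
    }
    start <- suppressWarnings(as.integer(parts[2L]))
    end <- suppressWarnings(as.integer(parts[3L]))
    strand_raw <- suppressWarnings(as.integer(parts[4L]))
    if (is.na(start) || is.na(end) || is.na(strand_raw)) {
      stop("ORF header parse error: non-numeric coordinates in record '",
           orf_id, "'")
    }
    data.frame(orf_id = orf_id, contig_id = m[2L],
               ordinal = as.integer(m[3L]),
               start = start, end = end,
               strand = if (strand_raw >= 0L) "+" else "-",
               stringsAsFactors = FALSE)
  }
  orfs <- do.call(rbind, lapply(headers, parse_one))
  validate_orfs(orfs)
  orfs
}

validate_orfs <- function(orfs) {
  if (any(orfs$start > orfs$end)) {
    stop("ORF with start > end: ",
         orfs$orf_id[orfs$start > orfs$end][1L])
  }
  if (anyDuplicated(orfs$orf_id)) {
    stop("duplicate orf_id: ", orfs$orf_id[duplicated(orfs$orf_id)][1L])
  }
  for (ctg in unique(orfs$contig_id)) {
    ords <- sort(orfs$ordinal[orfs$contig_id == ctg])
    if (!identical(ords, seq_along(ords))) {
      stop("ORF ordinals on contig '", ctg,
           "' are not consecutive from 1")
    }
  }
  invisible(orfs)
}

#' Parse profile-search tabular output (per-domain table dialect)
#'
#' Reads the whitespace-delimited per-domain table written by `hmmsearch
#' --domtblout`: `#` lines are comments; the target (column 1) is the
#' protein, the query (column 4) the profile; the full-sequence e-value and
#' bit score are columns 7 and 8. One hit row is returned per data row;
#' collapsing multiple rows per protein is [best_hit_per_orf()]'s job.
#'
#' @param path tabular search output.
#' @param database `"GVOG"` or `"PFAM"`, recorded on every hit.
#' @return `data.frame` with columns `orf_id`, `profile_id`, `database`,
#'   `bitscore`, `evalue`.
#' @export
parse_search_table <- function(path, database = c("GVOG", "PFAM")) {
  database <- match.arg(database)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  empty <- data.frame(orf_id = character(), profile_id = character(),
                      database = character(), bitscore = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE)
  if (!any(keep)) return(empty)
  rows <- lapply(which(keep), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 8L) {
      stop("search table parse error at line ", i, ": expected >= 8 columns")
    }
    ev <- suppressWarnings(as.numeric(f[7L]))
    sc <- suppressWarnings(as.numeric(f[8L]))
    if (is.na(ev) || is.na(sc)) {
      stop("search table parse error at line ", i,
           ": non-numeric e-value or score")
    }
    if (ev < 0) stop("search table parse error at line ", i,
                     ": negative e-value")
    data.frame(orf_id = f[1L], profile_id = f[4L], database = database,
               bitscore = sc, evalue = ev, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write hits in the per-domain table dialect
#'
#' Emits one row per hit in the 23-column whitespace-delimited layout of
#' `hmmsearch --domtblout`, readable back with [parse_search_table()]. Used
#' by the fixture generator and handy for round-trip tests.
#'
#' @param hits `data.frame` with `orf_id`, `profile_id`, `bitscore`,
#'   `evalue` columns.
#' @param path output file.
#' @export
write_search_table <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"
  ), con)
  if (nrow(hits) > 0L) {
    rows <- sprintf(
      "%-20s -          %5d %-20s -          %5d %9.2g %6.1f   0.0   1   1 %9.2g %9.2g %6.1f   0.0     1   100     1   100     1   100 0.90 -",
      hits$orf_id, 300L, hits$profile_id, 100L,
      hits$evalue, hits$bitscore, hits$evalue, hits$evalue, hits$bitscore)
    writeLines(rows, con)
  }
  writeLines("#", con)
  invisible(path)
}

#' Best hit per ORF and database
#'
#' Drops hits with e-value above the threshold, then keeps, for each
#' (ORF, database) pair, the single hit with the highest full-sequence bit
#' score; ties are broken by lexicographically smallest profile id.
#'
#' @param hits hit table from [parse_search_table()] (any number of
#'   databases mixed).
#' @param evalue_max e-value cutoff (default `1e-5`); hits with
#'   `evalue > evalue_max` are discarded.
#' @return Filtered hit table, one row per (orf_id, database).
#' @export
best_hit_per_orf <- function(hits, evalue_max = 1e-5) {
  if (!is.numeric(evalue_max) || evalue_max <= 0) {
    stop("evalue_max must be > 0")
  }
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$orf_id, hits$database, -hits$bitscore, hits$profile_id)
  hits <- hits[ord, , drop = FALSE]
  keep <- !duplicated(hits[, c("orf_id", "database")])
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate external gene-caller and profile-search binaries
#'
#' Optional adapter: the pipeline consumes parsed tables, so these binaries
#' are only needed when starting from raw nucleotide FASTA with a real
#' profile database on disk.
#'
#' @return Named character vector of resolved paths ("" when absent).
#' @export
external_tools <- function() {
  c(prodigal = Sys.which("prodigal"), hmmsearch = Sys.which("hmmsearch"))
}

#' Predict ORFs with the external gene caller
#'
#' Runs `prodigal` in default (or metagenome) mode on a nucleotide FASTA and
#' returns the path to the protein FASTA whose coordinate headers
#' [parse_orf_headers()] consumes.
#'
#' @param fasta nucleotide FASTA.
#' @param out_faa output protein FASTA path.
#' @param meta use metagenome mode (`-p meta`).
#' @export
predict_orfs_external <- function(fasta, out_faa, meta = FALSE) {
  bin <- Sys.which("prodigal")
  if (bin == "") stop("prodigal not found on PATH")
  args <- c("-i", fasta, "-a", out_faa, "-o", "/dev/null")
  if (meta) args <- c(args, "-p", "meta")
  status <- system2(bin, args, stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("prodigal exited with status ", status)
  invisible(out_faa)
}

#' Search proteins against a profile database with external hmmsearch
#'
#' @param faa protein FASTA.
#' @param hmm_file HMMER3 profile flatfile.
#' @param out_tbl per-domain table output path.
#' @param evalue reporting e-value threshold.
#' @param cpu worker threads.
#' @export
search_profiles_external <- function(faa, hmm_file, out_tbl,
                                     evalue = 1e-5, cpu = 1L) {
  bin <- Sys.which("hmmsearch")
  if (bin == "") stop("hmmsearch not found on PATH")
  status <- system2(bin, c("--domtblout", out_tbl, "-E", format(evalue),
                           "--cpu", cpu, hmm_file, faa),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("hmmsearch exited with status ", status)
  invisible(out_tbl)
}
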