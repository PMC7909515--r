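# Small hand-built profile metadata used across unit tests: one profile per
# archetype, with round proportions that are easy to score by hand.
tiny_db <- function() {
  profile_db(
    profile_id = c("GVOG_SPEC", "GVOG_SHARED", "GVOG_MARK",
                   "PF_NCLDV", "PF_PHAGE", "PF_CELL"),
    database = c("GVOG", "GVOG", "GVOG", "PFAM", "PFAM", "PFAM"),
    p_ncldv = c(0.8, 0.3, 0.9, 0.6, 0.0, 0.0),
    p_caudo = c(0.0, 0.3, 0.0, 0.05, 0.8, 0.0),
    annotation = c("polymerase", NA, "capsid", NA, "tail fiber", NA),
    marker_name = c(NA, NA, "MCP", NA, NA, NA)
  )
}

# Minimal ORF table for one contig: n consecutive 300 bp genes, 100 bp apart.
tiny_orfs <- function(n, contig = "c1") {
  start <- 1L + (seq_len(n) - 1L) * 400L
  data.frame(orf_id = sprintf("%s_%d", contig, seq_len(n)),
             contig_id = contig, ordinal = seq_len(n),
             start = start, end = start + 299L,
             strand = rep_len(c("+", "-"), n),
             stringsAsFactors = FALSE)
}

hit <- function(orf_id, profile_id, database, bitscore, evalue = 1e-20) {
  data.frame(orf_id = orf_id, profile_id = profile_id, database = database,
             bitscore = bitscore, evalue = evalue, stringsAsFactors = FALSE)
}
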