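#' Retain novel transcript candidates
#'
#' Keeps exactly the transcripts whose gffcompare class code is "u"
#' (intergenic / unknown), whose length is strictly greater than
#' \code{novel_min_length} nucleotides and which have more than
#' \code{novel_min_exons} exon(s). Record order is preserved and the filter
#' is idempotent.
#'
#' @param records Data frame of transcript records (columns
#'   \code{transcript_id}, \code{gene_id}, \code{class_code}, \code{length},
#'   \code{exon_count}).
#' @param config An \code{\link{atlas_config}}.
#' @return The retained subset of \code{records}.
#' @examples
#' rec <- data.frame(transcript_id = c("t1", "t2"), gene_id = c("g1", "g2"),
#'                   class_code = c("u", "="), length = c(500, 500),
#'                   exon_count = c(2, 2))
#' filter_novel_transcripts(rec)$transcript_id  # "t1"
#' @export
filter_novel_transcripts <- function(records, config = atlas_config()) {
  need <- c("class_code", "length", "exon_count")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  keep <- records$class_code == "u" &
    records$length > config$novel_min_length &
    records$exon_count > config$novel_min_exons
  records[keep, , drop = FALSE]
}

#' Count annotated queries per database and overall
#'
#' A query is annotated by a database when at least one of its hits passes
#' bit score > \code{annot_min_bitscore}, percent identity >
#' \code{annot_min_pident} and E-value < \code{annot_max_evalue}. Returns
#' the distinct passing query set per database and their union (the
#' "annotated by any database" count).
#'
#' @param hits Data frame of hits (columns \code{query_id},
#'   \code{database}, \code{bitscore}, \code{pident}, \code{evalue}).
#' @param config An \code{\link{atlas_config}}.
#' @return A list with \code{queries} (named list of sorted query-id
#'   vectors per database), \code{per_database} (named integer counts),
#'   \code{union_queries} and \code{union_count}.
#' @export
filter_annotation_hits <- function(hits, config = atlas_config()) {
  need <- c("query_id", "database", "bitscore", "pident", "evalue")
  if (!all(need %in% names(hits)))
    stop("hits must have columns: ", paste(need, collapse = ", "))
  if (any(hits$pident < 0 | hits$pident > 100)) stop("pident must be in [0, 100]")
  if (any(hits$evalue < 0)) stop("evalue must be >= 0")
  if (any(hits$bitscore < 0)) stop("bitscore must be >= 0")
  pass <- hits$bitscore > config$annot_min_bitscore &
    hits$pident > config$annot_min_pident &
    hits$evalue < config$annot_max_evalue
  passing <- hits[pass, c("query_id", "database")]
  dbs <- sort(unique(hits$database))
  queries <- lapply(dbs, function(db)
    sort(unique(passing$query_id[passing$database == db])))
  names(queries) <- dbs
  union_q <- sort(unique(passing$query_id))
  list(queries = queries,
       per_database = vapply(queries, length, integer(1)),
       union_queries = union_q,
       union_count = length(union_q))
}
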