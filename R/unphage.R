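#' Filter alignment hits into viral intervals on bacterial contigs
#'
#' A hit yields an interval on its subject (bacterial) contig iff its percent
#' identity is at least \code{min_identity} and its alignment covers at least
#' \code{min_coverage} of the viral query length. Both thresholds are
#' inclusive. Subject coordinates are order-normalised (minus-strand hits
#' have s_start > s_end as read) and converted to 0-based half-open.
#'
#' The coverage denominator is the viral query: the question the filter asks
#' is whether that viral genome is present on the contig.
#'
#' @param hits data.frame from \code{\link{read_blast_tab}}.
#' @param min_identity Percent identity threshold in (0, 100].
#' @param min_coverage Query-coverage threshold in (0, 1].
#' @return data.frame of intervals: \code{contig_id}, \code{start} (0-based
#'   inclusive), \code{end} (exclusive), \code{source_query}.
#' @export
filter_hits <- function(hits, min_identity = 70, min_coverage = 0.70) {
  stopifnot(min_identity > 0, min_identity <= 100,
            min_coverage > 0, min_coverage <= 1)
  if (nrow(hits) == 0L) {
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), source_query = character(0)))
  }
  if (any(!hits$query_length_known)) {
    bad <- unique(hits$query_id[!hits$query_length_known])
    stop("query length unknown for: ", paste(bad, collapse = ", "))
  }
  keep <- hits$pct_identity >= min_identity &
    hits$aln_length / hits$query_length >= min_coverage
  h <- hits[keep, , drop = FALSE]
  lo <- pmin(h$s_start, h$s_end)
  hi <- pmax(h$s_start, h$s_end)
  data.frame(
    contig_id = h$subject_id,
    start = lo - 1L,        # 1-based inclusive -> 0-based half-open
    end = hi,
    source_query = h$query_id,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Merge viral intervals per contig
#'
#' Unions overlapping and book-ended intervals per contig so that each viral
#' base is excised exactly once. Output is sorted by contig then start, and
#' pairwise disjoint within each contig. Source queries of merged intervals
#' are concatenated with commas.
#'
#' @param intervals data.frame as produced by \code{\link{filter_hits}}.
#' @return data.frame with the same columns, merged.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) return(intervals[, c("contig_id", "start", "end", "source_query")])
  out <- lapply(split(intervals, intervals$contig_id), function(iv) {
    ir <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)  # 1-based closed
    red <- IRanges::reduce(ir, min.gapwidth = 1L)                # merges adjacency
    ov <- IRanges::findOverlaps(ir, red, maxgap = 0L)
    src <- vapply(seq_along(red), function(k) {
      paste(sort(unique(iv$source_query[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == k]])),
            collapse = ",")
    }, character(1))
    data.frame(contig_id = iv$contig_id[1L],
               start = IRanges::start(red) - 1L,
               end = IRanges::end(red),
               source_query = src,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$contig_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Excise viral intervals from one contig and split the residue
#'
#' The merged intervals become prophage records; the complement substrings
#' become bacterial fragments named \code{<contig_id>_frag<k>} left to right.
#' Fragments shorter than \code{min_fragment_len} are dropped (their length
#' is returned so base conservation can be audited).
#'
#' @param contig A length-1 named \code{DNAStringSet}.
#' @param merged data.frame of disjoint sorted 0-based half-open intervals on
#'   this contig (columns \code{start}, \code{end}).
#' @param min_fragment_len Minimum residual fragment length in bp.
#' @return List with \code{fragments} and \code{prophages}
#'   (\code{DNAStringSet}s) and \code{dropped_bp} (total bp of dropped short
#'   fragments).
#' @export
excise_and_split <- function(contig, merged, min_fragment_len = 2000L) {
  stopifnot(length(contig) == 1L, !is.null(names(contig)))
  len <- Biostrings::width(contig)[1L]
  id <- names(contig)[1L]
  if (nrow(merged) == 0L) {
    frag <- contig
    names(frag) <- id
    if (len < min_fragment_len) {
      return(list(fragments = Biostrings::DNAStringSet(), prophages = Biostrings::DNAStringSet(),
                  dropped_bp = len))
    }
    return(list(fragments = frag, prophages = Biostrings::DNAStringSet(), dropped_bp = 0L))
  }
  if (any(merged$start < 0L) || any(merged$end > len) || any(merged$start >= merged$end)) {
    stop("interval out of bounds on contig ", id)
  }
  o <- order(merged$start)
  s <- merged$start[o]; e <- merged$end[o]
  if (any(s[-1] < e[-length(e)])) stop("intervals not disjoint on contig ", id)

  pp <- Biostrings::DNAStringSet(contig[[1L]], start = s + 1L, end = e)
  names(pp) <- sprintf("%s_pp%d", id, seq_along(pp))

  comp_start <- c(0L, e)
  comp_end <- c(s, len)
  keep <- comp_end > comp_start
  comp_start <- comp_start[keep]; comp_end <- comp_end[keep]
  dropped_bp <- 0L
  if (length(comp_start)) {
    fr <- Biostrings::DNAStringSet(contig[[1L]], start = comp_start + 1L, end = comp_end)
    names(fr) <- sprintf("%s_frag%d", id, seq_along(fr))
    short <- Biostrings::width(fr) < min_fragment_len
    dropped_bp <- sum(Biostrings::width(fr)[short])
    fr <- fr[!short]
  } else {
    fr <- Biostrings::DNAStringSet()
  }
  list(fragments = fr, prophages = pp, dropped_bp = as.integer(dropped_bp))
}

#' Unphage a bacterial reference database
#'
#' Full database unphasing: filter alignment hits at the identity/coverage
#' thresholds, merge the surviving viral intervals per contig, excise them,
#' and split each residual bacterial contig into fragments. Output order is
#' deterministic: input contig order, then position.
#'
#' @param contigs Named \code{DNAStringSet} of bacterial contigs.
#' @param hits data.frame from \code{\link{read_blast_tab}}.
#' @param min_identity,min_coverage Thresholds passed to
#'   \code{\link{filter_hits}}.
#' @param min_fragment_len Minimum residual fragment length, bp. Residual
#'   fragments below it are dropped, mirroring the pipeline's global contig
#'   floor.
#' @return List of class \code{unphage_result}: \code{fragments} and
#'   \code{prophages} (\code{DNAStringSet}s), \code{removed_count} (number of
#'   excised prophage records), and \code{per_contig_log} (data.frame with
#'   \code{contig_id}, \code{n_intervals}, \code{bp_removed},
#'   \code{n_fragments}, \code{bp_dropped}).
#' @export
unphage_database <- function(contigs, hits, min_identity = 70,
                             min_coverage = 0.70, min_fragment_len = 2000L) {
  stopifnot(methods::is(contigs, "DNAStringSet"), !is.null(names(contigs)))
  iv <- merge_intervals(filter_hits(hits, min_identity, min_coverage))
  unknown <- setdiff(unique(iv$contig_id), names(contigs))
  if (length(unknown)) {
    stop("hits reference contig(s) absent from database: ",
         paste(unknown, collapse = ", "))
  }
  iv_by <- split(iv, iv$contig_id)
  frags <- vector("list", length(contigs))
  pps <- vector("list", length(contigs))
  log <- data.frame(contig_id = names(contigs), n_intervals = 0L,
                    bp_removed = 0L, n_fragments = 0L, bp_dropped = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(contigs)) {
    id <- names(contigs)[i]
    m <- iv_by[[id]]
    if (is.null(m)) m <- data.frame(start = integer(0), end = integer(0))
    res <- excise_and_split(contigs[i], m, min_fragment_len = 0L)
    # fragment-length floor applied here so dropped bp are logged per contig
    short <- Biostrings::width(res$fragments) < min_fragment_len
    log$bp_dropped[i] <- sum(Biostrings::width(res$fragments)[short]) + res$dropped_bp
    res$fragments <- res$fragments[!short]
    if (nrow(m) == 0L && length(res$fragments)) names(res$fragments) <- id
    frags[[i]] <- res$fragments
    pps[[i]] <- res$prophages
    log$n_intervals[i] <- nrow(m)
    log$bp_removed[i] <- sum(m$end - m$start)
    log$n_fragments[i] <- length(res$fragments)
  }
  out <- list(
    fragments = do.call(c, frags),
    prophages = do.call(c, pps),
    removed_count = sum(lengths(pps)),
    per_contig_log = log
  )
  class(out) <- "unphage_result"
  out
}

#' @export
print.unphage_result <- function(x, ...) {
  cat("Unphaged database:\n")
  cat("  prophages removed: ", x$removed_count, "\n", sep = "")
  cat("  residual fragments:", length(x$fragments), "\n")
  cat("  bp excised:        ", sum(x$per_contig_log$bp_removed), "\n", sep = "")
  invisible(x)
}

#' Per-contig unphaging report
#'
#' @param result An \code{unphage_result}.
#' @param path Optional TSV output path.
#' @return The report data.frame (contig_id, n_intervals, bp_removed,
#'   n_fragments), invisibly when written.
#' @export
unphage_report <- function(result, path = NULL) {
  rep <- result$per_contig_log[, c("contig_id", "n_intervals", "bp_removed",
                                   "n_fragments")]
  if (!is.null(path)) {
    utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rep))
  }
  rep
}
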