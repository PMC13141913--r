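#' Drop contigs below a length floor
#'
#' Assembly contigs shorter than \code{min_len} are discarded (boundary
#' inclusive: a contig of exactly \code{min_len} bp is kept).
#'
#' @param contigs Named \code{DNAStringSet}.
#' @param min_len Minimum contig length in bp.
#' @return The filtered \code{DNAStringSet}.
#' @export
length_filter <- function(contigs, min_len = 2000L) {
  keep <- Biostrings::width(contigs) >= min_len
  log_stage("length_filter", length(contigs), sum(keep))
  contigs[keep]
}

#' Extract predicted prophage regions as candidate phage contigs
#'
#' Each predicted prophage region (CheckV/PhageBoost-style coordinates,
#' 0-based half-open) is excised into a candidate phage contig named
#' \code{<contig_id>_pp<k>}; overlapping regions from different predictors
#' are merged before excision so each base is excised once. Host-side
#' residual fragments are retained for the bacterial filter.
#'
#' @param contigs Named \code{DNAStringSet} of assembly contigs.
#' @param scores data.frame from \code{\link{read_scores_table}} (uses the
#'   \code{prophage_regions} list column).
#' @param min_fragment_len Floor for host-side residual fragments, bp.
#' @return List: \code{candidates} (prophage \code{DNAStringSet}),
#'   \code{host_fragments} (\code{DNAStringSet}), \code{parent} (named
#'   character, candidate/fragment ID -> parent contig ID).
#' @export
extract_prophages <- function(contigs, scores, min_fragment_len = 2000L) {
  stopifnot(methods::is(contigs, "DNAStringSet"))
  regions <- do.call(rbind, lapply(seq_len(nrow(scores)), function(i) {
    m <- scores$prophage_regions[[i]]
    if (nrow(m) == 0L) return(NULL)
    data.frame(contig_id = scores$contig_id[i], start = m[, 1], end = m[, 2],
               source_query = "prophage_predictor", stringsAsFactors = FALSE)
  }))
  if (is.null(regions)) {
    regions <- data.frame(contig_id = character(0), start = integer(0),
                          end = integer(0), source_query = character(0))
  }
  regions <- regions[regions$contig_id %in% names(contigs), , drop = FALSE]
  # reuse the unphaging excision machinery with the predicted intervals
  merged <- merge_intervals(regions)
  by_contig <- split(merged, merged$contig_id)
  cand <- vector("list", 0L); host <- vector("list", 0L)
  parent <- character(0)
  for (i in seq_along(contigs)) {
    id <- names(contigs)[i]
    m <- by_contig[[id]]
    if (is.null(m)) m <- data.frame(start = integer(0), end = integer(0))
    ex <- excise_and_split(contigs[i], m, min_fragment_len = min_fragment_len)
    if (length(ex$prophages)) {
      cand[[length(cand) + 1L]] <- ex$prophages
      parent[names(ex$prophages)] <- id
    }
    if (length(ex$fragments)) {
      host[[length(host) + 1L]] <- ex$fragments
      parent[names(ex$fragments)] <- id
    }
  }
  list(
    candidates = if (length(cand)) do.call(c, cand) else Biostrings::DNAStringSet(),
    host_fragments = if (length(host)) do.call(c, host) else Biostrings::DNAStringSet(),
    parent = parent
  )
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), aln_length = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             e_value = numeric(0), query_length = numeric(0),
             query_length_known = logical(0))
}

#' Remove contigs annotated as bacterial
#'
#' Contigs flagged bacterial (Kraken-style, against the unphaged reference)
#' are removed. A bacterial parent whose prophage candidates were extracted
#' is still removed — the candidates survive on their own.
#'
#' @param contigs Named \code{DNAStringSet} (parents, candidates, fragments).
#' @param scores data.frame with \code{contig_id} and \code{kraken_bacterial};
#'   contigs absent from the table are treated as non-bacterial.
#' @return Filtered \code{DNAStringSet}.
#' @export
remove_bacterial <- function(contigs, scores) {
  flag <- scores$kraken_bacterial
  flag[is.na(flag)] <- FALSE
  bacterial <- scores$contig_id[flag]
  keep <- !(names(contigs) %in% bacterial)
  log_stage("remove_bacterial", length(contigs), sum(keep))
  contigs[keep]
}

#' Consensus phage classification from classifier scores
#'
#' The consensus rule removes false-positive phage predictions: a contig is
#' called phage iff its PhaMer-style score passes the score threshold AND the
#' sum of the PhaMer-style and MetaPhaPred-style scores strictly exceeds the
#' agreement minimum. A missing MetaPhaPred score contributes 0 to the
#' agreement sum; a missing PhaMer score is an error since its threshold is
#' mandatory. DeepVirFinder/VirSorter2 evidence is recorded in the decision
#' trace and, only when \code{dvf_rescue = TRUE}, can rescue a contig that
#' failed the agreement rule but has both supplementary calls positive.
#'
#' @param scores data.frame with \code{contig_id}, \code{phamer},
#'   \code{metaphapred}, and optionally \code{deepvirfinder},
#'   \code{virsorter2_viral}.
#' @param phamer_threshold PhaMer score threshold (inclusive).
#' @param agreement_min Score-sum agreement minimum (strict).
#' @param dvf_rescue Allow supplementary-classifier rescue (off by default).
#' @param dvf_threshold DeepVirFinder score needed for a rescue.
#' @return data.frame: \code{contig_id}, \code{verdict}
#'   (\code{"phage"}/\code{"non_phage"}), \code{reason}.
#' @export
consensus_classify <- function(scores, phamer_threshold = 0.9,
                               agreement_min = 1.0, dvf_rescue = FALSE,
                               dvf_threshold = 0.9) {
  ph <- scores$phamer
  mp <- scores$metaphapred
  if (any(is.na(ph) & is.na(mp))) {
    bad <- scores$contig_id[is.na(ph) & is.na(mp)]
    stop("no primary classifier score for contig(s): ", paste(bad, collapse = ", "))
  }
  if (any(is.na(ph))) {
    stop("missing PhaMer score for contig(s): ",
         paste(scores$contig_id[is.na(ph)], collapse = ", "))
  }
  mp0 <- ifelse(is.na(mp), 0, mp)
  pass_th <- ph >= phamer_threshold
  pass_sum <- (ph + mp0) > agreement_min
  verdict <- ifelse(pass_th & pass_sum, "phage", "non_phage")
  reason <- sprintf("phamer=%.3f(%s) sum=%.3f(%s)", ph,
                    ifelse(pass_th, "pass", "fail"), ph + mp0,
                    ifelse(pass_sum, "pass", "fail"))
  if (!is.null(scores$deepvirfinder) || !is.null(scores$virsorter2_viral)) {
    dvf <- if (is.null(scores$deepvirfinder)) rep(NA_real_, nrow(scores)) else scores$deepvirfinder
    vs2 <- if (is.null(scores$virsorter2_viral)) rep(NA, nrow(scores)) else scores$virsorter2_viral
    reason <- paste0(reason, sprintf(" dvf=%s vs2=%s",
                                     ifelse(is.na(dvf), "NA", sprintf("%.3f", dvf)),
                                     ifelse(is.na(vs2), "NA", as.character(vs2))))
    if (dvf_rescue) {
      rescue <- verdict == "non_phage" &
        !is.na(dvf) & dvf >= dvf_threshold & !is.na(vs2) & vs2
      verdict[rescue] <- "phage"
      reason[rescue] <- paste0(reason[rescue], " rescued")
    }
  }
  data.frame(contig_id = scores$contig_id, verdict = verdict, reason = reason,
             stringsAsFactors = FALSE)
}

#' Run the contig-level mining cascade
#'
#' Length filter, prophage extraction, bacterial-contig removal, and
#' consensus classification, in that order. Prophage candidates inherit
#' their parent's classifier scores unless scored separately.
#'
#' @param contigs Named \code{DNAStringSet} of assembly contigs.
#' @param scores data.frame from \code{\link{read_scores_table}}.
#' @param config Named list from \code{\link{read_config}}.
#' @return List: \code{phage_contigs} (\code{DNAStringSet}),
#'   \code{decisions} (data.frame of per-contig verdicts).
#' @export
mine_phages <- function(contigs, scores, config = default_config()) {
  contigs <- length_filter(contigs, config$min_contig_len)
  ex <- extract_prophages(contigs, scores, config$min_fragment_len)
  # parents with excised regions are replaced by their host-side fragments
  split_parents <- unique(ex$parent[names(ex$candidates)])
  pool <- c(contigs[!names(contigs) %in% split_parents],
            ex$host_fragments[ex$parent[names(ex$host_fragments)] %in% split_parents],
            ex$candidates)
  # candidates inherit parent scores; parents flagged bacterial are dropped,
  # their candidates are not
  idx <- match(names(pool), scores$contig_id)
  parent_idx <- match(ex$parent[names(pool)], scores$contig_id)
  idx[is.na(idx)] <- parent_idx[is.na(idx)]
  sc <- scores[idx, , drop = FALSE]
  sc$contig_id <- names(pool)
  is_candidate <- names(pool) %in% names(ex$candidates)
  sc$kraken_bacterial[is_candidate] <- FALSE
  pool <- remove_bacterial(pool, sc)
  sc <- sc[sc$contig_id %in% names(pool), , drop = FALSE]
  dec <- consensus_classify(sc, config$phamer_threshold, config$agreement_min,
                            config$dvf_rescue)
  phage_ids <- dec$contig_id[dec$verdict == "phage"]
  log_stage("consensus", nrow(dec), length(phage_ids))
  list(phage_contigs = pool[names(pool) %in% phage_ids], decisions = dec)
}
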