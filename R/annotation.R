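#' Filter family-level taxonomy calls
#'
#' Nulls the family when the rejection score is below the threshold
#' (inclusive: score equal to the threshold passes) or when the family is
#' not in the reference-catalog whitelist, guarding against environmental
#' false classifications. Rows are retained with \code{NA} family for
#' traceability.
#'
#' @param calls data.frame with \code{contig_id}, \code{family}, \code{score}
#'   (and optionally \code{source}).
#' @param reject_below Rejection score threshold.
#' @param allowed_families Character vector whitelist of family names.
#' @return \code{calls} with failing families set to \code{NA}.
#' @export
filter_taxonomy <- function(calls, reject_below = 0.7, allowed_families) {
  stopifnot(length(allowed_families) > 0)
  has <- !is.na(calls$family)
  fail <- has & (is.na(calls$score) | calls$score < reject_below |
                   !(calls$family %in% allowed_families))
  calls$family[fail] <- NA_character_
  calls
}

#' Merge taxonomy calls from two classifiers by agreement
#'
#' Where both a PhaGCN-style and a ViroTaxo-style call survive filtering and
#' disagree, the call is nulled (\code{policy = "agreement"}) or the
#' PhaGCN-style call wins (\code{policy = "phagcn_priority"}); where only one
#' is present it is used.
#'
#' @param calls data.frame of filtered calls with a \code{source} column
#'   (\code{"phagcn_like"} / \code{"virotaxo_like"}).
#' @param policy Arbitration policy.
#' @return data.frame with one row per contig: \code{contig_id},
#'   \code{family}, \code{conflict} (logical).
#' @export
merge_taxonomy_sources <- function(calls, policy = c("agreement", "phagcn_priority")) {
  policy <- match.arg(policy)
  out <- lapply(split(calls, calls$contig_id), function(d) {
    pg <- d$family[d$source == "phagcn_like"]
    vt <- d$family[d$source == "virotaxo_like"]
    pg <- pg[!is.na(pg)][1]
    vt <- vt[!is.na(vt)][1]
    conflict <- !is.na(pg) && !is.na(vt) && pg != vt
    fam <- if (conflict) {
      if (policy == "agreement") NA_character_ else pg
    } else if (!is.na(pg)) pg else vt
    data.frame(contig_id = d$contig_id[1], family = fam, conflict = conflict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Propagate taxonomy to bin members and discard conflicting bins
#'
#' Within each bin the distinct non-null member families are counted:
#' exactly one distinct family is propagated to every member; two or more
#' discard the bin's annotation (members retained, families nulled, bin
#' flagged); zero leaves the bin unannotated. Only the family assignment is
#' voided for conflicting bins — the contigs still flow into quantification.
#'
#' @param bins data.frame with \code{bin_id}, \code{contig_id}; a contig may
#'   appear in at most one bin.
#' @param calls data.frame of per-contig filtered calls (\code{contig_id},
#'   \code{family}).
#' @return List: \code{bins} (data.frame \code{bin_id}, \code{family},
#'   \code{discarded}), \code{contig_families} (data.frame \code{contig_id},
#'   \code{family}), \code{discarded_bin_fraction}.
#' @export
propagate_bin_taxonomy <- function(bins, calls) {
  if (anyDuplicated(bins$contig_id)) {
    stop("contig assigned to multiple bins: ",
         bins$contig_id[duplicated(bins$contig_id)][1])
  }
  fam_of <- stats::setNames(calls$family, calls$contig_id)
  per_bin <- lapply(split(bins, bins$bin_id), function(b) {
    fams <- unique(stats::na.omit(unname(fam_of[b$contig_id])))
    if (length(fams) == 1L) {
      data.frame(bin_id = b$bin_id[1], family = fams, discarded = FALSE,
                 stringsAsFactors = FALSE)
    } else if (length(fams) == 0L) {
      data.frame(bin_id = b$bin_id[1], family = NA_character_, discarded = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(bin_id = b$bin_id[1], family = NA_character_, discarded = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  bin_tab <- do.call(rbind, per_bin)
  rownames(bin_tab) <- NULL
  # per-contig outcome: binned contigs take the bin family (NA if discarded
  # or unannotated), unbinned contigs keep their own call
  contig_families <- data.frame(contig_id = calls$contig_id,
                                family = calls$family,
                                stringsAsFactors = FALSE)
  bin_fam <- stats::setNames(bin_tab$family, bin_tab$bin_id)
  binned <- match(contig_families$contig_id, bins$contig_id)
  in_bin <- !is.na(binned)
  contig_families$family[in_bin] <- unname(bin_fam[bins$bin_id[binned[in_bin]]])
  list(bins = bin_tab, contig_families = contig_families,
       discarded_bin_fraction = mean(bin_tab$discarded))
}

#' Filter lifestyle calls by rejection score
#'
#' @param calls data.frame with \code{contig_id}, \code{lifestyle},
#'   \code{score}.
#' @param reject_below Rejection threshold (inclusive boundary: a score equal
#'   to it passes).
#' @return \code{calls} with failing lifestyles set to \code{NA}.
#' @export
filter_lifestyle <- function(calls, reject_below = 0.7) {
  has <- !is.na(calls$lifestyle)
  fail <- has & (is.na(calls$score) | calls$score < reject_below)
  calls$lifestyle[fail] <- NA_character_
  calls
}

#' Filter host predictions
#'
#' iPHoP-style calls are kept only with confidence at or above the cutoff
#' and at least one shared protein reported; Kraken-style calls pass
#' untouched (they are filtered upstream by their own pipeline).
#'
#' @param calls data.frame with \code{contig_id}, \code{host_genus},
#'   \code{host_species}, \code{confidence}, \code{shared_proteins},
#'   \code{source} (\code{"iphop_like"}/\code{"kraken_like"}).
#' @param min_confidence Confidence cutoff on the 0-100 scale.
#' @param require_shared_proteins Drop predictions reporting no shared
#'   proteins.
#' @return The filtered data.frame (failing rows removed).
#' @export
filter_hosts <- function(calls, min_confidence = 95,
                         require_shared_proteins = TRUE) {
  ip <- calls$source == "iphop_like"
  drop <- ip & (is.na(calls$confidence) | calls$confidence < min_confidence)
  if (require_shared_proteins) {
    drop <- drop | (ip & (is.na(calls$shared_proteins) | calls$shared_proteins <= 0))
  }
  calls[!drop, , drop = FALSE]
}

#' Merge host predictions from two sources
#'
#' Per contig the iPHoP-style call takes precedence; Kraken-style calls fill
#' contigs without a surviving iPHoP-style call. A conflict (both present,
#' different genus) resolves to the iPHoP-style call with a logged flag.
#'
#' @param iphop_calls,kraken_calls Filtered host-call data.frames.
#' @return data.frame, one row per contig: \code{contig_id},
#'   \code{host_genus}, \code{host_species}, \code{source},
#'   \code{conflict}.
#' @export
merge_host_sources <- function(iphop_calls, kraken_calls) {
  ids <- unique(c(iphop_calls$contig_id, kraken_calls$contig_id))
  ii <- match(ids, iphop_calls$contig_id)
  ki <- match(ids, kraken_calls$contig_id)
  use_ip <- !is.na(ii) & !is.na(iphop_calls$host_genus[ii])
  genus <- ifelse(use_ip, iphop_calls$host_genus[ii], kraken_calls$host_genus[ki])
  species <- ifelse(use_ip, iphop_calls$host_species[ii], kraken_calls$host_species[ki])
  src <- ifelse(use_ip, "iphop_like", "kraken_like")
  conflict <- use_ip & !is.na(ki) & !is.na(kraken_calls$host_genus[ki]) &
    kraken_calls$host_genus[ki] != iphop_calls$host_genus[ii]
  data.frame(contig_id = ids, host_genus = genus, host_species = species,
             source = src, conflict = conflict, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Annotation-rate report
#'
#' Fraction of contigs annotated at each level, as percentages of the mined
#' contig universe. This is the bookkeeping used to report e.g. taxonomy,
#' lifestyle and host annotation rates.
#'
#' @param n_total Number of mined contigs.
#' @param n_family,n_lifestyle,n_host_genus,n_host_species Annotated counts.
#' @return data.frame with \code{level}, \code{n}, \code{pct} (percent,
#'   exact division by \code{n_total} times 100).
#' @export
annotation_rates <- function(n_total, n_family = NA, n_lifestyle = NA,
                             n_host_genus = NA, n_host_species = NA) {
  stopifnot(n_total > 0)
  n <- c(family = n_family, lifestyle = n_lifestyle,
         host_genus = n_host_genus, host_species = n_host_species)
  data.frame(level = names(n), n = unname(n),
             pct = unname(100 * n / n_total), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Build a combined annotation table
#'
#' One row per contig with post-processed family, lifestyle and host calls,
#' as consumed by \code{\link{group_phages}}.
#'
#' @param contig_ids Character vector: the mined contig universe.
#' @param families data.frame \code{contig_id}, \code{family}.
#' @param lifestyles data.frame \code{contig_id}, \code{lifestyle}.
#' @param hosts data.frame \code{contig_id}, \code{host_genus}.
#' @return data.frame with \code{contig_id}, \code{family}, \code{lifestyle},
#'   \code{host_genus} (NA where unannotated).
#' @export
build_annotation_table <- function(contig_ids, families = NULL,
                                   lifestyles = NULL, hosts = NULL) {
  pick <- function(tab, col) {
    if (is.null(tab)) return(rep(NA_character_, length(contig_ids)))
    as.character(tab[[col]][match(contig_ids, tab$contig_id)])
  }
  data.frame(contig_id = contig_ids,
             family = pick(families, "family"),
             lifestyle = pick(lifestyles, "lifestyle"),
             host_genus = pick(hosts, "host_genus"),
             stringsAsFactors = FALSE)
}
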