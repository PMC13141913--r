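#' Pairwise identity and coverage between two contigs
#'
#' Local alignment (exact dynamic programming) of the shorter sequence
#' against the longer, on both strands since phage contigs are unoriented.
#' Identity is matched bases over aligned columns (gaps included); coverage
#' is the aligned span of the shorter sequence over its length, so coverage
#' is symmetric and containment of a short contig in a long one scores 1.
#'
#' @param a,b \code{DNAString}s or character sequences.
#' @return Named numeric vector \code{c(identity =, coverage =)}, fractions.
#' @export
pairwise_identity_coverage <- function(a, b) {
  a <- Biostrings::DNAString(as.character(a))
  b <- Biostrings::DNAString(as.character(b))
  stopifnot(length(a) > 0, length(b) > 0)
  if (length(a) >= length(b)) { long <- a; short <- b } else { long <- b; short <- a }
  best <- align_stats(short, long)
  rc <- align_stats(Biostrings::reverseComplement(short), long)
  if (rc[["score"]] > best[["score"]]) best <- rc
  c(identity = unname(best[["identity"]]), coverage = unname(best[["coverage"]]))
}

# cached +1/-1 substitution matrix (building it dominates small alignments)
.derep_env <- new.env(parent = emptyenv())
derep_submat <- function() {
  if (is.null(.derep_env$submat)) {
    .derep_env$submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                                  mismatch = -1)
  }
  .derep_env$submat
}

align_stats <- function(short, long) {
  aln <- Biostrings::pairwiseAlignment(short, long, type = "local",
                                       substitutionMatrix = derep_submat(),
                                       gapOpening = 2, gapExtension = 1)
  ind <- Biostrings::nindel(aln)
  gap_cols <- sum(Biostrings::insertion(ind)[, "WidthSum"]) +
    sum(Biostrings::deletion(ind)[, "WidthSum"])
  cols <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) + gap_cols
  ident <- if (cols > 0) Biostrings::nmatch(aln) / cols else 0
  span <- Biostrings::width(Biostrings::pattern(aln))  # aligned bases of the shorter
  c(score = Biostrings::score(aln), identity = ident,
    coverage = span / length(short))
}

#' Greedy dereplication of phage contigs
#'
#' Contigs are sorted by length descending (ties broken by lexicographic ID);
#' each contig joins the first existing cluster whose representative it
#' matches at or above both the identity and coverage thresholds, otherwise
#' it founds a new cluster. Representatives are therefore the longest member
#' of each cluster and pairwise non-redundant. Deterministic given the input.
#'
#' @param contigs Named \code{DNAStringSet}.
#' @param min_identity Identity threshold, fraction in (0, 1].
#' @param min_coverage Coverage threshold (of the shorter sequence), (0, 1].
#' @return List of class \code{derep_result}: \code{clusters} (data.frame
#'   with \code{representative_id}, \code{member_id}, \code{identity},
#'   \code{coverage}; representatives listed as their own members with 1, 1)
#'   and \code{representatives} (\code{DNAStringSet}).
#' @export
greedy_derep <- function(contigs, min_identity = 0.98, min_coverage = 0.85) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1,
            !is.null(names(contigs)))
  ord <- order(-Biostrings::width(contigs), names(contigs))
  contigs <- contigs[ord]
  reps <- integer(0)
  rows <- vector("list", length(contigs))
  for (i in seq_along(contigs)) {
    assigned <- FALSE
    for (r in reps) {
      st <- pairwise_identity_coverage(contigs[[r]], contigs[[i]])
      if (st[["identity"]] >= min_identity && st[["coverage"]] >= min_coverage) {
        rows[[i]] <- data.frame(representative_id = names(contigs)[r],
                                member_id = names(contigs)[i],
                                identity = st[["identity"]],
                                coverage = st[["coverage"]],
                                stringsAsFactors = FALSE)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      rows[[i]] <- data.frame(representative_id = names(contigs)[i],
                              member_id = names(contigs)[i],
                              identity = 1, coverage = 1,
                              stringsAsFactors = FALSE)
    }
  }
  clusters <- do.call(rbind, rows)
  out <- list(clusters = clusters, representatives = contigs[reps])
  class(out) <- "derep_result"
  out
}

#' @export
print.derep_result <- function(x, ...) {
  cat("Dereplication: ", nrow(x$clusters), " contigs -> ",
      length(x$representatives), " representatives\n", sep = "")
  invisible(x)
}

#' Cluster membership as a named vector
#'
#' @param result A \code{derep_result}.
#' @return Named character vector member_id -> representative_id.
#' @export
derep_membership <- function(result) {
  stats::setNames(result$clusters$representative_id, result$clusters$member_id)
}
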