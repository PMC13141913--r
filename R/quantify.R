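#' Viral relative units for one sample
#'
#' Per-contig abundance weight is mean depth over covered bases times the
#' covered fraction of the contig (equivalently, total mapped bases divided
#' by contig length); VRU is that weight normalised to sum to one within the
#' sample, addressing the under-representation of viral abundances in mixed
#' metagenomes. A sample with no mapped signal yields an all-zero vector
#' with an \code{empty} flag rather than an error.
#'
#' @param depths data.frame of per-contig depth summaries for one sample
#'   (\code{contig_id}, \code{mdepth}, \code{coverage}).
#' @return List: \code{vru} (named numeric vector summing to 1, or all-zero),
#'   \code{empty} (logical flag).
#' @export
compute_vru <- function(depths) {
  stopifnot(all(c("contig_id", "mdepth", "coverage") %in% names(depths)))
  if (anyDuplicated(depths$contig_id)) stop("duplicate contig in one sample's depths")
  if (any(depths$mdepth < 0) || any(depths$coverage < 0 | depths$coverage > 1)) {
    stop("invalid depth summary values")
  }
  w <- depths$mdepth * depths$coverage
  total <- sum(w)
  if (total == 0) {
    return(list(vru = stats::setNames(rep(0, length(w)), depths$contig_id),
                empty = TRUE))
  }
  list(vru = stats::setNames(w / total, depths$contig_id), empty = FALSE)
}

#' Aggregate per-contig VRU into phage groups
#'
#' Contigs sharing the same (family, lifestyle, host genus) annotation are
#' summed into one group; missing annotations map to an explicit
#' \code{"unclassified"} level so row sums are preserved exactly.
#'
#' @param vru_by_sample Named list: sample_id -> output of
#'   \code{\link{compute_vru}} (or a bare named VRU vector).
#' @param annotations data.frame from \code{\link{build_annotation_table}};
#'   every contig with VRU must have a row.
#' @return List of class \code{vru_table}: \code{values} (sample x group
#'   matrix), \code{groups} (data.frame \code{group}, \code{family},
#'   \code{lifestyle}, \code{host_genus}), \code{empty_samples} (character).
#' @export
group_phages <- function(vru_by_sample, annotations) {
  stopifnot(length(vru_by_sample) > 0, !is.null(names(vru_by_sample)))
  ann_key <- function(x) ifelse(is.na(x) | x == "", "unclassified", x)
  key <- paste(ann_key(annotations$family), ann_key(annotations$lifestyle),
               ann_key(annotations$host_genus), sep = "|")
  key_of <- stats::setNames(key, annotations$contig_id)
  groups <- sort(unique(key))
  empty_samples <- character(0)
  values <- matrix(0, nrow = length(vru_by_sample), ncol = length(groups),
                   dimnames = list(names(vru_by_sample), groups))
  for (s in names(vru_by_sample)) {
    v <- vru_by_sample[[s]]
    if (is.list(v)) {
      if (isTRUE(v$empty)) empty_samples <- c(empty_samples, s)
      v <- v$vru
    }
    missing <- setdiff(names(v)[v > 0], annotations$contig_id)
    if (length(missing)) {
      stop("contig(s) with VRU but no annotation row: ",
           paste(missing, collapse = ", "))
    }
    k <- key_of[names(v)]
    keep <- !is.na(k)
    agg <- tapply(v[keep], k[keep], sum)
    values[s, names(agg)] <- agg
  }
  parts <- do.call(rbind, strsplit(groups, "|", fixed = TRUE))
  out <- list(values = values,
              groups = data.frame(group = groups, family = parts[, 1],
                                  lifestyle = parts[, 2],
                                  host_genus = parts[, 3],
                                  stringsAsFactors = FALSE),
              empty_samples = empty_samples)
  class(out) <- "vru_table"
  out
}

#' @export
print.vru_table <- function(x, ...) {
  cat("VRU table: ", nrow(x$values), " samples x ", ncol(x$values),
      " phage groups\n", sep = "")
  if (length(x$empty_samples)) {
    cat("  samples with no viral signal:",
        paste(x$empty_samples, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Collapse a VRU table to one annotation level
#'
#' Sums groups sharing the same value of \code{level} (e.g. all groups of one
#' family), preserving row sums.
#'
#' @param vru_table A \code{vru_table}.
#' @param level One of \code{"family"}, \code{"lifestyle"},
#'   \code{"host_genus"}.
#' @return sample x level matrix.
#' @export
collapse_vru <- function(vru_table, level = c("family", "lifestyle", "host_genus")) {
  level <- match.arg(level)
  f <- factor(vru_table$groups[[level]])
  m <- vru_table$values %*% stats::model.matrix(~ f - 1)
  colnames(m) <- levels(f)
  m
}

#' Presence/absence from a VRU matrix
#'
#' Presence is any relative viral unit strictly greater than the threshold
#' (default 0, so any nonzero signal counts as present).
#'
#' @param values Numeric matrix (samples x groups) or a \code{vru_table}.
#' @param threshold Strict lower bound for presence.
#' @return Integer 0/1 matrix of the same shape.
#' @export
presence_table <- function(values, threshold = 0) {
  if (inherits(values, "vru_table")) values <- values$values
  m <- (values > threshold) + 0L
  m
}

#' Write a VRU table as long-format TSV
#'
#' @param vru_table A \code{vru_table}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_vru_table <- function(vru_table, path) {
  long <- data.frame(
    sample_id = rep(rownames(vru_table$values), ncol(vru_table$values)),
    family = rep(vru_table$groups$family, each = nrow(vru_table$values)),
    lifestyle = rep(vru_table$groups$lifestyle, each = nrow(vru_table$values)),
    host_genus = rep(vru_table$groups$host_genus, each = nrow(vru_table$values)),
    vru = as.vector(vru_table$values),
    stringsAsFactors = FALSE
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
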