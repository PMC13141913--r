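#' Read a FASTA file of contigs
#'
#' Reads nucleotide contigs into a \code{DNAStringSet}. Sequences are
#' uppercased; duplicate contig IDs and empty sequences are rejected because
#' every downstream stage keys on unique contig IDs.
#'
#' @param path Path to a FASTA file.
#' @return A named \code{\link[Biostrings]{DNAStringSet}}, one element per
#'   record; names are the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) {
    dup <- unique(names(x)[duplicated(names(x))])
    stop("duplicate contig ID(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  if (any(nchar(names(x)) == 0L)) stop("malformed FASTA header (empty ID) in ", path)
  if (any(Biostrings::width(x) == 0L)) {
    bad <- names(x)[Biostrings::width(x) == 0L]
    stop("empty sequence for contig(s): ", paste(bad, collapse = ", "))
  }
  toupper_dss(x)
}

# DNAStringSet is already an uppercase alphabet for ACGTN input, but FASTA may
# carry soft-masked lowercase; normalise once here.
toupper_dss <- function(x) {
  nm <- names(x)
  out <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(out) <- nm
  out
}

#' Write contigs to FASTA
#'
#' @param contigs Named \code{DNAStringSet}.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 80L) {
  Biostrings::writeXStringSet(contigs, filepath = path, width = width)
  invisible(path)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Parses the 12-column tab-separated BLAST dialect
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Coordinates are retained 1-based inclusive as read;
#' subject intervals are order-normalised downstream by
#' \code{\link{filter_hits}}. Rows whose query is missing from
#' \code{qlen_map} are flagged in the \code{query_length_known} column.
#'
#' @param path Path to the hit table. An empty file yields a zero-row table.
#' @param qlen_map Named integer vector mapping query (viral reference) IDs
#'   to their lengths in bp.
#' @return A data.frame with columns \code{query_id}, \code{subject_id},
#'   \code{pct_identity}, \code{aln_length}, \code{q_start}, \code{q_end},
#'   \code{s_start}, \code{s_end}, \code{e_value}, \code{query_length},
#'   \code{query_length_known}.
#' @export
read_blast_tab <- function(path, qlen_map = NULL) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  cols <- c("query_id", "subject_id", "pct_identity", "aln_length",
            "mismatch", "gapopen", "q_start", "q_end", "s_start", "s_end",
            "e_value", "bit_score")
  if (file.size(path) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 12L), cols))
    out$query_length <- numeric(0)
    out$query_length_known <- logical(0)
    return(out)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    stop("expected 12 tab-separated columns, got ", nf[nf != 12L][1L],
         " at row ", which(nf != 12L)[1L])
  }
  m <- do.call(rbind, fields)
  hits <- data.frame(
    query_id     = m[, 1L],
    subject_id   = m[, 2L],
    pct_identity = as.numeric(m[, 3L]),
    aln_length   = as.integer(m[, 4L]),
    mismatch     = as.integer(m[, 5L]),
    gapopen      = as.integer(m[, 6L]),
    q_start      = as.integer(m[, 7L]),
    q_end        = as.integer(m[, 8L]),
    s_start      = as.integer(m[, 9L]),
    s_end        = as.integer(m[, 10L]),
    e_value      = as.numeric(m[, 11L]),
    bit_score    = as.numeric(m[, 12L]),
    stringsAsFactors = FALSE
  )
  if (any(is.na(hits$pct_identity)) || any(hits$pct_identity < 0) ||
      any(hits$pct_identity > 100)) {
    stop("pct_identity outside [0, 100] in ", path)
  }
  if (any(hits$aln_length < 1L)) stop("alignment length < 1 in ", path)
  if (is.null(qlen_map)) {
    hits$query_length <- NA_real_
    hits$query_length_known <- FALSE
  } else {
    hits$query_length <- unname(qlen_map[hits$query_id])
    hits$query_length_known <- !is.na(hits$query_length)
  }
  hits[c("query_id", "subject_id", "pct_identity", "aln_length",
         "q_start", "q_end", "s_start", "s_end", "e_value",
         "query_length", "query_length_known")]
}

#' Summarise a per-base depth table into per-contig depth statistics
#'
#' Consumes a samtools-depth-style table (contig, 1-based position, depth).
#' Positions with zero depth may be absent. \code{mdepth} is the mean depth
#' over covered positions (depth > 0) and \code{coverage} the fraction of the
#' contig covered; contigs absent from the table get (0, 0). Together these
#' make the VRU weight mdepth x coverage equal total mapped bases divided by
#' contig length.
#'
#' @param path Path to the 3-column TSV (no header).
#' @param lengths Named integer vector of contig lengths; defines the contig
#'   universe of the result.
#' @return A data.frame with columns \code{contig_id}, \code{mdepth},
#'   \code{coverage}, \code{contig_length}, one row per name in
#'   \code{lengths}, in that order.
#' @export
read_depth_table <- function(path, lengths) {
  if (!file.exists(path)) stop("depth table not found: ", path)
  stopifnot(length(lengths) > 0, !is.null(names(lengths)))
  if (file.size(path) == 0L) {
    tab <- data.frame(contig_id = character(0), pos = integer(0),
                      depth = numeric(0))
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("contig_id", "pos", "depth"),
                             colClasses = c("character", "integer", "numeric"))
  }
  depth_summary(tab, lengths)
}

#' Depth summaries from an in-memory per-base depth table
#'
#' @param tab data.frame with columns \code{contig_id}, \code{pos} (1-based),
#'   \code{depth}.
#' @param lengths Named integer vector of contig lengths.
#' @return See \code{\link{read_depth_table}}.
#' @export
depth_summary <- function(tab, lengths) {
  unknown <- setdiff(unique(tab$contig_id), names(lengths))
  if (length(unknown)) {
    stop("depth rows for contig(s) absent from length map: ",
         paste(unknown, collapse = ", "))
  }
  over <- tab$pos > unname(lengths[tab$contig_id]) | tab$pos < 1L
  if (any(over)) {
    stop("position out of range for contig ", tab$contig_id[which(over)[1L]])
  }
  covered <- tab[tab$depth > 0, , drop = FALSE]
  n_cov <- tapply(covered$pos, covered$contig_id, function(p) length(unique(p)))
  sum_d <- tapply(covered$depth, covered$contig_id, sum)
  ids <- names(lengths)
  n <- ifelse(ids %in% names(n_cov), n_cov[ids], 0)
  s <- ifelse(ids %in% names(sum_d), sum_d[ids], 0)
  data.frame(
    contig_id = ids,
    mdepth = ifelse(n > 0, s / n, 0),
    coverage = n / unname(lengths),
    contig_length = unname(as.integer(lengths)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Read a sample metadata table
#'
#' Required named header columns: \code{sample_id}, \code{infant_id},
#' \code{age_months} (6 or 12), \code{delivery} (cesarean/vaginal),
#' \code{treatment} (control/PE). \code{infant_id} is the time-series ID
#' (infant x age window) used as the random-intercept grouping factor.
#'
#' @param path Path to a TSV with a header row.
#' @return A validated data.frame with factor columns at the stated levels.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  validate_sample_meta(meta)
}

#' Validate sample metadata
#'
#' @param meta data.frame with the columns of \code{\link{read_sample_meta}}.
#' @return \code{meta} with categorical columns coerced to factors.
#' @export
validate_sample_meta <- function(meta) {
  need <- c("sample_id", "infant_id", "age_months", "delivery", "treatment")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (any(!nzchar(meta$infant_id))) stop("empty infant_id in metadata")
  chk <- function(col, levels) {
    bad <- setdiff(unique(as.character(meta[[col]])), levels)
    if (length(bad)) {
      stop("invalid ", col, " level(s): ", paste(bad, collapse = ", "))
    }
    factor(as.character(meta[[col]]), levels = levels)
  }
  meta$age_months <- chk("age_months", c("6", "12"))
  meta$delivery <- chk("delivery", c("cesarean", "vaginal"))
  meta$treatment <- chk("treatment", c("control", "PE"))
  meta
}

#' Read a classifier score table
#'
#' Scores TSV with named header columns \code{contig_id}, \code{phamer},
#' \code{metaphapred}, \code{deepvirfinder}, \code{virsorter2_viral},
#' \code{kraken_bacterial}, \code{prophage_regions}. Missing scores are
#' empty fields or NA; \code{prophage_regions} is a semicolon-separated list
#' of 0-based half-open \code{start-end} pairs.
#'
#' @param path Path to the TSV.
#' @return data.frame with numeric/logical columns and
#'   \code{prophage_regions} as a list column of two-column matrices.
#' @export
read_scores_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = c("NA", ""),
                           stringsAsFactors = FALSE,
                           colClasses = c(prophage_regions = "character"))
  need <- c("contig_id", "phamer", "metaphapred", "deepvirfinder",
            "virsorter2_viral", "kraken_bacterial", "prophage_regions")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("scores table missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("phamer", "metaphapred", "deepvirfinder")) {
    v <- as.numeric(tab[[col]])
    if (any(v < 0 | v > 1, na.rm = TRUE)) stop(col, " score outside [0, 1]")
    tab[[col]] <- v
  }
  tab$virsorter2_viral <- as.logical(tab$virsorter2_viral)
  tab$kraken_bacterial <- as.logical(tab$kraken_bacterial)
  tab$prophage_regions <- lapply(tab$prophage_regions, parse_region_spec)
  tab
}

parse_region_spec <- function(spec) {
  if (is.na(spec) || !nzchar(spec)) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  parts <- strsplit(strsplit(spec, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed prophage region spec: ", spec)
  m <- matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE,
              dimnames = list(NULL, c("start", "end")))
  if (any(m[, 1] < 0L) || any(m[, 2] <= m[, 1])) {
    stop("malformed prophage region spec: ", spec)
  }
  m
}

format_region_spec <- function(m) {
  if (nrow(m) == 0L) return("")
  paste(sprintf("%d-%d", m[, 1], m[, 2]), collapse = ";")
}

#' Read a pipeline configuration file
#'
#' YAML file holding the thresholds of the mining pipeline; absent keys fall
#' back to the documented defaults.
#'
#' @param path Path to a YAML file, or NULL for defaults only.
#' @return A named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  unknown <- setdiff(names(cfg), names(default_config()))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg
}

#' Default pipeline configuration
#'
#' @return Named list: \code{min_identity} (percent, unphaging),
#'   \code{min_coverage} (fraction of the viral query aligned),
#'   \code{min_fragment_len} and \code{min_contig_len} (bp),
#'   \code{phamer_threshold}, \code{agreement_min}, \code{dvf_rescue},
#'   \code{derep_min_identity}, \code{derep_min_coverage},
#'   \code{taxonomy_reject}, \code{lifestyle_reject}, \code{host_min_confidence}.
#' @export
default_config <- function() {
  list(
    min_identity = 70,
    min_coverage = 0.70,
    min_fragment_len = 2000L,
    min_contig_len = 2000L,
    phamer_threshold = 0.9,
    agreement_min = 1.0,
    dvf_rescue = FALSE,
    derep_min_identity = 0.98,
    derep_min_coverage = 0.85,
    taxonomy_reject = 0.7,
    lifestyle_reject = 0.7,
    host_min_confidence = 95
  )
}

#' Log a per-stage record count
#'
#' Structured one-line log used by the pipeline stages; writes to
#' \code{message()} so it can be silenced with \code{suppressMessages()}.
#'
#' @param stage Stage name.
#' @param n_in,n_out Record counts entering and leaving the stage.
#' @keywords internal
log_stage <- function(stage, n_in, n_out) {
  message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))
  invisible(NULL)
}
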