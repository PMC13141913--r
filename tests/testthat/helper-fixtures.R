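# Shared fixture builders. Everything is generated in code at test time.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

dss <- function(...) {
  x <- c(...)
  out <- Biostrings::DNAStringSet(unname(x))
  names(out) <- names(x)
  out
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# per-base boolean-mask oracle: which 0-based positions of a contig fall in
# any interval of `iv` (data.frame start/end, 0-based half-open)
mask_oracle <- function(len, iv) {
  m <- logical(len)
  for (i in seq_len(nrow(iv))) {
    if (iv$end[i] > iv$start[i]) m[(iv$start[i] + 1):iv$end[i]] <- TRUE
  }
  m
}

# brute-force greedy dereplication oracle: full pairwise matrix, same
# longest-first order, first-matching-representative assignment
derep_oracle <- function(contigs, min_identity = 0.98, min_coverage = 0.85) {
  ord <- order(-Biostrings::width(contigs), names(contigs))
  contigs <- contigs[ord]
  n <- length(contigs)
  idm <- matrix(0, n, n); cvm <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      st <- pairwise_identity_coverage(contigs[[i]], contigs[[j]])
      idm[i, j] <- idm[j, i] <- st[["identity"]]
      cvm[i, j] <- cvm[j, i] <- st[["coverage"]]
    }
  }
  rep_of <- integer(n); reps <- integer(0)
  for (i in seq_len(n)) {
    hit <- 0L
    for (r in reps) {
      if (idm[r, i] >= min_identity && cvm[r, i] >= min_coverage) { hit <- r; break }
    }
    if (hit == 0L) { reps <- c(reps, i); rep_of[i] <- i } else rep_of[i] <- hit
  }
  setNames(names(contigs)[rep_of], names(contigs))
}

empty_hits_df <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             pct_identity = numeric(0), aln_length = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             e_value = numeric(0), query_length = numeric(0),
             query_length_known = logical(0))
}

# miniature cohort config used across statistical tests
mini_cohort_config <- function(seed) {
  sim_config(seed = seed, n_infants = 8, samples_per_infant = 10,
             effect_sizes = list(treatment = 0.8, delivery = 0.5, age = 1.0),
             random_intercept_sd = 0.5, residual_sd = 0.5)
}
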