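# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's own computational paths.

# Exhaustive sample-based rarefaction: average the observed richness over
# every size-t subset of sampling units.
enum_rarefy <- function(mat, t) {
  subsets <- utils::combn(nrow(mat), t, simplify = FALSE)
  mean(vapply(subsets, function(idx) {
    sum(colSums(mat[idx, , drop = FALSE]) > 0)
  }, numeric(1)))
}

# Double-loop mean pairwise Tanimoto (the definitionally obvious path).
brute_diversity <- function(bits) {
  n <- nrow(bits)
  sims <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- bits[i, ]; b <- bits[j, ]
      sims <- c(sims, sum(a & b) / sum(a | b))
    }
  }
  1 - mean(sims)
}

# Random incidence matrix with no empty GCF columns; NULL when the draw
# leaves no occupied column (caller retries with another seed).
random_incidence <- function(T, S, p = 0.4) {
  m <- matrix(rbinom(T * S, 1, p), nrow = T,
              dimnames = list(paste0("u", seq_len(T)),
                              paste0("g", seq_len(S))))
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) == 0) return(NULL)
  incidence_matrix(m)
}

# Incidence matrix from a named list unit -> character vector of GCFs.
toy_incidence <- function(presences) {
  gcfs <- sort(unique(unlist(presences)))
  m <- t(vapply(presences, function(g) as.integer(gcfs %in% g),
                integer(length(gcfs))))
  dimnames(m) <- list(names(presences), gcfs)
  incidence_matrix(m)
}

# Frequencies object straight from counts (bypasses matrix construction).
toy_freqs <- function(T, Y) smprospect:::new_incidence_freqs(T, Y)

# Random BGC-SM link table with known sharing structure.
random_links <- function(n_bgcs, max_sms = 4, pool = 2 * n_bgcs) {
  bgc <- character(0); sm <- character(0)
  for (b in seq_len(n_bgcs)) {
    k <- sample.int(min(max_sms, pool), 1)
    sm_ids <- sample.int(pool, k)
    bgc <- c(bgc, rep(sprintf("B%03d", b), k))
    sm <- c(sm, sprintf("S%03d", sm_ids))
  }
  df <- unique(data.frame(bgc_id = bgc, sm_id = sm,
                          stringsAsFactors = FALSE))
  bgc_sm_table(df)
}

# Random fingerprint set (each row guaranteed at least one set bit).
random_fps <- function(n, L = 64, p = 0.3) {
  bits <- matrix(runif(n * L) < p, nrow = n)
  empty <- rowSums(bits) == 0
  bits[cbind(which(empty), sample.int(L, sum(empty), replace = TRUE))] <- TRUE
  fingerprint_set(bits, ids = sprintf("c%03d", seq_len(n)))
}
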