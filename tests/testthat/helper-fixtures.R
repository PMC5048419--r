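# Small hand-built fixtures shared across test files.

# A dataset with `n_probes` x `n_samples` given intensities; first half of
# the samples are control, second half treatment. Probes alternate
# lncRNA/mRNA biotypes unless given.
make_dataset <- function(ints, flags = NULL, biotype = NULL,
                         scale = "linear") {
  ints <- as.matrix(ints)
  if (is.null(rownames(ints)))
    rownames(ints) <- sprintf("P%02d", seq_len(nrow(ints)))
  n <- ncol(ints)
  nc <- ceiling(n / 2)
  if (is.null(colnames(ints)))
    colnames(ints) <- c(sprintf("c%d", seq_len(nc)),
                        sprintf("t%d", seq_len(n - nc)))
  if (is.null(flags)) {
    flags <- matrix("P", nrow(ints), n, dimnames = dimnames(ints))
  } else if (is.matrix(flags)) {
    dimnames(flags) <- dimnames(ints)
  } else {
    flags <- matrix(flags, nrow(ints), n, byrow = TRUE,
                    dimnames = dimnames(ints))
  }
  if (is.null(biotype))
    biotype <- rep(c("lncRNA", "mRNA"), length.out = nrow(ints))
  ann <- data.frame(probe_id = rownames(ints), biotype = biotype,
                    gene_symbol = paste0("g_", rownames(ints)),
                    stringsAsFactors = FALSE)
  des <- data.frame(sample_id = colnames(ints),
                    group = rep(c("control", "treatment"), c(nc, n - nc)),
                    stringsAsFactors = FALSE)
  expression_dataset(ints, flags, ann, des, scale = scale,
                     control = "control", treatment = "treatment")
}

# qPCR table from per-sample Ct vectors (names = genes), 2 groups.
make_qpcr <- function(ct_by_gene, n_control = 3, n_treatment = 3,
                      reference_gene = "ref") {
  n <- n_control + n_treatment
  rows <- do.call(rbind, lapply(names(ct_by_gene), function(g) {
    data.frame(sample = sprintf("s%d", seq_len(n)),
               group = rep(c("control", "treatment"),
                           c(n_control, n_treatment)),
               gene = g, ct = ct_by_gene[[g]], stringsAsFactors = FALSE)
  }))
  qpcr_table(rows, reference_gene = reference_gene,
             control = "control", treatment = "treatment")
}

# Definitional Pearson correlation, written independently of pearson_r().
brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Literal Benjamini-Hochberg step-up, independent of stats::p.adjust.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    adj_sorted[i] <- min(c(vals, 1))
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Exhaustive hypergeometric upper tail: enumerate all C(N, n) draws of n
# from a universe 1..N and count overlaps with the set {1..K}.
enum_hyper_upper <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}
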