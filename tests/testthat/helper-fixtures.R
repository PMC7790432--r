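# shared fixtures and independent oracles

# random OTU table with Poisson counts (guaranteed positive grand total)
random_table <- function(n_otus, n_samples, lambda = 20, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_otus * n_samples, lambda), n_otus, n_samples,
              dimnames = list(sprintf("otu%03d", seq_len(n_otus)),
                              format(as.Date("2016-01-01") +
                                       seq_len(n_samples) - 1, "%Y-%m-%d")))
  m[1, 1] <- m[1, 1] + 1L   # never all-zero
  otu_table(m, as.Date("2016-01-01") + seq_len(n_samples) - 1)
}

series_from <- function(values, start = "2016-01-01", by_days = 1) {
  abundance_series(as.Date(start) + (seq_along(values) - 1) * by_days,
                   values / max(sum(values), 1))
}

# raw-valued series (detect_peaks is scale invariant, so unnormalized values
# are fine for peak-logic tests)
raw_series <- function(values, start = "2016-01-01", by_days = 1) {
  list(dates = as.Date(start) + (seq_along(values) - 1) * by_days,
       values = values)
}

# brute-force peak oracle: scan every interior triple directly
brute_force_peak_idx <- function(values, min_fraction_of_max = 0.10) {
  n <- length(values)
  vmax <- max(values)
  if (vmax <= 0 || n < 3) return(integer())
  out <- integer()
  for (i in 2:(n - 1)) {
    if (values[i] > values[i - 1] && values[i] >= values[i + 1] &&
        values[i] >= min_fraction_of_max * vmax)
      out <- c(out, i)
  }
  out
}

# dense generalized-eigenproblem oracle for constrained CA eigenvalues:
# build the explicit weighted projector and eigendecompose the projected
# cross-product (no SVD shortcut, independent of the fitting path)
cca_eigen_oracle <- function(counts, X) {
  tot <- sum(counts)
  p <- counts / tot
  r <- rowSums(p); c <- colSums(p)
  q <- (p - outer(r, c)) / sqrt(outer(r, c))
  Xc <- sweep(as.matrix(X), 2, colSums(as.matrix(X) * r), "-")
  Xw <- Xc * sqrt(r)
  proj <- Xw %*% MASS::ginv(crossprod(Xw)) %*% t(Xw)
  qhat <- proj %*% q
  ev <- eigen(crossprod(qhat), symmetric = TRUE, only.values = TRUE)$values
  ev[ev > 1e-10]
}

# Table-1-style parasitoid taxonomy: the printed phylum-level OTU counts
table1_phylum_counts <- function() {
  c(Dinoflagellata = 206, Cercozoa = 140, Stramenopiles_X = 51, Fungi = 20,
    Apicomplexa = 19, Mesomycetozoa = 14, Ciliophora = 5, Metazoa = 3,
    Lobosa = 2, Perkinsea = 1)
}

table1_taxonomy <- function() {
  counts <- table1_phylum_counts()
  phyla <- rep(names(counts), counts)
  taxonomy_table(sprintf("potu%03d", seq_along(phyla)),
                 paste("Eukaryota", "Supergroup", phyla, sep = ";"))
}
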