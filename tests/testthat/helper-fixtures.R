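# Shared fixtures and independent oracles.

# hand-built small molecules -------------------------------------------------

make_ethane <- function() molgraph("ethane", c("C", "C"), rbind(c(1, 2)))

make_ethanol <- function(som = 2L) {
  molgraph("ethanol", c("C", "C", "O"), rbind(c(1, 2), c(2, 3)),
           is_som = seq_len(3) %in% som)
}

make_benzene <- function() {
  molgraph("benzene", rep("C", 6),
           cbind(1:6, c(2:6, 1)))
}

make_toluene <- function() {
  molgraph("toluene", rep("C", 7),
           rbind(cbind(1:6, c(2:6, 1)), c(1, 7)))
}

# ethanol with explicit hydrogens, SOM on the second heavy atom (SDF atom 2);
# hydrogens interleaved so index remapping is actually exercised
write_ethanol_sdf <- function(path, som_field = "2") {
  lines <- c(
    "ethanol", "  test", "",
    "  9  8  0  0  0  0  0  0  0  0999 V2000",
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, c("C", "C", "H", "O", "H", "H", "H", "H", "H")),
    sprintf("%3d%3d%3d  0",
            c(1, 2, 2, 1, 1, 1, 2, 4),
            c(2, 3, 4, 5, 6, 7, 8, 9),
            1),
    "M  END"
  )
  if (!is.null(som_field)) {
    lines <- c(lines, "> <SOM>", som_field, "")
  }
  writeLines(c(lines, "$$$$"), path)
  path
}

# independent oracles --------------------------------------------------------

# truncated Taylor series for exp(-C/2); independent of the eigen route
taylor_expm_neg_half <- function(C, nterms = 40L) {
  n <- nrow(C)
  acc <- diag(n)
  term <- diag(n)
  M <- -C / 2
  for (k in seq_len(nterms)) {
    term <- term %*% M / k
    acc <- acc + term
  }
  acc
}

# random connected graph adjacency for property tests
random_adjacency <- function(n, extra_edge_prob = 0.2) {
  C <- matrix(0, n, n)
  if (n > 1L) {
    for (v in 2:n) {
      u <- sample.int(v - 1L, 1L)
      C[u, v] <- C[v, u] <- 1
    }
    for (u in seq_len(n - 1L)) {
      for (v in (u + 1L):n) {
        if (C[u, v] == 0 && stats::runif(1) < extra_edge_prob) {
          C[u, v] <- C[v, u] <- 1
        }
      }
    }
  }
  C
}

qna_dataset_cached <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 120L, seed = 7L, ...) {
    key <- paste(n, seed, ...)
    if (is.null(cache[[key]])) {
      cache[[key]] <- sim_som_dataset(n, seed = seed, ...)
    }
    cache[[key]]
  }
})
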