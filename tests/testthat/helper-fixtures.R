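# shared fixture builders for the test suite

# small complete sigma-eps table over arbitrary type names
random_table <- function(n_types, seed) {
  set.seed(seed)
  nm <- sort(replicate(n_types, paste0(sample(LETTERS, 2), collapse = "")))
  nm <- make.unique(nm, sep = "")
  pairs <- list()
  for (a in seq_len(n_types)) for (b in a:n_types) {
    pairs[[length(pairs) + 1]] <- data.frame(
      i = nm[a], j = nm[b],
      eps = signif(runif(1, 2, 5.6), 6),      # writer precision contract
      sigma = signif(runif(1, 0.4, 0.7), 6))
  }
  nonbond_table(data.frame(name = nm, mass = signif(runif(n_types, 40, 80), 6),
                           charge = 0),
                do.call(rbind, pairs))
}

# membrane-like frame: one 3-residue peptide plus water above and lipid
# below, built so residue 1 touches only water, residue 3 only lipid and
# residue 2 exactly ties
classification_frame <- function(box = c(10, 10, 10)) {
  prot <- rbind(c(5, 5, 7), c(5, 5, 5), c(5, 5, 3))
  water <- rbind(c(5, 5.5, 7), c(5, 4.5, 7), c(5.4, 5, 7),  # 3 near res 1
                 c(5, 5.5, 5))                              # 1 near res 2
  lipid <- rbind(c(5, 5.5, 3), c(5, 4.5, 3), c(5.4, 5, 3),  # 3 near res 3
                 c(5, 4.5, 5))                              # 1 near res 2
  cg_frame(rbind(prot, water, lipid),
           category = c(rep("protein", 3), rep("water", 4), rep("lipid", 4)),
           resid = c(1:3, rep(NA, 8)),
           peptide = c(rep(1L, 3), rep(NA, 8)),
           box = box)
}

# independent O(n^2) scalar-loop contact count (oracle for the vectorized path)
brute_contacts <- function(a, b, cutoff, box = NULL) {
  n <- 0L
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    d <- a[i, ] - b[j, ]
    if (!is.null(box)) d <- d - box * round(d / box)
    if (sqrt(sum(d^2)) <= cutoff) n <- n + 1L
  }
  n
}

# independent connected-components oracle: boolean transitive closure
brute_components <- function(coms, cutoff, box = NULL) {
  n <- nrow(coms)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- coms[i, ] - coms[j, ]
    if (!is.null(box)) d <- d - box * round(d / box)
    adj[i, j] <- sqrt(sum(d^2)) <= cutoff
  }
  reach <- adj
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (reach[i, k] && reach[k, j]) reach[i, j] <- TRUE
  vapply(seq_len(n), function(i) min(which(reach[i, ])), integer(1))
}

# fine-grid reference dG_dim for a true_pmf (independent of the WHAM path)
true_dgdim <- function(true_pmf, r_max = 2.0, r_ref = 2.75, temperature = 303) {
  r <- seq(attr(true_pmf, "domain")[1] + 5e-4, r_max - 5e-4, by = 1e-3)
  p <- pmf_profile(r, true_pmf(r) - true_pmf(r_ref), temperature)
  dimerization_free_energy(association_constant(p, r_max, temperature),
                           temperature)
}
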