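# Shared fixtures, built in code: the fibroin-H-like hairpin (31 residues,
# 13 cross-strand hydrogen-bond geometries) and a small two-sheet sandwich
# kept deliberately compact so dynamics tests stay fast.

fh_hairpin <- function(backbone = TRUE) {
  make_beta_hairpin(residues_per_strand = 14L, backbone = backbone)
}

fh_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_go_model(fh_hairpin())
    cache
  }
})

small_sandwich_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fold_spec(n_strands = 4L, residues_per_strand = 5L,
                        strands_per_sheet = 2L)
      cache <<- suppressMessages(build_go_model(make_beta_sandwich(spec)))
    }
    cache
  }
})

# brute-force contact oracle: all residue pairs, all atom pairs, no indexing
# tricks shared with the implementation
brute_force_contacts <- function(structure, cutoff, min_seq_sep = 3L,
                                 calpha_only = FALSE) {
  at <- structure$atoms
  if (calpha_only) at <- at[at$atom_name == "CA", ]
  n <- max(at$res_index)
  hits <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i <= min_seq_sep) next
      ai <- at[at$res_index == i, c("x", "y", "z")]
      aj <- at[at$res_index == j, c("x", "y", "z")]
      dmin <- Inf
      for (p in seq_len(nrow(ai))) {
        for (q in seq_len(nrow(aj))) {
          dmin <- min(dmin, sqrt(sum((ai[p, ] - aj[q, ])^2)))
        }
      }
      if (dmin <= cutoff) hits[[length(hits) + 1L]] <- c(i, j)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  out <- as.data.frame(do.call(rbind, hits))
  names(out) <- c("i", "j")
  out[order(out$i, out$j), ]
}

# deterministic rigid transform for invariance checks
rigid_transform <- function(xyz, seed = 1L) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  shift <- rnorm(3, sd = 20)
  sweep(xyz %*% t(R), 2, shift, "+")
}
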