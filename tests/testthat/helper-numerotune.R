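# Shared fixtures and independent oracles, built in code at test time.

tiny_cohort_config <- function(...) {
  args <- list(n_subjects = 2, voxels_per_roi = 16, nf_subjects = 1,
               n_localizer_runs = 2, n_block_runs = 2)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

# Independent signed-rank oracle: full enumeration over all 2^n sign
# assignments of the observed (mid)ranks; one-sided P(W >= w_obs).
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% rk)
  mean(w_all >= w_obs - 1e-12)
}

# Independent BH oracle: literal step-up rule, min over j >= i of m p(j) / j.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Count dot regions in a rendered display, preferring EBImage's labeller as
# an independent implementation when it is installed.
oracle_component_count <- function(img) {
  if (requireNamespace("EBImage", quietly = TRUE)) {
    max(EBImage::bwlabel(EBImage::Image(img * 1)))
  } else {
    numerotune:::count_components(img)
  }
}

# A manifest shared across tests (building it is cheap but not free).
shared_manifest <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_pool_manifest(seed = 101)
    cache
  }
})
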