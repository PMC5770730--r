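# Shared fixtures, built once per test run (all generated in code).

ref_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_reference_params(seed = 1)
    cache
  }
})

ref_baseline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- average_activation(simulate_network(ref_params()))
    }
    cache
  }
})

# naive, loop-based window mean (oracle for average_activation)
naive_window_mean <- function(trace, lo, hi) {
  units <- colnames(trace$activities)
  out <- numeric(length(units))
  names(out) <- units
  for (u in units) {
    s <- 0
    n <- 0
    for (t in lo:hi) {
      s <- s + trace$activities[t, u]
      n <- n + 1
    }
    out[u] <- s / n
  }
  out
}

# brute-force nested-loop elaboration of all adjustment sequences up to
# `depth` (oracle for enumerate_tree); returns sorted multiset of
# level:key strings
oracle_sequences <- function(params, receptors, depth) {
  root <- receptor_configuration(params, receptors)
  out <- paste0(0, ":", paste(root$delta, collapse = ","))
  recurse <- function(config, level) {
    if (level == depth) return(invisible())
    mv <- legal_moves(config)
    for (i in seq_len(nrow(mv))) {
      child <- apply_adjustment(config, mv$receptor[i], mv$direction[i])
      out <<- c(out, paste0(level + 1, ":", paste(child$delta, collapse = ",")))
      recurse(child, level + 1)
    }
  }
  recurse(root, 0)
  sort(out)
}
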