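# shared fixtures and independent oracles

default_smooth_params <- function(w_p = 0.3, w_t = 0, w_m = -0.7) {
  construction_params(eps = 0.05, theta = 0.5, w_s = 1, w_m = w_m,
                      w_p = w_p, w_t = w_t)
}

smooth_spec <- function() activation_spec("smooth", eps = 0.05, theta = 0.5)

# brute-force admissibility oracle: loops over all index combinations,
# independent of the vectorised implementation in validate_graph()
oracle_admissible <- function(A) {
  n <- nrow(A)
  for (i in seq_len(n)) if (A[i, i] == 1) return(FALSE)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && A[i, j] * A[j, i] == 1) return(FALSE)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (length(unique(c(i, j, k))) == 3 && A[i, j] * A[i, k] * A[j, k] == 1) return(FALSE)
  }
  TRUE
}

# reachability oracle via boolean matrix powers (independent of igraph)
oracle_strongly_connected <- function(A) {
  n <- nrow(A)
  R <- diag(n) + A
  for (s in seq_len(n)) R <- (R %*% R > 0) * 1
  all(R > 0)
}
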