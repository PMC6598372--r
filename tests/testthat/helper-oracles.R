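# Independent brute-force oracles, deliberately naive.

# pairwise AUC with half-credit ties: literal double loop
auc_pairwise <- function(cases, controls) {
  s <- 0
  for (a in cases) {
    for (b in controls) {
      s <- s + (a > b) + 0.5 * (a == b)
    }
  }
  s / (length(cases) * length(controls))
}

# exact two-sided rank-sum p by complete enumeration (tie-free inputs)
perm_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  centre <- n1 * length(y) / 2
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(w_all - centre) >= abs(w_obs - centre) - 1e-9)
}

# recount a 2x2 table from call vectors
recount_2x2 <- function(case_calls, control_calls) {
  c(
    tp = sum(case_calls == TRUE), fn = sum(case_calls == FALSE),
    fp = sum(control_calls == TRUE), tn = sum(control_calls == FALSE)
  )
}

# random integer score distribution for property tests
random_scores <- function(n, max_score = 10) {
  sample(0:max_score, n, replace = TRUE)
}
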