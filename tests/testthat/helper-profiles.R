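# shared fixtures built in code

gauss_profile <- function(centers, sigmas, amplitudes, n_frac = 24) {
  f <- seq_len(n_frac)
  y <- numeric(n_frac)
  for (k in seq_along(centers))
    y <- y + amplitudes[k] * exp(-(f - centers[k])^2 / (2 * sigmas[k]^2))
  y
}

# exhaustive one-to-one matching oracle: maximise pair count, then minimise
# total shift, over all injective assignments (feasible for <= 4 x 4)
exhaustive_match <- function(c1, c2, max_shift = 2) {
  n1 <- length(c1); n2 <- length(c2)
  best <- list(n = -1L, total = Inf, pairs = NULL)
  idx2 <- seq_len(n2)
  subsets1 <- unlist(lapply(0:min(n1, n2), function(k)
    if (k == 0) list(integer(0)) else
      utils::combn(n1, k, simplify = FALSE)), recursive = FALSE)
  for (s1 in subsets1) {
    k <- length(s1)
    if (k == 0) {
      if (best$n < 0) best <- list(n = 0L, total = 0, pairs = NULL)
      next
    }
    subs2 <- utils::combn(n2, k, simplify = FALSE)
    perms <- all_perms(k)
    for (s2 in subs2) for (pi in seq_len(nrow(perms))) {
      t2 <- s2[perms[pi, ]]
      sh <- abs(c1[s1] - c2[t2])
      if (all(sh <= max_shift)) {
        tot <- sum(sh)
        if (k > best$n || (k == best$n && tot < best$total))
          best <- list(n = k, total = tot,
                       pairs = data.frame(i = s1, j = t2, shift = sh))
      }
    }
  }
  best
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

# closed-form OLS oracle via normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  unname(solve(t(X) %*% X, t(X) %*% y)[, 1])
}

tiny_quant_table <- function() {
  f <- function(rep) sprintf("Intensity.%s.%02d", rep, 1:24)
  y1 <- c(0, 0, 5, 9, 4, rep(0, 19))
  y2 <- gauss_profile(10, 1.5, 100)
  tab <- data.frame(protein_id = c("A1", "A2"),
                    Peptides = c(3L, 1L), Score = c(50, 7.2),
                    check.names = FALSE)
  tab[f("bio1")] <- rbind(y1, y2)
  tab[f("bio2")] <- rbind(y1, y2 * 0.9)
  tab
}
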