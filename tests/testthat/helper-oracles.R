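# Brute-force re-implementations used as independent oracles. These are
# deliberately written in the most literal way possible and share no code
# with the package internals.

# Pooled-variance two-sample t with the same degenerate-case conventions
# the segmentation scan documents: zero pooled SD gives t = Inf when the
# means differ and 0 when they are equal.
oracle_pooled_t <- function(a, b) {
  ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  df <- length(a) + length(b) - 2
  se2 <- if (df > 0) ss / df * (1 / length(a) + 1 / length(b)) else 0
  d <- mean(a) - mean(b)
  if (se2 <= 0) {
    if (d == 0) 0 else Inf
  } else {
    abs(d) / sqrt(se2)
  }
}

# Exhaustive scan over every circular split (every linear arc [b1, b2)
# with b2 <= n-1; wrapping arcs are complements and give the same
# partition), ties broken by smaller start then shorter arc.
oracle_max_arc <- function(x) {
  n <- length(x)
  best <- list(b1 = -1L, b2 = -1L, t = -Inf)
  for (b1 in 0:(n - 2)) {
    max_b2 <- n - 1
    if (b1 + 1 > max_b2) next
    for (b2 in (b1 + 1):max_b2) {
      arc <- x[(b1 + 1):b2]
      rest <- x[-((b1 + 1):b2)]
      t <- oracle_pooled_t(arc, rest)
      if (t > best$t) best <- list(b1 = b1, b2 = b2, t = t)
    }
  }
  best
}

# Literal step-up definition: q for the i-th smallest p is
# min over j >= i of (m / j) p_(j), clipped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m / j * p[o[j]], 0)
    q[o[i]] <- min(c(cand, 1))
  }
  q
}

# Literal outlier rule: deviation from the median of the +/-k neighbours
# (excluding self) beyond z robust SDs of the whole chromosome.
oracle_outlier_flags <- function(values, k, z) {
  n <- length(values)
  rsd <- stats::mad(values)
  flags <- logical(n)
  if (rsd == 0 || n < 3) return(flags)
  for (i in seq_len(n)) {
    nb <- setdiff(max(1, i - k):min(n, i + k), i)
    flags[i] <- abs(values[i] - median(values[nb])) > z * rsd
  }
  flags
}

# Small default study used across tests (overridable).
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_samples = 12, n_chromosomes = 3, clones_per_chrom = 40,
         n_expr_clones = 150, seed = 42),
    list(...))
  do.call(sim_config, args)
}
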