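# Shared fixtures and the extra, definition-level oracle used by the tests.

fig1_variants <- function() {
  # a SNP and a 1 bp deletion that normalize to the same fork site
  data.frame(pos = c(4, 5), ref = c("TA", "A"), alt = c("T", "T"))
}

fig1_graph <- function() build_graph("ACGTACGT", fig1_variants())

rand_model <- function(mode = sample(c("semiglobal", "local"), 1)) {
  scoring_model(mode,
                match = if (mode == "local") sample(1:3, 1) else sample(0:3, 1),
                mismatch_min = sample(0:3, 1),
                mismatch_max = sample(3:8, 1),
                gap_open = sample(0:8, 1),
                gap_extend = sample(1:4, 1),
                ambig_penalty = sample(0:3, 1))
}

rand_graph <- function(L = sample(10:30, 1), snp_rate = 0.15, indel_rate = 0.1) {
  genome <- simulate_genome(L)
  vars <- simulate_variants(genome, snp_rate = snp_rate, indel_rate = indel_rate,
                            max_indel = 2)
  build_graph(genome, vars)
}

rand_read <- function(len = sample(3:10, 1), with_quals = runif(1) < 0.5) {
  list(seq = simulate_genome(len),
       quals = if (with_quals) sample(0:45, len, replace = TRUE) else NULL)
}

# Memoized recursion written directly from the affine-gap recurrence
# definition; the plainest possible scorer, used to cross-check the
# path-enumeration oracle on single-node graphs.
naive_affine <- function(ref, read, quals = NULL, model) {
  a <- strsplit(ref, "")[[1]]; b <- strsplit(read, "")[[1]]
  m <- length(b); L <- length(a)
  pen <- if (is.null(quals)) rep(model$mismatch_max, m) else
    mismatch_penalty(model, quals)
  go <- model$gap_open; ge <- model$gap_extend
  local <- model$mode == "local"
  subst <- function(i, j) {
    if (a[j] == "N" || b[i] == "N") -model$ambig_penalty
    else if (a[j] == b[i]) model$match else -pen[i]
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(key, f) {
    if (!is.null(memo[[key]])) return(memo[[key]])
    memo[[key]] <- f()
  }
  E <- function(i, j) rec(paste0("E", i, ",", j), function() {
    if (j == 0) return(-Inf)
    max(H(i, j - 1) - go - ge, E(i, j - 1) - ge)
  })
  Fv <- function(i, j) rec(paste0("F", i, ",", j), function() {
    if (i == 0) return(-Inf)
    max(H(i - 1, j) - go - ge, Fv(i - 1, j) - ge)
  })
  H <- function(i, j) rec(paste0("H", i, ",", j), function() {
    if (i == 0) return(0)
    h <- if (j == 0) Fv(i, 0) else
      max(H(i - 1, j - 1) + subst(i, j), E(i, j), Fv(i, j))
    if (local) max(h, 0) else h
  })
  if (local) max(0, vapply(0:L, function(j)
    max(vapply(0:m, function(i) H(i, j), numeric(1))), numeric(1)))
  else max(vapply(0:L, function(j) H(m, j), numeric(1)))
}
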