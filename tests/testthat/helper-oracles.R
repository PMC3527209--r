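# Independent brute-force oracles and small fixture builders.
# These re-derive every quantity from first principles (explicit pair and
# path enumeration) and never call the package's own vectorized paths.

BASES <- c("A", "C", "G", "T")

# random aligned haplotypes as a character matrix (L x n), iid sites with
# occasional missing data and a controllable polymorphism rate
rand_haps <- function(n, L, poly = 0.05, miss = 0.05) {
  m <- matrix("A", L, n)
  anc <- sample(BASES, L, replace = TRUE)
  m[] <- rep(anc, n)
  nvar <- rpois(1, poly * L)
  if (nvar > 0) {
    at <- sample.int(L, min(nvar, L))
    for (s in at) {
      alt <- sample(setdiff(BASES, anc[s]), 1)
      carriers <- sample.int(n, sample.int(n - 1, 1))
      m[s, carriers] <- alt
    }
  }
  if (miss > 0) m[runif(length(m)) < miss] <- "N"
  colnames(m) <- sprintf("h%02d", seq_len(n))
  m
}

chr_to_hs <- function(m, arm = "arm", pop = "pop") {
  seqs <- apply(m, 2, paste0, collapse = "")
  meta <- data.frame(genome_id = colnames(m), population = pop,
                     depth = 30, role = "query")
  haplotype_set(seqs, meta, arm = arm)
}

# per-site pairwise deletion oracle for pi (within a character matrix)
oracle_pi <- function(m) {
  L <- nrow(m); n <- ncol(m)
  tot <- 0; nsites <- 0
  for (s in seq_len(L)) {
    called <- which(m[s, ] != "N")
    if (length(called) < 2) next
    d <- 0; p <- 0
    for (i in called) for (j in called) if (i < j) {
      p <- p + 1
      if (m[s, i] != m[s, j]) d <- d + 1
    }
    tot <- tot + d / p
    nsites <- nsites + 1
  }
  if (nsites == 0) return(list(pi = NA_real_, n = 0))
  list(pi = tot / nsites, n = nsites)
}

oracle_dxy <- function(ma, mb) {
  L <- nrow(ma)
  tot <- 0; nsites <- 0
  for (s in seq_len(L)) {
    ca <- which(ma[s, ] != "N"); cb <- which(mb[s, ] != "N")
    if (!length(ca) || !length(cb)) next
    d <- 0; p <- 0
    for (i in ca) for (j in cb) {
      p <- p + 1
      if (ma[s, i] != mb[s, j]) d <- d + 1
    }
    tot <- tot + d / p
    nsites <- nsites + 1
  }
  if (nsites == 0) return(list(dxy = NA_real_, n = 0))
  list(dxy = tot / nsites, n = nsites)
}

# Hudson F_ST oracle: per-site Hw/Hb accumulated over sites usable in
# both populations and between them
oracle_fst <- function(ma, mb) {
  L <- nrow(ma)
  hw <- 0; hb <- 0; nsites <- 0
  pi_site <- function(row) {
    called <- which(row != "N")
    if (length(called) < 2) return(NA_real_)
    d <- 0; p <- 0
    for (i in called) for (j in called) if (i < j) {
      p <- p + 1; if (row[i] != row[j]) d <- d + 1
    }
    d / p
  }
  dxy_site <- function(ra, rb) {
    ca <- which(ra != "N"); cb <- which(rb != "N")
    if (!length(ca) || !length(cb)) return(NA_real_)
    d <- 0; p <- 0
    for (i in ca) for (j in cb) { p <- p + 1
      if (ra[i] != rb[j]) d <- d + 1 }
    d / p
  }
  for (s in seq_len(L)) {
    a <- pi_site(ma[s, ]); b <- pi_site(mb[s, ])
    ab <- dxy_site(ma[s, ], mb[s, ])
    if (is.na(a) || is.na(b) || is.na(ab)) next
    hw <- hw + (a + b) / 2; hb <- hb + ab
    nsites <- nsites + 1
  }
  if (nsites == 0 || hb == 0) return(NA_real_)
  1 - hw / hb
}

# signed LD oracle from the 2x2 haplotype table (minor-allele coupling).
# When either site is at exactly 50/50 frequency the minor allele - and
# hence the sign - is convention-dependent; the result then carries
# attr "ambiguous_sign" = TRUE and only |r| is meaningful.
oracle_rw <- function(x, y) {
  ok <- x != "N" & y != "N"
  x <- x[ok]; y <- y[ok]
  ax <- names(sort(table(x)))
  ay <- names(sort(table(y)))
  if (length(ax) != 2 || length(ay) != 2) return(NA_real_)
  xm <- as.numeric(x == ax[1])   # minor indicator
  ym <- as.numeric(y == ay[1])
  pA <- mean(xm); pB <- mean(ym); pAB <- mean(xm * ym)
  D <- pAB - pA * pB
  den <- sqrt(pA * (1 - pA) * pB * (1 - pB))
  if (den == 0) return(NA_real_)
  structure(D / den, ambiguous_sign = (pA == 0.5 || pB == 0.5))
}

# exhaustive path-enumeration posterior for the two-state chain
enum_posterior <- function(lik, tau, p0) {
  n <- nrow(lik)
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  w <- apply(states, 1, function(s) {
    p <- if (s[1] == 1) p0 else 1 - p0
    p <- p * lik[1, s[1] + 1]
    if (n > 1) for (t in 2:n) {
      p <- p * (if (s[t] == s[t - 1]) 1 - tau else tau) * lik[t, s[t] + 1]
    }
    p
  })
  vapply(seq_len(n), function(t) sum(w[states[, t] == 1]) / sum(w),
         numeric(1))
}
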